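vs1 = 0
vs2 = 0.87281706041562723
vs3 = 2.5088667883898874
vs4 = 0.97882150399222101
vs5 = 1.2824376393448043
v1 = 0.31309512679316504
v2 = 0.8313243639243616
v3 = 2.4045705737715077
v4 = 0.43081889446739507
v5 = 0.81214574371331116
v6 = 2.635604959580903
v7 = 1.6135273753350645
v8 = 0.86011274698875495
v9 = 0.44399958813984908
v10 = 0.9736944614221259
v11 = 0.38845364296459373
ke1 = 1.2698490393870991
ke2 = 1.4814401696153849
ke3 = 0.051711082232086016
ke4 = 0.050029219816068116
ke5 = 0.050193170281487287
ke6 = 0.050000000000000003
ke7 = 0.45022134761615457
ke8 = 1.4729598473782035
ke9 = 2.5257526818868734
ke10 = 0.27197321479500741
ke11 = 0.52139815150552082
kd1 = 0.10173176427456528
kd2 = 0.23324747627328332
kd3 = 0.14576982255334603
kd4 = 0.052074683953484441
kd5 = 0.099820421137744364
kd6 = 0.12126307071736825
kd7 = 0.18536003817516289
kd8 = 0.1109271527045959
kd9 = 0.14391172335499555
kd10 = 0.11257809733326184
kd11 = 0.068096070352954549
kd12 = 7.0503827038032396
kd13 = 2.4402160212123176
k1 = 1.348040263127239
k2 = 1.1828074925401548
k3 = 0.82012569623304843
k4 = 0.41580680163088657
k5 = 0.39979602016071075
k6 = 0.1187426797037055
k7 = 0.32526627237811784
kp1 = 0.073315091911957883
kp2 = 0.093928538037949497
kp3 = 0.058941407868117454
kp4 = 0.19036183709024435
ka1 = 2.6823420730427139
ka2 = 0.53073098957627074
ka3 = 2.1425446486389466
ka4 = 0.74867712104406081
kI1 = 0.26079006437400992
kx = 0.10000000000000001
kk = 0
m = 2
w = 2
s = 2
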