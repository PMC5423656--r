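vs1 = 0.50318479984865039
vs2 = 0.87115802207956261
vs3 = 2.5040979698472752
vs4 = 0.97696097390758418
vs5 = 1.2800000000000002
v1 = 0.3125
v2 = 0.82974419431952107
v3 = 2.4000000000000004
v4 = 0.48783138987335795
v5 = 0.81060202855878549
v6 = 2.6305952389132243
v7 = 1.6104604052981866
v8 = 0.85847785683214783
v9 = 0.44315563999615654
v10 = 0.97184367674756433
v11 = 0.38771527576865994
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
kd1 = 0.10153839397444003
kd2 = 0.23280412276602783
kd3 = 0.14549274533427542
kd4 = 0.051975701130009218
kd5 = 0.099630683891647476
kd6 = 0.12103257558592199
kd7 = 0.18500770843362396
kd8 = 0.11071630394006809
kd9 = 0.14363817798462736
kd10 = 0.11236411047651071
kd11 = 0.067966634304583648
kd12 = 7.036981435977463
kd13 = 2.4355776930779629
k1 = 1.3454779272420745
k2 = 1.1805592287706839
k3 = 0.81856681289752509
k4 = 0.41501644193744341
k5 = 0.39903609353446351
k6 = 0.11851697529588642
k7 = 0.32464801084339578
kp1 = 0.073175735621149221
kp2 = 0.093749999999999986
kp3 = 0.058829372872847924
kp4 = 0.18792498620409945
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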