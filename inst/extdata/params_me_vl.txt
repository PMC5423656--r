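vs1 = 0.65411326245535861
vs2 = 0
vs3 = 4.2050138300701621
vs4 = 0.91291875704893477
vs5 = 0.46722375889668472
v1 = 0.41115690782908254
v2 = 1.2895375745548496
v3 = 1.560527354714927
v4 = 0.4558528313688488
v5 = 0.75746505350502702
v6 = 2.458153191321518
v7 = 1.504890728235394
v8 = 0.80220250239737212
v9 = 0.41410568779054052
v10 = 0.90813691141994324
v11 = 0.36229957705259597
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
kd1 = 0.094882300210140713
kd2 = 0.21754323465077754
kd3 = 0.074755801423469562
kd4 = 0.048568564906507142
kd5 = 0.093099645258605826
kd6 = 0.11309858982840318
kd7 = 0.17287999391843933
kd8 = 0.10345857539605288
kd9 = 0.13422233887809723
kd10 = 0.10499836412383537
kd11 = 0.063511252718687863
kd12 = 6.5756898356071609
kd13 = 2.2759195296896033
k1 = 1.345604425622452
k2 = 1.1031706409328201
k3 = 0.76490772646012173
k4 = 0.38781108401188003
k5 = 0.37287828711324222
k6 = 0.11074789338161915
k7 = 0.30336652788916607
kp1 = 0.10278922695727064
kp2 = 0.1682005532028065
kp3 = 0.054972961454373324
kp4 = 0.17560603688977391
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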