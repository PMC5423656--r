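vs1 = 0.54564928280265212
vs2 = 0.85945358809963035
vs3 = 2.1212387485149105
vs4 = 0.7008125074075845
vs5 = 1.2800000000000002
v1 = 0.2778178957458336
v2 = 0.57035813375971678
v3 = 2.4000000000000004
v4 = 0.40099703126067049
v5 = 0.82587460046649486
v6 = 2.6305952389132243
v7 = 1.5768015035186598
v8 = 0.94108650086029522
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
kd1 = 0.18889073630269324
kd2 = 0.25049473669105288
kd3 = 0.14549274533427542
kd4 = 0.047629914489427709
kd5 = 0.13410438640242286
kd6 = 0.12103257558592199
kd7 = 0.18625837078422267
kd8 = 0.11384723539454389
kd9 = 0.14363817798462736
kd10 = 0.11236411047651071
kd11 = 0.067966634304583648
kd12 = 7.036981435977463
kd13 = 2.4355776930779629
k1 = 1.5936079370831817
k2 = 1.1805592287706839
k3 = 1.1914978838940746
k4 = 0.41501644193744341
k5 = 0.42059610766083344
k6 = 0.11851697529588642
k7 = 0.32464801084339578
kp1 = 0.073175735621149221
kp2 = 0.093749999999999986
kp3 = 0.058829372872847924
kp4 = 0.18792498620409945
ka1 = 2.7147284786954824
ka2 = 0.53573887722072111
ka3 = 1.0386166119133728
ka4 = 0.74867712104406081
kI1 = 0.26079006437400992
kx = 0.10000000000000001
kk = 0
m = 2
w = 2
s = 2
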