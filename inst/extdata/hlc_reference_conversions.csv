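taxon,trap,collected,hlc,hlc_lo,hlc_hi
culex,SUN,10,10,9,11
culex,SUN,20,20,18,23
culex,SUN,30,30,26,35
culex,SUN,40,41,35,47
culex,SUN,50,51,43,59
culex,SUN,60,61,51,72
culex,SUN,70,71,59,84
culex,SUN,80,81,68,97
culex,SUN,90,92,76,110
culex,SUN,100,102,84,123
culex,BGS,10,11,10,12
culex,BGS,20,23,20,25
culex,BGS,30,35,30,39
culex,BGS,40,47,40,54
culex,BGS,50,59,49,68
culex,BGS,60,71,59,83
culex,BGS,70,83,69,98
culex,BGS,80,96,79,114
culex,BGS,90,108,89,129
culex,BGS,100,121,99,145
culex,ITTC,10,8,8,9
culex,ITTC,20,16,14,18
culex,ITTC,30,23,20,26
culex,ITTC,40,30,26,35
culex,ITTC,50,37,32,43
culex,ITTC,60,44,37,51
culex,ITTC,70,51,43,59
culex,ITTC,80,57,48,68
culex,ITTC,90,64,53,76
culex,ITTC,100,70,59,84
culex,MMX,10,25,22,30
culex,MMX,20,68,54,83
culex,MMX,30,120,94,150
culex,MMX,40,179,137,230
culex,MMX,50,246,185,320
culex,MMX,60,318,236,418
culex,MMX,70,395,290,525
culex,MMX,80,476,347,639
culex,MMX,90,562,406,760
culex,MMX,100,652,467,888
culex,MTRC,10,9,8,9
culex,MTRC,20,17,16,19
culex,MTRC,30,25,23,28
culex,MTRC,40,33,30,37
culex,MTRC,50,41,37,46
culex,MTRC,60,49,44,55
culex,MTRC,70,56,50,63
culex,MTRC,80,64,57,72
culex,MTRC,90,72,63,81
culex,MTRC,100,79,70,90
culex,MTR,10,9,9,10
culex,MTR,20,19,17,20
culex,MTR,30,27,25,30
culex,MTR,40,36,33,40
culex,MTR,50,45,40,51
culex,MTR,60,54,48,61
culex,MTR,70,63,55,71
culex,MTR,80,72,63,81
culex,MTR,90,80,70,91
culex,MTR,100,89,77,102
an_arabiensis,SUN,10,14,12,16
an_arabiensis,SUN,20,31,25,37
an_arabiensis,SUN,30,49,39,60
an_arabiensis,SUN,40,68,53,85
an_arabiensis,SUN,50,88,67,111
an_arabiensis,SUN,60,108,82,139
an_arabiensis,SUN,70,129,97,167
an_arabiensis,SUN,80,150,112,196
an_arabiensis,SUN,90,172,127,226
an_arabiensis,SUN,100,194,142,257
an_arabiensis,BGS,10,20,16,25
an_arabiensis,BGS,20,51,38,66
an_arabiensis,BGS,30,87,62,117
an_arabiensis,BGS,40,126,88,175
an_arabiensis,BGS,50,170,115,239
an_arabiensis,BGS,60,216,144,308
an_arabiensis,BGS,70,264,174,382
an_arabiensis,BGS,80,315,204,460
an_arabiensis,BGS,90,368,235,543
an_arabiensis,BGS,100,423,268,629
an_arabiensis,ITTC,10,20,17,24
an_arabiensis,ITTC,20,50,39,64
an_arabiensis,ITTC,30,86,63,112
an_arabiensis,ITTC,40,125,90,166
an_arabiensis,ITTC,50,168,118,227
an_arabiensis,ITTC,60,213,147,292
an_arabiensis,ITTC,70,261,178,361
an_arabiensis,ITTC,80,311,209,435
an_arabiensis,ITTC,90,363,241,512
an_arabiensis,ITTC,100,417,275,592
an_arabiensis,MMX,10,18,14,22
an_arabiensis,MMX,20,43,30,57
an_arabiensis,MMX,30,71,48,99
an_arabiensis,MMX,40,102,66,146
an_arabiensis,MMX,50,135,85,198
an_arabiensis,MMX,60,170,105,253
an_arabiensis,MMX,70,207,125,311
an_arabiensis,MMX,80,245,145,373
an_arabiensis,MMX,90,284,166,437
an_arabiensis,MMX,100,325,187,504
an_arabiensis,MTRC,10,13,11,14
an_arabiensis,MTRC,20,27,23,32
an_arabiensis,MTRC,30,43,36,51
an_arabiensis,MTRC,40,59,48,70
an_arabiensis,MTRC,50,75,61,91
an_arabiensis,MTRC,60,92,74,112
an_arabiensis,MTRC,70,109,87,134
an_arabiensis,MTRC,80,127,100,157
an_arabiensis,MTRC,90,144,114,179
an_arabiensis,MTRC,100,162,127,203
an_arabiensis,MTR,10,16,14,18
an_arabiensis,MTR,20,36,31,43
an_arabiensis,MTR,30,59,49,71
an_arabiensis,MTR,40,84,68,102
an_arabiensis,MTR,50,109,88,135
an_arabiensis,MTR,60,136,108,170
an_arabiensis,MTR,70,164,129,207
an_arabiensis,MTR,80,192,150,244
an_arabiensis,MTR,90,222,172,283
an_arabiensis,MTR,100,251,194,323
an_funestus,SUN,10,2,1,7
an_funestus,SUN,20,3,1,12
an_funestus,SUN,30,3,1,17
an_funestus,SUN,40,4,1,21
an_funestus,SUN,50,4,1,26
an_funestus,SUN,60,5,1,30
an_funestus,SUN,70,5,1,34
an_funestus,SUN,80,6,1,38
an_funestus,SUN,90,6,1,42
an_funestus,SUN,100,7,1,46
an_funestus,BGS,10,22,3,67
an_funestus,BGS,20,63,4,237
an_funestus,BGS,30,118,4,497
an_funestus,BGS,40,185,5,840
an_funestus,BGS,50,263,5,1262
an_funestus,BGS,60,352,6,1760
an_funestus,BGS,70,452,6,2332
an_funestus,BGS,80,561,6,2975
an_funestus,BGS,90,679,7,3689
an_funestus,BGS,100,807,7,4471
an_funestus,ITTC,10,7,3,13
an_funestus,ITTC,20,12,3,28
an_funestus,ITTC,30,17,4,44
an_funestus,ITTC,40,22,4,60
an_funestus,ITTC,50,27,5,77
an_funestus,ITTC,60,32,5,95
an_funestus,ITTC,70,37,6,113
an_funestus,ITTC,80,42,6,131
an_funestus,ITTC,90,47,6,149
an_funestus,ITTC,100,51,6,167
an_funestus,MMX,10,5,1,16
an_funestus,MMX,20,9,1,35
an_funestus,MMX,30,13,1,58
an_funestus,MMX,40,17,1,81
an_funestus,MMX,50,21,1,106
an_funestus,MMX,60,26,1,131
an_funestus,MMX,70,30,1,158
an_funestus,MMX,80,34,1,185
an_funestus,MMX,90,38,1,213
an_funestus,MMX,100,43,1,242
an_funestus,MTRC,10,10,5,16
an_funestus,MTRC,20,19,8,37
an_funestus,MTRC,30,29,10,60
an_funestus,MTRC,40,39,12,85
an_funestus,MTRC,50,49,14,111
an_funestus,MTRC,60,59,16,139
an_funestus,MTRC,70,69,18,167
an_funestus,MTRC,80,79,20,196
an_funestus,MTRC,90,89,21,226
an_funestus,MTRC,100,99,23,256
an_funestus,MTR,10,7,3,11
an_funestus,MTR,20,12,5,23
an_funestus,MTR,30,17,6,36
an_funestus,MTR,40,22,6,48
an_funestus,MTR,50,26,7,61
an_funestus,MTR,60,31,8,74
an_funestus,MTR,70,35,9,86
an_funestus,MTR,80,40,9,99
an_funestus,MTR,90,44,10,113
an_funestus,MTR,100,49,10,126
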