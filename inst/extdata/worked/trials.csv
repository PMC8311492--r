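subject_id,trial_index,gain,loss,response,rt
s001,1,38,17,1,0.87
s001,2,24,17,4,0.578
s001,3,24,10,2,1.113
s001,4,34,9,2,2.1219
s001,5,16,18,4,1.5187
s001,6,20,5,1,1.1267
s001,7,26,16,1,1.6505
s001,8,10,13,3,1.4089
s001,9,30,10,2,0.6461
s001,10,36,11,2,1.2221
s001,11,12,12,3,0.6607
s001,12,22,10,2,0.9355
s001,13,18,18,4,1.586
s001,14,26,11,2,0.9044
s001,15,40,19,1,1.7507
s001,16,26,19,4,2.834
s001,17,26,6,1,1.2235
s001,18,24,15,1,0.7552
s001,19,12,9,4,2.1414
s001,20,24,8,2,0.8504
s002,1,38,17,4,0.7211
s002,2,24,17,4,0.7244
s002,3,24,10,3,1.1981
s002,4,34,9,1,1.1718
s002,5,16,18,4,2.0034
s002,6,20,5,2,0.9082
s002,7,26,16,3,2.2103
s002,8,10,13,4,1.8129
s002,9,30,10,3,1.4731
s002,10,36,11,2,1.4967
s002,11,12,12,3,1.2054
s002,12,22,10,3,1.544
s002,13,18,18,3,1.0674
s002,14,26,11,4,1.4547
s002,15,40,19,4,1.2021
s002,16,26,19,3,0.9813
s002,17,26,6,2,0.3875
s002,18,24,15,3,1.1331
s002,19,12,9,3,1.0405
s002,20,24,8,2,1.2273
s003,1,38,17,4,1.373
s003,2,24,17,3,1.5256
s003,3,24,10,3,1.3083
s003,4,34,9,1,0.7379
s003,5,16,18,4,2.3986
s003,6,20,5,1,0.7836
s003,7,26,16,3,0.8989
s003,8,10,13,3,1.7439
s003,9,30,10,2,1.2555
s003,10,36,11,2,1.1305
s003,11,12,12,3,1.2788
s003,12,22,10,3,1.062
s003,13,18,18,4,1.9201
s003,14,26,11,4,1.3987
s003,15,40,19,3,0.9045
s003,16,26,19,4,0.8827
s003,17,26,6,1,0.5941
s003,18,24,15,3,0.8119
s003,19,12,9,4,1.2961
s003,20,24,8,4,2.1121
s004,1,38,17,1,1.1134
s004,2,24,17,4,2.3549
s004,3,24,10,1,1.7132
s004,4,34,9,1,1.0231
s004,5,16,18,3,1.4753
s004,6,20,5,2,2.4069
s004,7,26,16,4,1.4529
s004,8,10,13,4,1.428
s004,9,30,10,2,1.3204
s004,10,36,11,2,1.2781
s004,11,12,12,3,1.2104
s004,12,22,10,2,0.7653
s004,13,18,18,3,1.1298
s004,14,26,11,2,1.3327
s004,15,40,19,4,1.5562
s004,16,26,19,4,1.0616
s004,17,26,6,1,1.0043
s004,18,24,15,3,1.4577
s004,19,12,9,4,1.2252
s004,20,24,8,2,1.296
s005,1,38,17,2,0.5191
s005,2,24,17,1,1.7961
s005,3,24,10,1,0.7593
s005,4,34,9,2,0.6041
s005,5,16,18,1,1.7438
s005,6,20,5,2,0.889
s005,7,26,16,1,0.8207
s005,8,10,13,2,1.733
s005,9,30,10,2,0.5713
s005,10,36,11,2,1.2637
s005,11,12,12,2,1.0243
s005,12,22,10,1,0.8023
s005,13,18,18,2,0.5491
s005,14,26,11,2,1.812
s005,15,40,19,2,2.5147
s005,16,26,19,1,1.3119
s005,17,26,6,2,0.5326
s005,18,24,15,1,1.0908
s005,19,12,9,2,1.085
s005,20,24,8,2,1.9804
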