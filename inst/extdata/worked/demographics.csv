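subject_id,age,sex,race_ethnicity,smoking,iq,mother_education,scanner_id
s001,41.7905,M,3,0,118.1,15.5,2
s002,18.346,F,3,0,105.7,17.5,1
s003,47.8505,M,1,0,101.8,15.3,1
s004,27.8744,M,3,1,116.6,15.9,2
s005,45.7383,M,2,0,112.9,12.1,2
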