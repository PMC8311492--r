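subject_id,age,sex,race_ethnicity,scanner_id,etiv,qc_pass,insula_lh_thickness,insula_lh_volume,insula_rh_thickness,insula_rh_volume,medialorbitofrontal_lh_thickness,medialorbitofrontal_lh_volume,medialorbitofrontal_rh_thickness,medialorbitofrontal_rh_volume,lateralorbitofrontal_lh_thickness,lateralorbitofrontal_lh_volume,lateralorbitofrontal_rh_thickness,lateralorbitofrontal_rh_volume,rostralanteriorcingulate_lh_thickness,rostralanteriorcingulate_lh_volume,rostralanteriorcingulate_rh_thickness,rostralanteriorcingulate_rh_volume,caudalanteriorcingulate_lh_thickness,caudalanteriorcingulate_lh_volume,caudalanteriorcingulate_rh_thickness,caudalanteriorcingulate_rh_volume,posteriorcingulate_lh_thickness,posteriorcingulate_lh_volume,posteriorcingulate_rh_thickness,posteriorcingulate_rh_volume,superiorfrontal_lh_thickness,superiorfrontal_lh_volume,superiorfrontal_rh_thickness,superiorfrontal_rh_volume,precentral_lh_thickness,precentral_lh_volume,precentral_rh_thickness,precentral_rh_volume,lateraloccipital_lh_thickness,lateraloccipital_lh_volume,lateraloccipital_rh_thickness,lateraloccipital_rh_volume,superiortemporal_lh_thickness,superiortemporal_lh_volume,superiortemporal_rh_thickness,superiortemporal_rh_volume
s002,18.346,F,3,1,1730602,TRUE,2.9841,6918,2.817,7806,2.26,4528,2.2322,5263,2.4392,8406,2.5728,7652,2.7317,1917,2.867,2308,2.556,2066,2.4597,2084,2.5424,3413,2.5469,3440,2.5595,21769,2.6306,23330,2.4516,12839,2.4503,13362,2.0832,12261,2.018,10440,2.7154,12763,2.7012,11457
s003,47.8505,M,1,1,1505448,TRUE,2.6727,5891,2.8363,7695,2.1622,5142,2.1741,5824,2.3233,7308,2.36,7315,2.6275,2191,2.5507,2451,2.4329,1931,2.4078,2132,2.4159,2994,2.4169,3176,2.3727,20708,2.3586,25241,2.2999,14714,2.2635,12103,1.9012,11603,2.0098,11075,2.4825,12212,2.409,11787
s004,27.8744,M,3,2,1614355,TRUE,3.0476,5751,3.0411,6192,2.452,5787,2.3488,5650,2.5617,7157,2.7162,7526,2.8081,2351,2.9089,1957,2.6069,1888,2.6433,2036,2.6965,3199,2.6858,3239,2.6827,23115,2.6952,19019,2.4923,12974,2.5673,15346,2.1352,10833,2.2062,10801,2.7899,11907,2.863,11070
s005,45.7383,M,2,2,1545649,FALSE,2.9863,6823,2.9702,7038,2.3604,5434,2.3652,5617,2.5492,8101,2.4492,7200,2.7927,2375,2.8072,2221,2.4542,2165,2.5958,1750,2.5428,3575,2.5162,3092,2.6489,18294,2.5872,23479,2.3986,11603,2.4809,13092,2.125,11297,2.1384,10544,2.7084,13940,2.6831,11305
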