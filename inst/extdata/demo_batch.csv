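sample_id,native_osm,fat,protein,cho,volume_ml,add_HMF1,add_Microlipid,add_Protein1,add_Polycose
S0001,294.129,3.704,1.001,5.752,100,4,1.776,0.943,2.23
S0002,295.731,3.349,1.318,7.261,100,4,2.934,0.816,1.381
S0003,298.495,3.363,1.69,6.682,100,4,2.649,0.926,1.501
S0004,288.258,4.046,1.163,6.776,100,4,2.017,1.375,1.695
S0005,290.923,3.936,0.966,6.474,100,4,0.047,0.794,1.672
S0006,296.689,3.04,0.907,6.035,100,4,0.936,0.995,1.625
S0007,297.122,3.551,1.19,6.269,100,4,0.715,0.742,2.527
S0008,298.395,3.605,1.301,6.718,100,4,3.11,0.844,2.061
S0009,303.458,3.306,1.124,6.44,100,4,1.173,0.933,1.176
S0010,297.555,3.489,1.418,6.634,100,4,0.754,0.643,1.181
S0011,303.762,3.937,1.341,6.71,100,4,0.342,0.687,1.571
S0012,307.055,2.619,1.139,6.527,100,4,0.227,1.465,1.28
S0013,297.788,3.089,1.19,6.102,100,4,0.904,1.377,1.657
S0014,297.703,3.797,0.987,6.472,100,4,0.804,0.983,1.534
S0015,286.254,2.697,1.431,6.66,100,4,1.371,0.975,2.571
S0016,307.521,2.696,1.517,6.784,100,4,2.605,0.816,1.601
S0017,299.806,4.148,1.056,7.081,100,4,2.151,1.313,2.339
S0018,301.027,3.31,1.189,6.636,100,4,0.419,1.114,1.347
S0019,299.385,3.77,0.993,6.34,100,4,2.585,0.884,1.72
S0020,284.047,3.678,1.015,6.769,100,4,2.945,0.675,2.325
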