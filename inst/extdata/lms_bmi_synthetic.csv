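sex,age_months,L,M,S
female,96,-1.35,15.9,0.112
female,97,-1.3538,15.9434,0.11229
female,98,-1.3575,15.987,0.11258
female,99,-1.3613,16.0308,0.11288
female,100,-1.365,16.0747,0.11317
female,101,-1.3688,16.1188,0.11346
female,102,-1.3725,16.163,0.11375
female,103,-1.3763,16.2074,0.11404
female,104,-1.38,16.252,0.11433
female,105,-1.3838,16.2967,0.11463
female,106,-1.3875,16.3417,0.11492
female,107,-1.3913,16.3868,0.11521
female,108,-1.395,16.432,0.1155
female,109,-1.3988,16.4774,0.11579
female,110,-1.4025,16.523,0.11608
female,111,-1.4062,16.5688,0.11638
female,112,-1.41,16.6147,0.11667
female,113,-1.4138,16.6608,0.11696
female,114,-1.4175,16.707,0.11725
female,115,-1.4213,16.7534,0.11754
female,116,-1.425,16.8,0.11783
female,117,-1.4288,16.8468,0.11813
female,118,-1.4325,16.8937,0.11842
female,119,-1.4363,16.9408,0.11871
female,120,-1.44,16.988,0.119
female,121,-1.4438,17.0354,0.11929
female,122,-1.4475,17.083,0.11958
female,123,-1.4513,17.1307,0.11988
female,124,-1.455,17.1787,0.12017
female,125,-1.4587,17.2267,0.12046
female,126,-1.4625,17.275,0.12075
female,127,-1.4663,17.3234,0.12104
female,128,-1.47,17.372,0.12133
female,129,-1.4738,17.4208,0.12162
female,130,-1.4775,17.4697,0.12192
female,131,-1.4813,17.5188,0.12221
female,132,-1.485,17.568,0.1225
female,133,-1.4888,17.6174,0.12279
female,134,-1.4925,17.667,0.12308
female,135,-1.4963,17.7168,0.12338
female,136,-1.5,17.7667,0.12367
female,137,-1.5038,17.8167,0.12396
female,138,-1.5075,17.867,0.12425
female,139,-1.5112,17.9174,0.12454
female,140,-1.515,17.968,0.12483
female,141,-1.5188,18.0188,0.12513
female,142,-1.5225,18.0697,0.12542
female,143,-1.5263,18.1208,0.12571
female,144,-1.53,18.172,0.126
female,145,-1.5337,18.2234,0.12629
female,146,-1.5375,18.275,0.12658
female,147,-1.5413,18.3268,0.12688
female,148,-1.545,18.3787,0.12717
female,149,-1.5488,18.4307,0.12746
female,150,-1.5525,18.483,0.12775
female,151,-1.5563,18.5354,0.12804
female,152,-1.56,18.588,0.12833
female,153,-1.5638,18.6408,0.12862
female,154,-1.5675,18.6937,0.12892
female,155,-1.5713,18.7467,0.12921
female,156,-1.575,18.8,0.1295
female,157,-1.5788,18.8534,0.12979
female,158,-1.5825,18.907,0.13008
female,159,-1.5863,18.9607,0.13037
female,160,-1.59,19.0147,0.13067
female,161,-1.5938,19.0688,0.13096
female,162,-1.5975,19.123,0.13125
female,163,-1.6013,19.1774,0.13154
female,164,-1.605,19.232,0.13183
female,165,-1.6088,19.2868,0.13212
female,166,-1.6125,19.3417,0.13242
female,167,-1.6162,19.3968,0.13271
male,96,-1.55,15.7,0.118
male,97,-1.5546,15.7401,0.11837
male,98,-1.5592,15.7804,0.11875
male,99,-1.5637,15.8209,0.11912
male,100,-1.5683,15.8617,0.1195
male,101,-1.5729,15.9026,0.11987
male,102,-1.5775,15.9438,0.12025
male,103,-1.5821,15.9851,0.12062
male,104,-1.5867,16.0267,0.121
male,105,-1.5913,16.0684,0.12137
male,106,-1.5958,16.1104,0.12175
male,107,-1.6004,16.1526,0.12212
male,108,-1.605,16.195,0.1225
male,109,-1.6096,16.2376,0.12288
male,110,-1.6142,16.2804,0.12325
male,111,-1.6188,16.3234,0.12362
male,112,-1.6233,16.3667,0.124
male,113,-1.6279,16.4101,0.12438
male,114,-1.6325,16.4537,0.12475
male,115,-1.6371,16.4976,0.12512
male,116,-1.6417,16.5417,0.1255
male,117,-1.6462,16.5859,0.12587
male,118,-1.6508,16.6304,0.12625
male,119,-1.6554,16.6751,0.12662
male,120,-1.66,16.72,0.127
male,121,-1.6646,16.7651,0.12737
male,122,-1.6692,16.8104,0.12775
male,123,-1.6738,16.8559,0.12812
male,124,-1.6783,16.9017,0.1285
male,125,-1.6829,16.9476,0.12887
male,126,-1.6875,16.9937,0.12925
male,127,-1.6921,17.0401,0.12962
male,128,-1.6967,17.0867,0.13
male,129,-1.7012,17.1334,0.13037
male,130,-1.7058,17.1804,0.13075
male,131,-1.7104,17.2276,0.13112
male,132,-1.715,17.275,0.1315
male,133,-1.7196,17.3226,0.13188
male,134,-1.7242,17.3704,0.13225
male,135,-1.7288,17.4184,0.13262
male,136,-1.7333,17.4667,0.133
male,137,-1.7379,17.5151,0.13338
male,138,-1.7425,17.5637,0.13375
male,139,-1.7471,17.6126,0.13412
male,140,-1.7517,17.6617,0.1345
male,141,-1.7563,17.7109,0.13488
male,142,-1.7608,17.7604,0.13525
male,143,-1.7654,17.8101,0.13562
male,144,-1.77,17.86,0.136
male,145,-1.7746,17.9101,0.13638
male,146,-1.7792,17.9604,0.13675
male,147,-1.7837,18.0109,0.13712
male,148,-1.7883,18.0617,0.1375
male,149,-1.7929,18.1126,0.13788
male,150,-1.7975,18.1638,0.13825
male,151,-1.8021,18.2151,0.13862
male,152,-1.8067,18.2667,0.139
male,153,-1.8113,18.3184,0.13938
male,154,-1.8158,18.3704,0.13975
male,155,-1.8204,18.4226,0.14012
male,156,-1.825,18.475,0.1405
male,157,-1.8296,18.5276,0.14088
male,158,-1.8342,18.5804,0.14125
male,159,-1.8388,18.6334,0.14162
male,160,-1.8433,18.6867,0.142
male,161,-1.8479,18.7401,0.14238
male,162,-1.8525,18.7937,0.14275
male,163,-1.8571,18.8476,0.14312
male,164,-1.8617,18.9017,0.1435
male,165,-1.8662,18.9559,0.14388
male,166,-1.8708,19.0104,0.14425
male,167,-1.8754,19.0651,0.14462
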