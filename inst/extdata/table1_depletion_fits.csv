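cultivar,treatment,replicate,a,b,c,r_squared
Rougui,Mg_control,1,0.0193,-0.8309,40.243,0.9744
Rougui,Mg_control,2,0.0358,-1.1029,40.817,0.9799
Rougui,Mg_control,3,0.0150,-0.8598,41.448,0.9454
Rougui,Mg_All,1,0.0285,-1.0544,41.384,0.9536
Rougui,Mg_All,2,0.0201,-0.8050,40.289,0.9719
Rougui,Mg_All,3,0.0144,-0.6315,39.163,0.9710
Rougui,Mg_N,1,0.0300,-1.0287,35.260,0.9466
Rougui,Mg_N,2,0.0528,-1.3075,35.470,0.9320
Rougui,Mg_N,3,0.0574,-1.4664,35.737,0.9638
Rougui,Mg_P,1,0.0858,-1.9995,37.448,0.9507
Rougui,Mg_P,2,0.0695,-1.4634,33.778,0.9696
Rougui,Mg_P,3,0.0408,-1.0898,33.227,0.9518
Rougui,Mg_K,1,0.1003,-2.2019,39.482,0.9659
Rougui,Mg_K,2,0.0898,-2.0375,38.301,0.9572
Rougui,Mg_K,3,0.0781,-1.8894,38.561,0.9541
Rougui,Mg_other,1,0.0261,-0.8686,38.800,0.9503
Rougui,Mg_other,2,0.0198,-0.8696,39.118,0.9535
Rougui,Mg_other,3,0.0458,-1.2589,39.884,0.9548
Rougui,Mg_Mg,1,0.0584,-1.7316,37.554,0.9551
Rougui,Mg_Mg,2,0.0609,-1.8390,38.581,0.9581
Rougui,Mg_Mg,3,0.0475,-1.6286,37.780,0.9692
Shuixian,Mg_control,1,0.0069,-0.2439,39.694,0.9798
Shuixian,Mg_control,2,0.0101,-0.5420,42.105,0.9549
Shuixian,Mg_control,3,0.0092,-0.4046,39.962,0.9946
Shuixian,Mg_All,1,0.0166,-0.4589,40.484,0.9961
Shuixian,Mg_All,2,0.0116,-0.3326,40.376,0.9209
Shuixian,Mg_All,3,0.0100,-0.4064,40.968,0.9792
Shuixian,Mg_N,1,0.1242,-2.837,37.746,0.9795
Shuixian,Mg_N,2,0.0927,-2.406,38.063,0.9878
Shuixian,Mg_N,3,0.097,-2.4888,38.323,0.9855
Shuixian,Mg_P,1,0.0809,-2.3360,38.843,0.9874
Shuixian,Mg_P,2,0.0718,-2.1898,38.092,0.9555
Shuixian,Mg_P,3,0.0846,-2.3411,38.275,0.9697
Shuixian,Mg_K,1,0.0747,-2.2755,39.551,0.9465
Shuixian,Mg_K,2,0.0776,-2.2964,39.252,0.9382
Shuixian,Mg_K,3,0.0655,-2.1466,39.167,0.9497
Shuixian,Mg_other,1,0.0082,-0.5152,39.718,0.9271
Shuixian,Mg_other,2,0.0206,-0.6038,39.524,0.9610
Shuixian,Mg_other,3,0.0125,-0.6367,40.097,0.9975
Shuixian,Mg_Mg,1,0.1192,-2.9243,38.356,0.9797
Shuixian,Mg_Mg,2,0.1287,-3.1176,38.757,0.9878
Shuixian,Mg_Mg,3,0.1056,-2.8264,39.028,0.9862
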