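T_a,T_mrt,VP,v,PET_ref
35.577422,50.379976,5.453278,0.597849,38.868447
8.129606,29.987566,8.776425,2.906465,3.534521
26.862910,38.177088,26.210153,2.680953,22.091847
16.475742,31.253462,16.145086,1.330592,14.780717
30.366454,45.781980,14.673590,2.934084,24.056438
27.227392,38.234199,17.351821,0.722373,28.249217
22.174208,21.653290,8.212220,1.083672,15.190441
19.161220,22.241641,13.431054,1.981400,12.189714
11.560500,25.398106,11.603682,2.868117,5.760551
31.219811,37.583083,29.428351,0.739634,33.254825
36.302557,36.504147,23.200615,0.890396,34.783096
9.486690,37.784829,4.852366,2.457884,6.329094
35.940995,54.688295,9.346348,1.594426,36.776181
25.977216,49.512921,11.817354,0.811513,31.094412
19.959504,48.144264,7.740730,0.377273,30.156703
26.897345,38.269104,10.203311,0.743094,26.421704
32.330251,51.962435,17.172485,1.587811,34.324844
35.992910,49.982083,7.356461,1.982767,32.593661
12.679062,34.356873,11.313845,1.953182,10.291274
22.328472,34.495879,14.866460,0.527659,23.940738
7.898873,32.567909,8.596077,2.891329,3.890813
17.543026,37.391273,4.867732,1.861353,13.380643
8.387949,10.628630,3.595614,0.777049,3.305299
25.470685,28.407350,27.464212,2.773719,19.064763
32.897534,36.102363,18.257862,2.993005,24.539759
17.854517,21.256681,13.717206,1.848709,11.394341
15.937297,13.572176,11.406590,0.506758,11.524919
11.882594,24.002027,8.781986,2.212032,6.225675
16.265757,17.223776,13.934867,2.448445,8.574444
37.288772,43.537089,5.556841,2.595605,28.726121
25.566953,36.039540,28.476212,1.861809,23.208379
31.485852,36.513969,3.306154,0.949798,26.394935
10.733024,39.496818,8.527577,1.458271,11.549572
30.068032,47.433263,5.407035,0.345449,35.961829
9.724517,5.515601,10.555276,2.203381,1.308160
36.835892,40.405705,18.129705,1.170397,34.940842
34.242950,41.198666,8.154849,2.780667,24.891373
37.563709,62.396846,18.268902,2.181935,42.199867
16.203030,25.669076,4.931171,1.118801,11.825222
34.245524,43.147287,4.338677,2.750852,24.405504
12.929867,15.988086,4.461528,0.445586,9.853355
15.761645,31.165301,13.501410,1.731609,12.581669
28.801819,45.048516,13.001500,1.159371,29.086841
30.948045,36.864883,26.758567,2.946695,25.693230
7.693694,23.236674,7.017223,0.950992,6.547508
37.911985,58.062999,8.173295,1.461547,40.431603
17.956584,23.357657,8.965753,1.864233,11.010968
25.991595,47.839384,19.962695,0.633198,33.337752
5.945654,28.370183,3.338611,1.457936,4.087110
33.420802,40.536211,15.521963,1.700266,29.525369
35.977466,44.273894,7.534234,2.448712,28.715086
5.154023,20.438951,4.373802,1.872794,0.426770
15.201216,27.192869,9.122236,0.205116,19.047957
34.334440,61.938708,21.970670,2.247099,39.651862
20.544349,37.552516,14.196020,0.164132,28.890105
37.942471,60.112514,3.210437,2.531081,35.598882
12.324015,29.371205,12.733841,2.120128,8.713762
10.088894,16.206019,8.843502,0.952420,6.323453
33.340508,57.670287,19.962182,2.391708,35.602124
20.649094,29.573469,17.197380,0.658746,20.042862
22.617482,47.929471,24.447216,1.819750,24.177082
18.817532,39.443428,7.396444,0.788884,20.128318
15.017328,11.363796,14.059288,0.233217,12.195114
24.598183,29.563377,4.891515,1.132743,18.228135
28.747823,25.163519,15.700314,1.451036,20.512518
24.033118,22.409502,8.957917,1.244238,16.227837
33.590388,30.074042,6.045228,2.175191,21.413558
35.477136,53.169060,3.871797,0.880305,38.063881
32.830699,29.588674,9.445188,1.533609,23.598157
15.207802,11.777834,5.940297,1.653096,6.369604
15.714977,24.912065,9.166680,1.458897,10.913710
18.310358,44.828987,8.118876,1.211547,19.202702
36.141696,32.152971,22.990891,2.527658,29.308306
35.885049,51.302536,24.611244,2.512161,36.719995
20.811184,33.417792,10.257253,2.096950,14.955190
12.055462,41.395368,8.780055,0.687557,17.822883
20.817027,31.595584,14.095457,1.032055,18.434396
29.817645,26.277411,28.999540,2.964471,21.716429
30.925089,60.027980,22.722290,1.992590,36.547451
26.679698,24.938519,4.849518,1.228360,17.900939
15.276752,21.784938,7.074738,2.013945,8.161609
26.983280,56.403568,29.966852,2.069770,32.785945
6.757479,20.413024,7.747705,2.055723,1.859467
12.087088,32.048281,12.292427,0.613518,15.367218
36.877852,66.201648,20.002169,1.546695,46.265137
13.531904,18.504961,10.188944,0.166122,14.720542
35.760509,33.690615,22.955447,1.975276,30.503104
25.050365,34.394969,4.965945,2.259326,16.580757
31.656566,44.427312,29.262315,1.554093,33.707446
34.407023,57.575040,25.730443,2.940993,36.986925
27.888169,57.449512,12.024687,2.471386,26.918172
6.255006,17.465255,3.040703,2.149431,-0.307513
32.380449,57.948961,16.824604,1.000329,40.214433
35.319088,50.375812,20.551244,2.149724,35.460868
28.296518,24.175566,29.356462,2.884315,20.345390
24.016162,24.222950,25.815753,0.131518,25.510046
25.361825,46.187349,6.770356,1.137538,25.334780
32.274001,32.500525,28.842290,2.179362,27.910575
16.575262,20.288279,9.492063,0.283363,15.734237
21.891790,50.550950,24.814839,0.811076,31.196521
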