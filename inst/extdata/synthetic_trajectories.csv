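traj_id,frame,x_um,y_um,true_mode,true_D
1,0,0.0034,-0.0342,confined,0.2228
1,1,0.1626,-0.253,confined,0.2228
1,2,-0.2677,-0.153,confined,0.2228
1,3,-0.2968,0.0926,confined,0.2228
1,4,-0.3632,0.1972,confined,0.2228
1,5,-0.3302,0.1861,confined,0.2228
1,6,-0.301,-0.0849,confined,0.2228
1,7,-0.0367,-0.4069,confined,0.2228
1,8,-0.2215,-0.0756,confined,0.2228
1,9,-0.3668,0.0116,confined,0.2228
1,10,-0.3056,0.2198,confined,0.2228
1,11,-0.0994,0.0953,confined,0.2228
1,12,-0.1772,-0.0194,confined,0.2228
1,13,-0.2244,0.1697,confined,0.2228
1,14,-0.2287,0.2491,confined,0.2228
1,15,-0.174,0.1282,confined,0.2228
1,16,-0.0437,0.2127,confined,0.2228
1,17,-0.0471,0.124,confined,0.2228
1,18,0.272,0.0449,confined,0.2228
1,19,0.0638,-0.1461,confined,0.2228
1,20,0.0463,-0.4216,confined,0.2228
1,21,0.1194,-0.295,confined,0.2228
1,22,0.2985,-0.1357,confined,0.2228
1,23,0.2737,-0.0345,confined,0.2228
1,24,0.093,0.2414,confined,0.2228
1,25,0.0926,0.3401,confined,0.2228
1,26,-0.0559,0.3951,confined,0.2228
1,27,-0.0383,0.2721,confined,0.2228
1,28,0.1315,0.3221,confined,0.2228
1,29,-0.0815,0.384,confined,0.2228
1,30,-0.0921,0.0795,confined,0.2228
1,31,-0.0457,0.2623,confined,0.2228
1,32,0.0792,-0.0068,confined,0.2228
1,33,0.1982,-0.1462,confined,0.2228
1,34,0.283,-0.0523,confined,0.2228
1,35,0.0528,-0.0682,confined,0.2228
1,36,0.0237,0.0416,confined,0.2228
1,37,-0.368,-0.1807,confined,0.2228
1,38,-0.2694,-0.1189,confined,0.2228
1,39,-0.2022,-0.1511,confined,0.2228
2,0,-0.0196,0.0075,brownian,0.0893
2,1,-0.1113,0.3572,brownian,0.0893
2,2,-0.1777,0.5055,brownian,0.0893
2,3,-0.2239,0.6555,brownian,0.0893
2,4,-0.2662,0.7171,brownian,0.0893
2,5,-0.1573,0.7073,brownian,0.0893
2,6,-0.1811,0.9516,brownian,0.0893
2,7,0.0098,1.0879,brownian,0.0893
2,8,0.0108,1.0802,brownian,0.0893
2,9,-0.1388,1.012,brownian,0.0893
2,10,-0.3411,0.9855,brownian,0.0893
2,11,-0.295,0.9338,brownian,0.0893
2,12,-0.2595,1.0207,brownian,0.0893
2,13,-0.4401,1.0805,brownian,0.0893
2,14,-0.6837,1.2304,brownian,0.0893
2,15,-0.8528,0.9645,brownian,0.0893
2,16,-1.0589,0.7849,brownian,0.0893
2,17,-1.0221,0.5724,brownian,0.0893
2,18,-0.7879,0.4826,brownian,0.0893
2,19,-0.837,0.5467,brownian,0.0893
2,20,-0.8051,0.5611,brownian,0.0893
2,21,-0.7626,0.3925,brownian,0.0893
2,22,-0.5726,0.1502,brownian,0.0893
2,23,-0.5398,0.2081,brownian,0.0893
2,24,-0.5172,0.3667,brownian,0.0893
2,25,-0.38,0.325,brownian,0.0893
2,26,-0.2898,0.4055,brownian,0.0893
2,27,-0.4147,0.2654,brownian,0.0893
2,28,-0.1572,0.3586,brownian,0.0893
2,29,0.0138,0.1964,brownian,0.0893
2,30,0.106,0.2174,brownian,0.0893
2,31,0.302,0.232,brownian,0.0893
2,32,0.3141,0.2017,brownian,0.0893
2,33,0.4103,0.3811,brownian,0.0893
2,34,0.2805,0.2579,brownian,0.0893
2,35,0.3689,0.2214,brownian,0.0893
2,36,0.7063,0.0389,brownian,0.0893
2,37,0.7966,0.0745,brownian,0.0893
2,38,0.6857,-0.1182,brownian,0.0893
2,39,0.8253,-0.0461,brownian,0.0893
3,0,0.0216,-0.0356,confined,0.2533
3,1,-0.0301,0.2352,confined,0.2533
3,2,0.0572,0.2063,confined,0.2533
3,3,-0.0633,0.0591,confined,0.2533
3,4,-0.1715,0.1415,confined,0.2533
3,5,-0.1531,0.059,confined,0.2533
3,6,-0.2744,0.0764,confined,0.2533
3,7,-0.2471,-0.0682,confined,0.2533
3,8,-0.0147,-0.1894,confined,0.2533
3,9,-0.0328,0.0286,confined,0.2533
3,10,0.192,0.0696,confined,0.2533
3,11,0.0623,-0.0138,confined,0.2533
3,12,-0.2881,0.1247,confined,0.2533
3,13,-0.2655,0.1743,confined,0.2533
3,14,-0.2634,-0.0479,confined,0.2533
3,15,-0.0448,0.1754,confined,0.2533
3,16,-0.1032,0.1077,confined,0.2533
3,17,-0.0638,0.0122,confined,0.2533
3,18,-0.0205,-0.3206,confined,0.2533
3,19,0.0096,-0.2159,confined,0.2533
3,20,0.0072,-0.2943,confined,0.2533
3,21,0.0116,-0.0196,confined,0.2533
3,22,0.1433,-0.2706,confined,0.2533
3,23,0.1498,-0.1611,confined,0.2533
3,24,0.1562,-0.3574,confined,0.2533
3,25,0.2729,-0.0652,confined,0.2533
3,26,0.2366,0.0871,confined,0.2533
3,27,0.2244,-0.2542,confined,0.2533
3,28,0.0996,-0.0408,confined,0.2533
3,29,-0.2513,0.1671,confined,0.2533
3,30,-0.1155,-0.034,confined,0.2533
3,31,-0.1548,-0.377,confined,0.2533
3,32,0.0562,-0.2348,confined,0.2533
3,33,-0.1083,-0.1131,confined,0.2533
3,34,-0.1074,-0.2416,confined,0.2533
3,35,0.091,-0.1609,confined,0.2533
3,36,0.1884,-0.2115,confined,0.2533
3,37,-0.1428,-0.3916,confined,0.2533
3,38,-0.2133,-0.0649,confined,0.2533
3,39,-0.1576,0.3435,confined,0.2533
4,0,0.0052,-0.0575,confined,0.0429
4,1,-0.123,-0.0461,confined,0.0429
4,2,-0.0774,0.0478,confined,0.0429
4,3,-0.1064,0.1802,confined,0.0429
4,4,7e-04,0.0382,confined,0.0429
4,5,-0.1189,0.0163,confined,0.0429
4,6,-0.1734,0.0821,confined,0.0429
4,7,-0.1098,-0.0674,confined,0.0429
4,8,-0.1621,0.0178,confined,0.0429
4,9,-0.0873,-0.0153,confined,0.0429
4,10,-0.1438,0.0529,confined,0.0429
4,11,0.0099,0.0354,confined,0.0429
4,12,-0.0379,-0.0145,confined,0.0429
4,13,0.0162,-0.0749,confined,0.0429
4,14,-0.1268,-0.0637,confined,0.0429
4,15,-0.0809,-0.0312,confined,0.0429
4,16,-0.0427,-0.0351,confined,0.0429
4,17,-0.036,0.1135,confined,0.0429
4,18,-0.0383,-0.0352,confined,0.0429
4,19,0.0719,0.1549,confined,0.0429
4,20,-0.088,-0.1228,confined,0.0429
4,21,-0.134,-0.0605,confined,0.0429
4,22,-0.0546,0.1123,confined,0.0429
4,23,-0.011,0.0271,confined,0.0429
4,24,0.1585,-0.0493,confined,0.0429
4,25,0.1843,-0.0099,confined,0.0429
4,26,0.1163,-0.082,confined,0.0429
4,27,0.017,-0.0995,confined,0.0429
4,28,0.0128,-0.088,confined,0.0429
4,29,-0.0469,-0.1572,confined,0.0429
4,30,0.0721,-0.0897,confined,0.0429
4,31,0.0925,-0.13,confined,0.0429
4,32,-0.0144,-0.0778,confined,0.0429
4,33,-0.18,-0.0408,confined,0.0429
4,34,-0.1744,-0.0442,confined,0.0429
4,35,0.0375,-0.1176,confined,0.0429
4,36,0.0265,-0.1883,confined,0.0429
4,37,0.1196,-0.0913,confined,0.0429
4,38,0.0782,-0.0355,confined,0.0429
4,39,0.0177,0.0657,confined,0.0429
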