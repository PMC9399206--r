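"metric","depth_perception","bimanual_dexterity","efficiency","autonomy","total"
"Time",0.0546,-0.5241,-0.5874,-0.5885,-0.4959
"BD",0.166,0.6235,0.4522,0.1771,-0.0841
"ROB",0.2162,0.1337,-0.1921,-0.2467,-0.2485
"RPLB",0.0205,0.0705,-0.1662,0.2177,0.2527
"ADB",0.1747,0.1474,0.0352,-0.0578,-0.1255
"ADBO",-0.153,-0.1293,0.1831,-0.2898,0.1831
"R-PL",0.1949,-0.5185,-0.447,-0.1432,-0.4939
"R-V",-0.225,-0.1402,0.5657,0.6239,0.4786
"R-A",-0.1783,0.1266,0.6582,0.5891,0.5126
"R-J",0.2931,-0.23,-0.0095,-0.0875,0.5095
"R-VR",0.0577,0.0318,-0.0846,0.2967,0.2741
"R-Idle",0.2133,0.1505,0.1333,0.018,-0.2605
"R-Low",0.1268,-0.0619,0.5082,0.5744,0.0957
"R-Middle",0.1487,-0.1485,0.4859,0.4488,0.2485
"R-High",-0.2741,0.1663,0.6549,0.6373,-0.1487
"R-Very_high",-0.0677,0.2577,0.0398,-0.2644,-0.1815
"R-DPL",0.536,0.2627,0.595,-0.1428,-0.1757
"R-DV",0.6242,0.0317,0.4866,0.2387,-0.215
"R-NOC",0.0085,0.0294,-0.1766,-0.1471,0.1851
"R-AGRA",0.0759,-0.1038,0.1352,0.142,-0.0957
"R-Roll",-0.0387,-0.0048,-0.1281,-0.0141,0.1304
"R-Pitch",0.1402,0.0215,0.0085,0.1575,-0.2319
"R-Yaw",0.2611,-0.2559,-0.0676,-0.0471,-0.2588
"R-AL-Roll",0.2675,0.541,0.099,-0.2124,-0.1959
"R-AL-PitchYaw",-0.0206,0.1498,-0.1241,0.2839,0.2872
"R-WA",0.041,-0.1926,-0.1565,-0.1338,-0.2624
"R-AIT",0.1394,0.2186,0.2816,-0.2439,-0.2407
"R-Close",0.0281,0.1939,-0.2333,0.1538,0.2756
"R-Near",0.061,-0.2968,-0.2099,-0.1688,-0.2937
"R-Far",0.223,-0.0471,-0.2053,0.1103,0.1391
"L-PL",-0.1499,-0.443,-0.68,0.2596,-0.5252
"L-V",-0.2229,-0.1485,0.4905,0.5572,0.6775
"L-A",-0.1042,-0.1716,0.0589,0.0847,0.1766
"L-J",-0.166,-0.0386,0.0975,0.1658,-0.2523
"L-VR",-0.1279,0.2656,0.1831,-0.065,-0.0686
"L-Idle",0.1469,0.2405,-0.6242,-0.5077,0.2168
"L-Low",0.242,0.2976,-0.0758,-0.1005,0.261
"L-Middle",0.1907,-0.0451,0.6107,0.5847,0.1722
"L-High",-0.0437,0.0408,-0.1006,0.2857,0.1779
"L-Very_high",-0.1029,0.077,-0.1588,-0.0827,-0.2382
"L-DPL",0.6661,0.1836,0.5065,0.0876,0.2702
"L-DV",0.6637,0.2405,0.5671,-0.1255,-0.136
"L-NOC",-0.1749,-0.0377,-0.2943,-0.08,-0.1431
"L-AGRA",-0.2153,-0.2339,-0.2236,-0.298,0.2829
"L-Roll",0.2156,0.248,0.198,0.0594,-0.1591
"L-Pitch",0.2782,-0.1881,-0.1458,0.0837,-0.0154
"L-Yaw",0.1702,-0.2306,0.2259,0.1594,-0.0973
"L-AL-Roll",0.1944,0.5913,-0.1124,-0.1925,-0.1416
"L-AL-PitchYaw",-0.2681,0.5187,0.5785,-0.2103,0.2806
"L-WA",-0.1743,-0.1378,0.0294,0.0026,-0.0067
"L-AIT",-0.1214,0.2713,-0.0134,0.0155,0.1984
"L-Close",0.1527,-0.1148,0.0771,-0.062,-0.0659
"L-Near",0.031,-0.2713,0.0507,0.2969,-0.2721
"L-Far",0.0873,-0.0661,-0.0116,0.1717,-0.0036
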