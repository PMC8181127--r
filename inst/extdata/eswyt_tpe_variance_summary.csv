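year,eswyt,e_tpe,g,g_tpe,g_e_tpe,r_e,sb_er,residual,v_z,h2,r,cr,dr
2001,22,4.0036,0.0783,0,0.1008,0.01097,0.0731,0.2612,0.10,0.77,,,0.25
2005,26,0.7807,0.0312,0.01168,0.1298,0.00358,0.05208,0.2705,0.07,0.62,0.42,0.41,0.16
2006,27,1.5786,0.0318,0,0.1981,0.0332,0.09257,0.201,0.05,0.60,0.55,0.49,0.14
2007,28,1.0941,0.0222,0.03947,0.1228,0.01797,0.03856,0.1703,0.08,0.79,0.47,0.50,0.22
2008,29,3.3262,0.0126,0,0.1749,0.02885,0.07857,0.09306,0.03,0.41,0.41,0.36,0.07
2009,30,0.5347,0.0169,0.00117,0.1189,0.00566,0.02894,0.108,0.03,0.59,0.54,0.49,0.10
2010,31,0.731,0.0303,0.01759,0.1847,0.00575,0.02445,0.2474,0.07,0.73,,,0.19
2011,32,2.4407,0.0443,0.00755,0.1826,0,0.07045,0.2638,0.06,0.80,0.70,0.57,0.20
2012,33,1.1673,0.0392,0.01684,0.2073,0.00638,0.03984,0.1878,0.07,0.80,0.51,0.47,0.21
2013,34,2.1213,0.0163,0.02693,0.28,0.05409,0.04214,0.2104,0.07,0.66,0.90,0.89,0.17
2014,35,0.6268,0.0344,0.0083,0.1122,0.00852,0.04085,0.1364,0.05,0.79,0.54,0.48,0.18
2015,36,0.632,0.0242,0.01403,0.1412,0.00112,0.03473,0.1841,0.06,0.68,0.28,0.24,0.16
2016,37,2.2357,0.022,0.00963,0.1416,0.02188,0.03929,0.2225,0.04,0.70,0.56,0.52,0.15
Average,,1.6364,0.0311,0.0118,0.1611,0.0152,0.0504,0.1967,0.06,0.72,0.53,0.50,0.17
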