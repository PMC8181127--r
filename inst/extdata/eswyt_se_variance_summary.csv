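year,eswyt,g,g_se,r_sb,r_sb_se,residual,v_z,h2,dr
2001,22,0.4496,,0.15857,,0.40665,0.65,,0.56
2005,26,0.18293,0,,0.09811,0.37411,0.28,0.66,0.35
2006,27,0.17917,0.06219,,0.36282,0.2721,0.28,0.64,0.34
2007,28,0.05154,0.0706,,0.14638,0.10379,0.08,0.63,0.18
2008,29,0.02129,0.05575,,0.12668,0.07947,0.04,0.53,0.11
2009,30,0.03146,0,,0.05682,0.10463,0.05,0.64,0.14
2010,31,0.1926,,0.00927,,0.18273,0.28,,0.36
2011,32,0.03193,0.02453,,0.06503,0.08938,0.06,0.58,0.14
2012,33,0.09795,0.06943,,0.09896,0.04184,0.14,0.68,0.26
2013,34,0.02496,0.06268,,0.08571,0.08912,0.05,0.48,0.11
2014,35,0.03325,0.02416,,0.08932,0.07997,0.05,0.67,0.15
2015,36,0.02962,0.07571,,0.08995,0.11402,0.06,0.53,0.12
2016,37,0.03387,0.04699,,0.06042,0.05311,0.05,0.65,0.15
Mean,,0.1046,0.0447,0.0839,0.1164,0.1531,0.14,0.73,0.28
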