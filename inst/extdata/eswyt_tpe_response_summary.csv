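year,tpe,v_z,h2_tpe,r,cr,dr
2001,1,0.14,0.3,,,0.11
2005,1,0.11,0.54,0.65,0.72,0.18
2006,1,0.07,0.41,0.38,0.48,0.11
2007,1,0.06,0.57,0.39,0.41,0.14
2008,1,0.05,0.22,0.9,1.55,0.05
2009,1,0.04,0.46,0.42,0.50,0.1
2010,1,0.14,0.56,,,0.21
2011,1,0.12,0.69,0.99,0.83,0.24
2012,1,0.10,0.66,0.45,0.45,0.21
2013,1,0.14,0.64,0.82,0.71,0.24
2014,1,0.08,0.72,0.54,0.52,0.21
2015,1,0.09,0.66,0.32,0.29,0.2
2016,1,0.09,0.62,0.53,0.54,0.18
Mean,1,0.1,0.54,0.58,0.64,0.17
2001,2,0.15,0.67,,,0.26
2005,2,0.06,0.64,0.57,0.58,0.16
2006,2,0.2,0.22,0.99,1.70,0.1
2007,2,0.72,0.44,0.84,1.01,0.37
2008,2,0.16,0.2,0.06,0.10,0.08
2009,2,0.16,0.2,0.99,1.79,0.08
2010,2,0.08,0.25,,,0.07
2011,2,0.08,0.14,0.45,0.92,0.04
2012,2,0.09,0.38,0.16,0.21,0.11
2013,2,0.12,0.06,0.99,2.86,0.02
2014,2,0.11,0.49,0.49,0.58,0.16
2015,2,0.2,0.65,0.03,0.03,0.29
2016,2,0.08,0.18,0.29,0.55,0.05
Mean,2,0.18,0.39,0.60,0.94,0.16
2001,3,0.09,0.34,,,0.1
2005,3,0.10,0.2,-0.09,-0.16,0.06
2006,3,0.05,0,,,0.00
2007,3,0.10,0.58,-0.04,-0.04,0.18
2008,3,0.05,0,,,0.00
2009,3,0.06,0.33,0.14,0.20,0.08
2010,3,0.08,0.46,,,0.13
2011,3,0.09,0.63,0.63,0.61,0.19
2012,3,0.11,0.64,0.59,0.61,0.21
2013,3,0.08,0.18,0.7,1.13,0.05
2014,3,0.08,0.53,0.46,0.52,0.15
2015,3,0.10,0.17,0.13,0.23,0.05
2016,3,0.07,0.42,0.55,0.68,0.11
Mean,3,0.08,0.38,0.34,0.42,0.11
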