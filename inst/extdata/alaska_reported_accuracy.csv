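year,afs_ha,product,p_pct,ce,oe,te
2000,304631.50,mcd45a1_c51,6.79,0.037,0.935,0.938
2000,304631.50,mcd64a1_c6,0.00,0.000,1.000,1.000
2001,88658.25,fire_cci_51,1.23,0.303,0.991,0.995
2001,88658.25,mcd45a1_c51,0.40,1.000,1.000,1.004
2001,88658.25,mcd64a1_c6,6.64,1.000,1.000,1.066
2002,856081.50,fire_cci_51,66.06,0.095,0.402,0.465
2002,856081.50,mcd45a1_c51,12.30,0.071,0.886,0.895
2002,856081.50,mcd64a1_c6,66.44,0.166,0.446,0.556
2003,241061.25,fire_cci_51,75.92,0.093,0.311,0.382
2003,241061.25,mcd45a1_c51,49.76,0.113,0.558,0.614
2003,241061.25,mcd64a1_c6,83.36,0.386,0.488,0.810
2004,2712368.00,fire_cci_51,71.02,0.064,0.335,0.380
2004,2712368.00,mcd45a1_c51,31.88,0.053,0.698,0.715
2004,2712368.00,mcd64a1_c6,74.73,0.174,0.383,0.513
2005,1896684.75,fire_cci_41,22.23,0.056,0.790,0.802
2005,1896684.75,fire_cci_51,58.17,0.089,0.470,0.522
2005,1896684.75,mcd45a1_c51,30.40,0.069,0.717,0.738
2005,1896684.75,mcd64a1_c6,77.11,0.151,0.345,0.461
2006,108509.00,fire_cci_41,52.42,0.097,0.527,0.578
2006,108509.00,fire_cci_51,45.83,0.147,0.609,0.676
2006,108509.00,mcd45a1_c51,28.18,0.232,0.784,0.849
2006,108509.00,mcd64a1_c6,29.60,0.424,0.830,0.956
2007,263894.00,fire_cci_41,41.26,0.188,0.665,0.743
2007,263894.00,fire_cci_51,82.46,0.155,0.303,0.431
2007,263894.00,mcd45a1_c51,21.12,0.107,0.811,0.834
2007,263894.00,mcd64a1_c6,76.64,0.316,0.476,0.718
2008,39164.50,fire_cci_41,54.20,0.124,0.525,0.592
2008,39164.50,fire_cci_51,79.43,0.292,0.438,0.670
2008,39164.50,mcd45a1_c51,23.74,0.234,0.818,0.874
2008,39164.50,mcd64a1_c6,67.49,0.573,0.712,1.099
2009,1198139.50,fire_cci_41,58.17,0.034,0.438,0.458
2009,1198139.50,fire_cci_51,80.36,0.062,0.247,0.297
2009,1198139.50,mcd45a1_c51,29.78,0.075,0.725,0.747
2009,1198139.50,mcd64a1_c6,56.17,0.094,0.491,0.544
2010,46494.00,fire_cci_41,22.22,0.077,0.795,0.812
2010,46494.00,fire_cci_51,61.34,0.110,0.454,0.521
2010,46494.00,mcd45a1_c51,30.19,0.125,0.736,0.774
2010,46494.00,mcd64a1_c6,38.51,0.214,0.697,0.779
2011,122486.75,fire_cci_41,3.91,0.079,0.964,0.967
2011,122486.75,fire_cci_51,59.29,0.230,0.543,0.679
2011,122486.75,mcd45a1_c51,11.85,0.116,0.895,0.909
2011,122486.75,mcd64a1_c6,12.71,0.221,0.901,0.929
2012,111290.25,fire_cci_51,58.97,0.118,0.480,0.550
2012,111290.25,mcd45a1_c51,27.14,0.113,0.759,0.790
2012,111290.25,mcd64a1_c6,88.14,0.516,0.574,1.029
2013,532279.00,fire_cci_51,63.72,0.055,0.398,0.433
2013,532279.00,mcd45a1_c51,44.37,0.049,0.578,0.600
2013,532279.00,mcd64a1_c6,47.23,0.219,0.631,0.734
2014,117193.00,fire_cci_51,69.59,0.065,0.350,0.395
2014,117193.00,mcd45a1_c51,48.26,0.065,0.549,0.580
2014,117193.00,mcd64a1_c6,51.04,0.238,0.611,0.732
2015,2073041.25,fire_cci_51,61.02,0.041,0.415,0.440
2015,2073041.25,mcd45a1_c51,24.38,0.038,0.766,0.775
2015,2073041.25,mcd64a1_c6,61.69,0.155,0.478,0.574
2016,201944.75,fire_cci_51,58.92,0.101,0.470,0.530
2016,201944.75,mcd45a1_c51,30.75,0.055,0.709,0.726
2016,201944.75,mcd64a1_c6,55.52,0.203,0.558,0.671
2017,292026.50,fire_cci_51,65.17,0.073,0.396,0.444
2017,292026.50,mcd64a1_c6,52.91,0.111,0.529,0.588
all_years,11623847.75,fire_cci_41,34.53,0.059,0.675,0.695
all_years,11623847.75,fire_cci_51,65.89,0.075,0.390,0.439
all_years,11623847.75,mcd45a1_c51,28.11,0.066,0.737,0.756
all_years,11623847.75,mcd64a1_c6,63.22,0.178,0.480,0.593
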