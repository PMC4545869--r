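probe_id,crude_beta,crude_p,adjusted_beta,adjusted_p,pct_diff_beta
cg00155310,2.24,0.00066,2.24,0.0011,-0.26
cg00528600,1.66,0.0038,1.68,0.0043,1.11
cg00854799,1.23,0.0062,1.25,0.0067,1.29
cg01097406,0.25,0.0050,0.27,0.0042,5.08
cg01190915,2.43,0.00020,2.61,0.00011,7.49
cg01203365,-1.25,0.0051,-1.19,0.0087,-4.59
cg01777765,-1.51,0.0030,-1.69,0.0015,11.76
cg01847596,-2.62,0.0015,-2.65,0.0019,1.49
cg02201050,2.08,0.0012,2.10,0.0017,0.87
cg02366798,0.84,0.0097,0.85,0.014,0.46
cg02775369,-1.55,0.00072,-1.53,0.0011,-1.37
cg03131171,-1.21,0.0064,-1.28,0.0049,5.47
cg03468115,1.68,0.0017,1.58,0.0052,-5.88
cg03553407,1.54,0.00037,1.50,0.00060,-2.44
cg04085542,1.00,0.00033,0.95,0.00094,-5.15
cg04162999,0.92,0.030,1.05,0.016,14.72
cg04342090,-1.55,0.0086,-1.46,0.014,-5.58
cg04775941,-1.67,0.020,-1.54,0.034,-7.5
cg04798929,2.20,0.0024,2.14,0.0034,-2.98
cg04983687,-1.18,0.000010,-1.43,0.0000017,21.45
cg05048002,-1.91,0.00074,-1.75,0.0036,-8.1
cg05104993,2.89,0.0018,3.18,0.0012,10.1
cg05560165,1.37,0.0011,1.55,0.00062,13.84
cg05652668,-1.15,0.00068,-1.27,0.00031,10.57
cg06816054,-1.37,0.0081,-1.49,0.0068,9.25
cg06824199,-2.11,0.000029,-2.45,0.000011,16.35
cg06851336,-1.78,0.00099,-1.76,0.0011,-0.86
cg07765167,-2.47,0.000065,-2.52,0.000095,1.94
cg07880854,1.21,0.014,1.43,0.0070,18.16
cg07908654,-1.67,0.000013,-1.80,0.0000099,7.96
cg07970948,-1.26,0.000027,-1.42,0.000014,12.22
cg08397758,0.84,0.043,1.90,0.0032,125.56
cg09249800,-1.14,0.000016,-1.27,0.0000094,11.06
cg09332506,-1.97,0.0000097,-2.10,0.0000078,6.38
cg09570585,0.85,0.064,0.82,0.082,-3.88
cg09635874,1.96,0.00037,1.90,0.0010,-3.11
cg10016610,-0.57,0.098,-0.63,0.085,9.8
cg11182893,1.81,0.00032,1.64,0.0015,-9.47
cg11372831,2.62,0.00018,2.63,0.00029,0.2
cg11569718,-1.54,0.011,-1.44,0.021,-6.64
cg12578575,-0.58,0.012,-0.59,0.014,1.49
cg12819826,-1.90,0.000087,-1.93,0.00029,1.67
cg12819873,-2.36,0.0000045,-2.47,0.0000051,4.97
cg13168187,1.65,0.0024,2.79,0.000043,69.09
cg13197551,-1.84,0.000062,-1.77,0.00016,-3.49
cg13233042,-1.64,0.000032,-1.74,0.000031,6.21
cg13713293,-1.43,0.00039,-1.40,0.00070,-1.67
cg14322298,-1.53,0.0031,-1.57,0.0052,2.77
cg14478663,1.81,0.00020,1.91,0.00017,5.64
cg14574726,1.75,0.0058,1.91,0.0037,9.54
cg15281774,-1.91,0.0014,-2.13,0.00076,11.37
cg17041511,-1.97,0.000021,-2.25,0.000027,14.69
cg17549513,1.62,0.0094,1.82,0.0051,12.16
cg17594242,1.72,0.000035,1.71,0.000071,-0.93
cg17971837,-3.38,0.000061,-3.64,0.000069,7.85
cg23527183,-0.83,0.0048,-0.92,0.0034,10.38
cg24077454,1.33,0.0056,1.27,0.012,-4.29
cg24836822,-1.09,0.000020,-1.17,0.000014,8.19
cg25854298,-1.40,0.000042,-1.51,0.000037,7.39
cg27202913,-0.67,0.010,-0.69,0.0094,2.01
cg27468224,-1.83,0.00013,-1.85,0.00019,1.29
cg27469152,-1.99,0.00021,-2.21,0.000094,11.21
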