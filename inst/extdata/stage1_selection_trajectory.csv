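iteration,n_variables,oob_error_pct,nonatopic_error_pct,atopic_error_pct
1,254460,38.43,19.87,78.95
2,127230,35.12,17.46,73.68
3,63615,33.05,19.27,63.15
4,31807,27.68,10.24,65.78
5,15903,24.38,9.03,57.89
6,7951,16.94,4.21,44.73
7,3975,14.87,5.42,35.52
8,1987,11.15,4.21,26.31
9,993,11.57,4.81,26.31
10,496,9.09,5.42,17.10
11,248,8.67,5.42,15.78
12,124,9.09,5.42,17.10
13,62,9.50,7.22,14.47
14,31,11.98,9.63,17.10
15,15,15.70,13.85,19.73
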