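N,region,xd_mean,xd_ci_lo,xd_ci_hi,xd_r2,xp_mean,xp_ci_lo,xp_ci_hi,xp_r2
1,C,15.1,13.2,17.1,0.08,3.9,2.7,5.1,0.13
2,C,11.2,9.6,12.8,0.63,6.7,4.7,8.6,0.29
3,C,10.9,9.8,12.0,0.60,6.6,5.3,7.9,0.39
4,C,10.9,9.4,12.5,0.59,7.8,6.0,9.5,0.00
5,C,10.3,8.5,12.1,0.65,9.7,6.4,13.0,0.07
6,C,11.3,10.2,12.4,0.61,12.9,10.6,15.2,0.13
7,C,11.7,10.7,12.6,0.57,15.1,13.0,17.3,0.08
8,T,12.6,11.7,13.4,0.01,13.7,11.7,15.8,0.66
9,T,13.7,12.6,14.9,0.29,14.5,11.3,17.6,0.37
10,T,14.4,13.3,15.5,0.09,14.6,12.5,16.8,0.36
11,T,15.7,15.0,16.4,0.00,12.8,10.0,15.6,0.61
12,T,16.9,15.8,18.1,0.29,10.4,8.4,12.3,0.26
13,T,18.1,16.9,19.3,0.07,11.6,9.6,13.7,0.25
14,T,18.8,17.3,20.2,0.15,11.5,9.8,13.2,0.23
15,T,19.4,17.9,20.9,0.34,12.6,10.1,15.1,0.35
16,T,20.5,19.2,21.8,0.18,12.3,9.7,14.9,0.66
17,T,20.7,18.9,22.6,0.31,11.5,9.6,13.4,0.58
18,T,21.4,19.8,23.1,0.42,10.4,8.7,12.0,0.46
19,T,21.5,19.9,23.1,0.43,10.0,8.8,11.2,0.28
20,L,22.6,20.5,24.8,0.47,9.4,9.0,9.9,0.02
21,L,23.8,21.6,25.9,0.35,9.9,8.0,11.8,0.36
22,L,24.5,21.8,27.1,0.62,11.7,9.5,13.9,0.09
23,L,25.5,23.3,27.6,0.26,10.7,8.9,12.6,0.01
24,L,26.7,23.6,29.9,0.00,8.2,5.4,11.0,0.46
25,S,26.2,21.3,31.1,0.61,3.4,1.8,5.1,0.24
26,S,16.8,10.9,22.6,0.46,3.0,1.4,4.5,0.15
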