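study_id,year,design,n_treat,n_control,estimate,variance
1,1998,1,10,8,1.425,0.2814
2,2003,2,22,23,1.068,0.1016
3,1993,2,29,32,0.924,0.0727
4,1993,2,29,32,0.909,0.0725
5,2005,1,23,11,0.281,0.1355
6,2005,2,21,20,1.646,0.1307
7,1997,2,15,14,1.007,0.1556
8,2002,2,55,66,0.996,0.0374
9,2002,2,55,66,0.731,0.0355
10,1998,2,11,10,1.882,0.2752
11,2000,2,13,16,1.082,0.1596
12,1997,2,9,9,2.326,0.3725
13,1994,2,6,6,-0.229,0.3355
14,1980,2,10,10,0.191,0.2009
15,2001,2,18,33,0.980,0.0953
16,2001,2,16,33,1.620,0.1196
17,2005,2,10,8,2.997,0.4745
18,1999,1,6,6,0.860,0.3642
19,2006,2,10,10,1.494,0.2558
20,2003,1,11,15,0.597,0.1644
21,1998,2,19,16,0.674,0.1216
22,1998,2,19,16,0.490,0.1186
23,2004,2,6,9,3.780,0.7541
24,2004,2,10,9,1.590,0.2776
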