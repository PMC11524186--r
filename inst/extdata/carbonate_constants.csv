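temp_c,pk1,pk2,pkw,pkh,pksp
0,6.578562,10.628572,14.942096,1.108383,8.381419
5,6.516302,10.554413,14.732231,1.192068,8.394223
10,6.463342,10.487878,14.533826,1.269375,8.410478
15,6.418795,10.428426,14.346057,1.34082,8.430173
20,6.381871,10.375567,14.168183,1.406868,8.453297
25,6.351864,10.328854,13.999531,1.46794,8.47983
30,6.328147,10.28788,13.839491,1.524416,8.509751
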