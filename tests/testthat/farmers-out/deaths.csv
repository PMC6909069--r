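"round","id","class","strategy","wealth"
1,205,"poor","titfortat",-0.28
1,267,"poor","exploit",-0.28
2,21,"poor","exploit",-0.350000000000001
2,110,"poor","exploit",-0.320000000000001
3,206,"poor","exploit",-0.0399999999999996
4,285,"poor","titfortat",-0.31
4,323,"poor","exploit",-0.119999999999999
4,356,"poor","titfortat",-0.410000000000001
5,178,"poor","exploit",-0.69
5,291,"poor","exploit",-0.830000000000001
6,265,"poor","exploit",-0.0199999999999987
6,352,"poor","titfortat",-0.0699999999999983
7,44,"poor","exploit",-0.56
7,119,"poor","exploit",-0.39
7,180,"poor","titfortat",-0.800000000000001
7,353,"poor","exploit",-0.16
8,27,"poor","exploit",-0.57
8,68,"poor","titfortat",-0.630000000000001
8,243,"poor","titfortat",-0.0699999999999998
8,305,"poor","titfortat",-0.829999999999995
10,140,"poor","exploit",-8.88178419700125e-16
11,72,"poor","exploit",-0.0399999999999976
11,88,"poor","titfortat",-0.459999999999994
11,303,"poor","titfortat",-0.00999999999999734
11,325,"poor","titfortat",-0.02999999999999
12,248,"poor","titfortat",-0.12
12,324,"poor","exploit",-0.399999999999994
13,129,"poor","exploit",-0.639999999999999
14,138,"poor","thief",-0.0200000000000073
14,344,"poor","exploit",-0.689999999999994
15,149,"poor","exploit",-0.829999999999996
15,311,"poor","exploit",-0.49
15,326,"poor","titfortat",-0.319999999999989
16,118,"rich","titfortat",-0.460000000000008
16,187,"poor","titfortat",-0.54
17,8,"poor","thief",-5.99520433297585e-15
17,98,"poor","exploit",-0.139999999999994
17,141,"poor","titfortat",-0.229999999999998
18,246,"poor","exploit",-0.84
19,131,"poor","exploit",-0.509999999999997
19,221,"poor","titfortat",-0.219999999999999
19,226,"rich","thief",-0.0400000000000151
19,242,"poor","exploit",-0.00999999999999424
23,164,"poor","thief",-0.0300000000000176
24,91,"poor","thief",-0.0500000000000189
24,166,"poor","exploit",-0.479999999999998
25,162,"poor","exploit",-0.529999999999992
26,70,"poor","thief",-0.01000000000002
26,159,"rich","subsist",-0.0400000000000147
26,312,"poor","exploit",-0.609999999999996
26,322,"rich","titfortat",-0.010000000000058
28,350,"poor","titfortat",-0.499999999999991
29,184,"rich","subsist",-0.0100000000000235
29,266,"rich","exploit",-0.270000000000097
30,87,"poor","exploit",-0.569999999999985
30,186,"poor","subsist",-0.040000000000052
30,227,"poor","subsist",-0.0100000000000395
31,188,"poor","titfortat",-0.479999999999981
32,29,"poor","thief",-0.0200000000000269
32,86,"poor","titfortat",-0.569999999999987
32,208,"poor","titfortat",-0.979999999999984
32,313,"poor","titfortat",-0.00999999999997958
33,146,"rich","titfortat",-0.0100000000000393
33,209,"poor","exploit",-0.939999999999982
34,85,"poor","titfortat",-0.639999999999992
34,314,"poor","titfortat",-0.149999999999984
35,122,"poor","exploit",-0.359999999999991
37,197,"poor","titfortat",-0.259999999999997
38,165,"rich","exploit",-0.520000000000078
38,212,"poor","titfortat",-0.239999999999992
39,144,"rich","exploit",-0.790000000000078
41,28,"rich","exploit",-0.690000000000048
42,50,"rich","exploit",-0.660000000000032
42,163,"rich","exploit",-0.930000000000119
43,102,"poor","titfortat",-0.779999999999976
44,309,"poor","titfortat",-0.149999999999984
44,346,"rich","thief",-2.04503081135954e-13
45,147,"poor","thief",-1.66533453693773e-14
45,228,"poor","thief",-0.300000000000041
45,245,"poor","thief",-0.0400000000001106
45,327,"rich","thief",-0.0400000000001777
45,342,"poor","thief",-0.330000000000025
45,364,"rich","thief",-0.0300000000002349
45,366,"poor","exploit",-0.329999999999993
45,369,"poor","titfortat",-0.189999999999998
46,127,"rich","titfortat",-0.920000000000073
46,244,"rich","exploit",-0.860000000000123
46,264,"rich","thief",-0.0100000000001332
46,307,"poor","thief",-0.0200000000000367
46,328,"rich","thief",-0.0500000000000669
46,341,"rich","titfortat",-0.520000000000041
46,362,"rich","thief",-0.700000000000099
46,363,"rich","titfortat",-0.210000000000069
46,384,"poor","exploit",-0.589999999999968
46,386,"poor","thief",-0.170000000000002
47,92,"rich","titfortat",-0.190000000000032
47,329,"rich","titfortat",-0.370000000000122
47,385,"poor","titfortat",-0.919999999999964
48,330,"rich","thief",-0.610000000000132
48,345,"rich","thief",-0.0100000000001847
49,106,"rich","exploit",-0.0800000000001071
49,107,"poor","thief",-4.55191440096314e-14
49,128,"poor","thief",-0.00999999999999801
49,142,"rich","thief",-0.470000000000128
49,145,"poor","thief",-0.0600000000000398
49,224,"rich","thief",-0.0100000000000648
49,229,"poor","thief",-0.0400000000000458
49,289,"rich","thief",-0.0300000000000831
49,306,"rich","middle",-0.0400000000001897
49,308,"rich","thief",-0.670000000000014
49,321,"rich","middle",-0.0500000000001841
49,331,"rich","titfortat",-0.870000000000215
49,351,"poor","thief",-0.530000000000073
49,370,"poor","thief",-0.0300000000000467
50,66,"poor","thief",-0.0600000000000345
50,82,"poor","thief",-0.0300000000000173
50,89,"poor","thief",-0.0100000000000748
50,103,"rich","thief",-0.0300000000001306
50,108,"rich","thief",-0.0500000000000811
50,109,"rich","exploit",-0.100000000000119
50,143,"poor","thief",-0.0300000000000262
50,148,"poor","thief",-0.0400000000000238
50,150,"rich","exploit",-0.860000000000144
50,161,"poor","thief",-0.0300000000000094
50,168,"rich","thief",-0.0300000000001284
50,230,"rich","titfortat",-0.450000000000076
50,241,"poor","thief",-0.780000000000044
50,268,"poor","middle",-1.57873714101697e-13
50,283,"poor","subsist",-0.0600000000001502
50,286,"poor","middle",-0.0400000000002199
50,287,"poor","middle",-2.08499884024604e-13
50,288,"poor","middle",-0.0200000000000522
50,293,"rich","thief",-0.970000000000185
50,294,"rich","titfortat",-0.340000000000163
50,334,"rich","titfortat",-0.589999999999984
50,347,"rich","subsist",-0.0300000000001159
50,349,"rich","exploit",-0.30000000000009
50,354,"rich","thief",-6.50590692430342e-14
50,371,"poor","titfortat",-0.820000000000008
50,372,"poor","exploit",-0.959999999999952
50,390,"rich","thief",-0.0100000000000813
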