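compound,cayman_id,pct_inhibition,pct_sd,vina_score_kcal_mol
1,18532,50.9,1.3,-11.0
2,26113,41.4,0.9,-9.6
3,19922,34.7,2.1,-10.6
4,18006,24.9,1.8,-9.8
5,24159,20.2,1.3,-10.5
6,29424,18.7,1.1,-10.3
7,19160,18.5,0.7,-9.4
8,21546,17.0,1.0,-9.6
9,70635,16.6,1.3,-9.8
10,24057,15.9,2.1,-10.6
11,32729,15.4,1.3,-10.8
12,25747,14.4,0.9,-10.1
13,21688,13.5,1.3,-9.7
14,31758,13.1,1.3,-10.4
15,21137,12.4,1.5,-10.9
16,19404,5.8,1.8,-9.8
17,19876,-4.3,1.5,-10.4
18,18124,-4.4,1.2,-10.3
19,25326,-4.5,2.0,-9.9
20,17034,-4.6,1.4,-10.9
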