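label	unique_kmers	reads	bases
500 plus	1293	2142203	70692699
300-500	1414	536701	17711133
100-299	6561	1097771	36226443
35-99	15119	871270	28751910
20-34	14510	374818	12368994
15-20	12040	206542	6815886
11-14	15645	192046	6337518
9-10	15234	143581	4738173
7-8	29215	216367	7140111
6	26648	159888	5276304
5	43105	215525	7112325
4	72955	291820	9630060
3	130555	391665	12924945
2	259225	518450	17108850
1	1312518	1312518	43313094
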