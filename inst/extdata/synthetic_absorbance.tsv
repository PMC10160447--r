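# Synthetic absorbance readings (96% ethanol peel extracts, 1 cm path),
# constructed to emulate a green parent (G), yellow parent (Y) and their F1
# at 0-20 days after pollination, three biological replicates each.
# Columns: line, day, replicate, D470, D649, D665
line	day	replicate	D470	D649	D665
G	0	1	0.520	0.310	0.760
G	0	2	0.512	0.302	0.748
G	0	3	0.531	0.318	0.772
G	10	1	0.488	0.272	0.664
G	10	2	0.479	0.264	0.651
G	10	3	0.495	0.280	0.676
G	20	1	0.452	0.238	0.571
G	20	2	0.444	0.231	0.560
G	20	3	0.461	0.245	0.583
Y	0	1	0.592	0.082	0.176
Y	0	2	0.585	0.078	0.169
Y	0	3	0.601	0.086	0.184
Y	10	1	0.668	0.094	0.203
Y	10	2	0.659	0.090	0.196
Y	10	3	0.677	0.099	0.211
Y	20	1	0.741	0.108	0.234
Y	20	2	0.733	0.104	0.227
Y	20	3	0.752	0.113	0.242
F1	0	1	0.561	0.121	0.278
F1	0	2	0.553	0.116	0.270
F1	0	3	0.570	0.126	0.287
F1	10	1	0.547	0.133	0.301
F1	10	2	0.539	0.128	0.293
F1	10	3	0.556	0.138	0.310
F1	20	1	0.521	0.142	0.322
F1	20	2	0.514	0.137	0.314
F1	20	3	0.530	0.148	0.331
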