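# Synthetic CIELAB colorimeter readings of fruit peel at the ovary stage,
# constructed to emulate a light-green parent (G), a yellow parent (Y) and
# their F1 (yellow, slightly fainter than Y). Three fruits per line.
# Columns: line, fruit, L, a, b
line	fruit	L	a	b
G	1	46.2	-11.8	24.6
G	2	44.8	-12.4	25.3
G	3	45.9	-11.2	23.8
Y	1	71.4	8.2	56.1
Y	2	69.8	7.6	54.3
Y	3	72.0	8.9	57.2
F1	1	67.3	5.1	49.8
F1	2	66.1	4.6	48.2
F1	3	68.0	5.7	50.9
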