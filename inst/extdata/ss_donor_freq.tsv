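# Donor (5') splice-site per-position base frequencies, percent scale.
# Window layout: positions -3..-1 exonic, +1..+6 intronic (9-mer).
# Representative human splice-donor frequencies compiled from the
# splice-signal literature; pass your own table of this layout to
# ss_frequency_matrix(kind, path=) to use an exact published matrix.
pos	A	C	G	T
-3	33	37	18	12
-2	61	12	13	14
-1	10	3	80	7
+1	0	0	100	0
+2	0	0	0	100
+3	53	3	42	2
+4	71	8	12	9
+5	7	6	82	5
+6	16	17	19	48
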