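# Acceptor (3') splice-site per-position base frequencies, percent scale.
# Window layout: positions -20..-1 intronic (ending in the invariant AG),
# +1..+3 exonic (23-mer).
# Representative human splice-acceptor frequencies compiled from the
# splice-signal literature; pass your own table of this layout to
# ss_frequency_matrix(kind, path=) to use an exact published matrix.
pos	A	C	G	T
-20	9	31	15	45
-19	9	31	14	46
-18	8	31	15	46
-17	8	32	11	49
-16	9	33	10	48
-15	9	33	10	48
-14	9	37	9	45
-13	9	38	9	44
-12	9	39	9	43
-11	9	40	8	43
-10	9	40	8	43
-9	10	41	8	41
-8	10	42	7	41
-7	10	44	7	39
-6	11	45	7	37
-5	11	45	7	37
-4	23	28	23	26
-3	4	42	3	51
-2	100	0	0	0
-1	0	0	100	0
+1	25	13	49	13
+2	17	37	19	27
+3	22	31	25	22
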