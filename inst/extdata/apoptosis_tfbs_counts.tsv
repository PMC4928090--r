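tf	present_divergent	absent_divergent	present_nondivergent	absent_nondivergent	odds_ratio_ref	pvalue_ref
STAT1	15	9	8	33	6.63	9.84E-04
NFKB1	13	11	8	33	4.74	5.98E-03
Bcl6	14	10	10	31	4.23	8.44E-03
Esrrb	10	14	6	35	4.06	1.95E-02
CEBPA	16	8	15	26	3.40	2.31E-02
REL	9	15	5	36	4.21	2.73E-02
YY1	12	12	9	32	3.48	2.83E-02
Stat5a::Stat5b	12	12	9	32	3.48	2.83E-02
Nkx3-2	10	14	7	34	3.40	4.16E-02
ESRRA	11	13	8	33	3.42	4.61E-02
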