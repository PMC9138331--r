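# Universal mtMLSA primer table, Lepidoptera. Sequences are IUPAC-coded;
# **bold** marks degenerate bases introduced during design and is stripped
# on read. A printed Degeneracy of 0 means no degenerate base was
# introduced.
Gene	Primer	Sequence	Gene Location	Degeneracy	Ref
3' COI	C1-J-2183-Lepido (F)	CAACA**Y**TTATT**Y**TGATT**Y**TT**Y**GG	COI	16	B60
3' COI	L2-N-3014-Lepido (R)	TCCATTACAT**R**TA**D**TCTG**Y**CA**Y**ATTA	trnL	24	B60
3' COI	C1-J-2441-Lepido (F)	ATTAAAATTTT**Y**AG**H**TGA**H**T**R**GC	COI	36	B60
ND3	ND3-J-Gly-Lepido (F)	AGTATATTT**R**A**Y**TTCCAATC	trnG	4	a
ND3	ND3-N-5952-Lepido (R)	TA**R**TAT**N**TTTTG**R**T**H**TCATTC	ND3	48	B60
ND3	ND3-N-Arg-Lepido (R)	CTTTTA**D**GTCGAAA**H**TAAATGC	trnA	9	a
ND6	ND6-J-10090-Lepido (F)	ATCWATAATCTCCAAAATTAT	trnP	2	B48
ND6	ND6-N-10624-Lepido (R)	GGNCCA**W**A**R**AA**R**AT**R**TT**D**GT	ND6	192	B48
ND6	ND6-N-10589-Dipt/Lepido (R)	TAAWGANCC**R**AA**R**TTTCATC	CytB	32	a
16S 5'	LR-J-12888-Dipt/Lepido (F)	CCGGTT**B**GAACTCARATCA**Y**GTA	16S	12	B60
16S 5'	LR-N-13398-Dipt/Lepido (R)	C**Y**CCT**Y**TTTA**W**CAAAA**M**CAT	16S	16	B60
16S 3'	LR-J-13342-Dipt/Lepido (F)	CCTTTGCACRGT**Y**A**RR**ATACYGC	16S	32	B60
16S 3'	LR-N-13889-Dipt/Lepido (R)	ATTTAT**H**GTACCTTK**K**GTATCAG	16S	12	B60
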