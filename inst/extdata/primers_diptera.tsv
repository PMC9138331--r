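# Universal mtMLSA primer table, Diptera. Sequences are IUPAC-coded;
# **bold** marks degenerate bases introduced during design and is stripped
# on read. A printed Degeneracy of 0 means no degenerate base was
# introduced. Primers marked * in the name were selected for final testing.
Gene	Primer	Sequence	Gene Location	Degeneracy	Ref
3' COI	C1-J-2183-Dipt (F)	CAACA**Y**TTATT**Y**TG**R**TT**Y**TT**Y**GG	COI	32	B60
3' COI	C1-N-2926-Dipt (R)	CATTC**R**AT**W**GA**W**GA**R**TTTA**R**TTG	COI	32	a
3' COI	C1-N-2776-Dipt (R) *	GG**R**TA**R**TC**N**GA**R**TA**H**CG**N**CGNGG	COI	1536	B61
3' COI	C1-N-2944-Dipt (R) *	GG**N**GG**N**GT**R**TTTTG**R**TA**Y**C**Y**TTC	COI	256	a
3' COI	L2-N-3014-Dipt (R)	T**Y**CAATGCACTA**D**TCTGCCA**H**A**H**TA	trnL	54	B60
3' COI	C1-J-2195-Dipt (F) *	TTG**R**TT**Y**TT**Y**GG**D**CA**Y**CC**H**GA**R**GT	COI	288	B62
3' COI	C1-J-2441-Dipt (F)	AT**Y**AA**R**ATTTT**Y**AG**H**TGA**H**T**D**GC	COI	216	B60
ND3	ND3-J-Gly-Dipt (F)	TATATTTGACTTCCAATC	trnG	0	a
ND3	ND3-N-5952-Dipt (R)	TAATAT**N**CCTTG**R**TTTCATTC	ND3	8	B60
ND3	ND3-J-5463-Dipt (F)	GAAGC**H**GC**H**GC**H**TGATA**Y**TGAC	COIII	54	B63
ND6	ND6-J-Thr-Dipt (F)	TAAAAACATTGGTCTTG	trnT	0	B64
ND6	ND6-N-10589-Dipt/Lepido (R)	TAA**W**GA**N**CC**R**AA**R**TTTCATC	CytB	32	a
ND6	ND6-J-Pro-Dipt (F)	TCATTAATC**Y**CCAAA**R**TTA	trnP	4	B65
ND6	ND6-J-10070-Dipt (F) *	GGA**N**TAAT**NY**T**WY**T**WR**T**H**CAAAC	ND6	1536	a
16S 5'	LR-J-12888-Dipt/Lepido (F)	CCGGTT**B**GAACTCARATCA**Y**GTA	16S	12	B60
16S 5'	LR-N-13398-Dipt/Lepido (R)	C**Y**CCT**Y**TTTA**W**CAAAA**M**CAT	16S	16	B60
16S 3'	LR-J-13342-Dipt/Lepido (F)	CCTTTGCACRGT**Y**A**RR**ATACYGC	16S	32	B60
16S 3'	LR-N-13889-Dipt/Lepido (R)	ATTTAT**H**GTACCTTK**K**GTATCAG	16S	12	B60
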