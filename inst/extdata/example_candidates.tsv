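id	forward	reverse	domain	amplicon_length
bact_341f_805r	CCTACGGGNGGCWGCAG	GACTACHVGGGTATCTAATCC	Bacteria	464
univ_515f_806r	GTGYCAGCMGCCGCGGTAA	GGACTACNVGGGTWTCTAAT	Universal	291
bact_27f_1492r	AGAGTTTGATCMTGGCTCAG	TACGGYTACCTTGTTACGACTT	Bacteria	1465
arch_349f_806r	GYGCASCAGKCGMGAAW	GGACTACVSGGGTATCTAAT	Archaea	457
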