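id	forward	reverse
setpair1	TCCTACGGGAGGCAGCA,TCCTACCGGAGGCACCA,TCCTACGGGCGAATGCAG,CCTACGCGAGGCTGCAA,CCTACGCGAGGCAGCAA,CCTACGGAAGGCAGCAG,CCTACGGGTGGCTGCAG,CTACGGTGGGCTGCAG	TTCACGGCACGAGCTGAC,GACACGAGCTGACGACA
setpair2	TCCTACGGGAGGCAGCA,TCCTACCGGAGGCACCA,TCCTACGGGTGGTTGCAG,TCCTACGGAAGGCAGCAG,CCTACGCGAGGCAGCAA,CCTACGCGAGGCTGCAA,CCTACGGGCGAATGCAG,CTACGGTTGGCTGCAG	TTCACGGCACGAGCTGAC,ACGACACGAGCTGACGAC
setpair3	CTCCTACGGAAGGCAGCA,TCCTACGGGAGCCTGCA,TCCTACGGAAGGGTGCAG,CCTACGGGTTGCAGCAG,CCTACGCGAGGCAGCAA,CCTACGCGTGGTTGCAG,TCTACGGACGGCAGCAA,CTACGTGCGGTTGCAG	TACGACACGAGCTGACGA,ACGACACGAGCTGACAAC,CACCACGAGCTGACGAC,CAACACGAGCTGACGAGAG
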