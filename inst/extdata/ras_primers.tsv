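gene	direction	sequence
KRAS	forward	GCCATTTCGGACTGGGAGC
KRAS	reverse	CTCGAACTAATGTATAGAAGGCATCATC
NRAS	forward	GCTGTGGTCCTAAATCTGTCCA
NRAS	reverse	CTGTGAGACTGAAGACAGCAAC
HRAS	forward	GCAGTCGCGCCTGTGAAC
HRAS	reverse	GCACCTCCATGTCCTGAGCTT
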