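sample_date	site	MYC	KDR	TAOK2	MAP4K2	SIN3B	TP53	NLRC4
6/2/08	Left nasal mass	CCC	AGG	GAC	ATC	AAG	TTC	AGG
6/2/08	Right nasal mass	CCC	AGG	GAC	ATC	AAG	TTC	AGG
6/12/08	Frontal tumor	CCC	AGG	GAC	ATC	AAG	TTC	AGG
6/12/08	Nasal tumor	CCC	N/A	GAC	ATC	AAG	TTC	AGG
7/26/10	Right cheek	CTC	AAG	GAC	ATC	ATG	TTC	AAG
7/26/10	Right cheek (repeat)	CTC	AAG	GAC	ATC	ATG	TTC	AAG
11/3/10	Right cheek (WGS)	CTC	AAG	GAC	ATC	ATG	TTC	AAG
reference	reference	CCC	AGG	GGC	AGC	AAG	TGC	AGG
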