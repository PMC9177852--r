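sample_id	v_call	d_call	j_call	junction	junction_aa	duplicate_count	productive
pt_ex1	TRGV9*01		TRGJP*01	TGTGCCCTGTGGGAGGTGCAGGAGCTGGGCAAGAAAATCAAGGTGTTT	CALWEVQELGKKIKVF	55650	T
pt_ex1	TRGV9*01		TRGJ1/2*01	TGTGCCCTGGAGAGGGGCAAGCTGTTT	CALERGKLF	26050	T
pt_ex1	TRGV2*01		TRGJP2*01	TGTGCCACCTGGGATGGGAGCAGCGATTGGATCAAGACCTTT	CATWDGSSDWIKTF	12000	T
pt_ex1	TRGV3*01		TRGJ1/2*01	TGTGCCACCTGGGACAGGTATTATAAGAAACTGTT	CATWDRYYKKL	3100	F
pt_ex1	TRGV8*01		TRGJ1/2*01	TGTGCTACCTGGGATTAATATAAGAAACTGTTT	CATWD*YKKLF	900	F
pt_ex1	TRGV4*01		TRGJP1*01	TGTGCCACATGGACCACCGGCTGGTTCAAGATCTTT	CATWTTGWFKIF	6300	T
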