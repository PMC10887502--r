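mt-MRCA
	L0	263A 750T 1438C 2706C 4769T 8860G
		L0a	3594T 5442G 9042G
			L0a1	10398C 12705G
		L0b	5603A 9347T 13276C
		L0c	922C 15301T
	M	489T 10400G 14783G 15043C
		M7	6455T 9824T 12091A
			M7a	2772G 16324T
		M8	4715T 7196T 8584C
			M8a	6179A 14470T
		D4	4883T 5178C 8414G
	R	11467C 12372A
		B2	8281C 11177A 16189G
			B2a	13590T
		U5	3197G 9477T 13617T 16270C
			U5a	14793A 16256A
		H	7028C 11719T
			H1	3010T
			H3	6776T
				H3a	1018A
			H27	16093G
			H2	4680G
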