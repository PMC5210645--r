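chrom	start	end	summit_offset	caller	experiment_id	tf
chr1	3275	3276		GEM	exp01	USF1
chr1	3277	3278		GEM	exp02	USF1
chr1	3277	3278		GEM	exp03	USF1
chr1	3280	3281		GEM	exp04	USF1
chr1	3281	3282		GEM	exp05	USF1
chr1	3274	3275		GEM	exp06	USF1
chr1	3276	3277		GEM	exp07	USF1
chr1	3279	3280		GEM	exp08	USF1
chr1	3278	3279		GEM	exp09	USF1
chr1	3131	3431		PICS	exp01	USF1
chr1	3125	3425		PICS	exp02	USF1
chr1	3121	3421		PICS	exp03	USF1
chr1	3136	3436		PICS	exp04	USF1
chr1	3122	3422		PICS	exp05	USF1
chr1	3124	3424		PICS	exp06	USF1
chr1	3125	3425		PICS	exp07	USF1
chr1	3113	3413		PICS	exp08	USF1
chr1	3129	3429		PICS	exp09	USF1
chr1	3117	3417	150	MACS	exp01	USF1
chr1	3132	3432	150	MACS	exp02	USF1
chr1	3122	3422	150	MACS	exp03	USF1
chr1	3131	3431	150	MACS	exp04	USF1
chr1	3124	3424	150	MACS	exp05	USF1
chr1	3114	3414	150	MACS	exp06	USF1
chr1	3135	3435	150	MACS	exp07	USF1
chr1	3121	3421	150	MACS	exp08	USF1
chr1	3118	3418	150	MACS	exp09	USF1
chr1	3121	3421		SISSRS	exp01	USF1
chr1	3124	3424		SISSRS	exp02	USF1
chr1	3144	3444		SISSRS	exp03	USF1
chr1	3111	3411		SISSRS	exp04	USF1
chr1	3142	3442		SISSRS	exp05	USF1
chr1	3119	3419		SISSRS	exp06	USF1
chr1	3130	3430		SISSRS	exp07	USF1
chr1	3107	3407		SISSRS	exp08	USF1
chr1	3096	3396		SISSRS	exp09	USF1
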