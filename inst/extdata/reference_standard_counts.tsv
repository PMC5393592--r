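category	source	n_preferred	n_variants	n_shared_preferred	n_shared_genus	n_shared_epithet
birds	BirdLife	500	628	70	24	50
birds	CoL	500	622	114	30	89
mammals	ITIS	500	629	135	102	65
mammals	CoL	500	635	144	106	62
plants	PLANTS	500	770	343	341	124
plants	CoL	500	1195	426	697	193
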