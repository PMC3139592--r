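name	subsites	aa_sequence
LZF01	GAV	YKCKQCGKAFGCPSNLRRHGRTH
LZF02	GAW	YRCKYCDRSFSISSNLQRHVRNIH
LZF03	GGA	YKCGQCGKFYSQVSHLTRHQKIH
LZF04	HGA	YKCEECGKAFRQSSHLTTHKIIH
LZF05	GAA	FECKDCGKAFIQKSNLIRHQRTH
LZF06	NAA	YVCSKCGKAFTQSSNLTVHQKIH
LZF07	GYA	YKCPDCGKSFSQSSSLIRHQRTH
LZF08	HGA	YECHDCGKSFRQSTHLTQHRRIH
LZF09	GHG	YVCDVEGCTWKFARSDELNRHKKRH
LZF10	NGG	FQCKTCQRKFSRSDHLKTHTRTH
LZF11	GGG	YKCMECGKAFNRRSHLTRHQRIH
LZF12	GAG	YICRKCGRGFSRKSNLIRHQRTH
LZF13	AAT	YECDHCGKAFSVSSNLNVHRRIH
LZF14	GTD, GCD	YTCKQCGKAFSVSSSLRRHETTH
LZF15	GCW	YECNYCGKTFSVSSTLIRHQRIH
LZF16	GTG	FACPECPKRFMRSDALTRHIKTH
LZF17	GGC	FMCTWSYCGKRFTDRSHLARHKRTH
LZF18	GCC	FACPECPKRFMDRSDLTRHIKTH
LZF19	AAG	FACPECPKRFMRSDNLTQHIKTH
LZF20	RTC	YSCGICGKSFSDSSAKRRHCILH
LZF21	GRA, MGA	YVCRECGRGFRQHSHLVRHKRTH
LZF22	MAA	YMCSECGRGFSQKSNLIIHQRTH
LZF23	VGA, GAA	YECHDCGKSFRQSTHLTRHRRIH
LZF24	GGW	YRCEECGKAFRWPSNLTRHKRIH
LZF25	NNN	YACPVESCDRRFSRKWLLRLHIRIH
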