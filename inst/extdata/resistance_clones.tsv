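clone_id	finger1	finger2	finger3	finger4
7	LZF15	LZF23	LZF10	LZF20
19	LZF10	LZF02	LZF18	LZF12
64	LZF08	LZF25	LZF11	LZF23
70	LZF12	LZF03	LZF04	LZF21
83	LZF10	LZF25	LZF19	LZF23
115	LZF13	LZF14	LZF13	LZF23
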