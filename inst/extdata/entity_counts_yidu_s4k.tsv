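category	train	test
Disease	4212	1323
Anatomy	8426	3094
Laboratory	1195	590
Image	969	348
Medicine	1822	485
Operation	1029	162
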