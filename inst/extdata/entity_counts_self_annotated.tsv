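category	train	test
Disease	9470	4504
Symptoms	26334	11065
Anatomy	17877	7588
Examination	19664	8746
Instrument	1244	560
Medicine	5314	2566
Operation	2578	1133
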