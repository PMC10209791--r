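# Reference character code table: published input-method codings
# (5-stroke/wubi, Zheng, pinyin, stroke sequence) for six characters.
char	five_stroke	zheng	phonological	stroke_seq
呕	kaqy	jhos	ǒu	2511345
吐	kfg	jbvv	tù	251121
肿	ekhh	qji	zhǒng	35112512
胀	etay	qch	zhàng	35113154
心	nyny	wz	xīn	4544
手	rtgh	md	shǒu	3112
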