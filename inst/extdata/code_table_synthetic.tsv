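# SYNTHETIC code table: invented, well-formed codes for the synthetic-corpus
# character set (for offline testing only; not real wubi/Zheng/pinyin/stroke
# codings). Real reference codes live in code_table_reference.tsv.
char	five_stroke	zheng	phonological	stroke_seq
予	xosr	xj	kvn0	4412322
于	dqk	bqoh	yve3	1414
今	jon	kuxb	buang4	44213152
仪	zexm	reis	di0	413
伴	ja	ph	wong0	415
出	hc	fzey	nan0	531342435
刀	mn	lanm	gun3	412
切	of	mmte	qin2	431
及	pag	kpg	jei1	3145
后	wy	exnm	ma0	4514443
咳	gir	sjf	chun3	25
器	bep	uzia	zo2	555
好	lgj	zvtk	mao0	245324
引	io	ddl	hua3	42135
影	tnpp	fj	wang4	244
患	ikjp	en	iang0	253
无	bst	amqw	suai1	1123
日	phqy	abix	gao4	4513241
明	hate	elhs	mun4	2444
显	gxta	evh	rv2	32242
晕	otxi	uu	siong2	12113
有	gipy	uuxq	shue0	252
术	vfo	ee	nuai1	55
查	ibxg	jimk	gve0	143
检	dtd	zjoq	buan1	52
流	uf	ysx	ci4	55245
液	ass	jio	diang2	33
炎	zdm	gdgg	jui0	544
热	mmoi	vin	piong1	12532
片	twzf	ulj	tia3	434523
现	cyt	wan	sun1	4513
电	tzn	cmjx	eng0	545242
疡	ht	oce	ca2	543421224
疸	pgbe	ltxq	hie1	342
痛	ou	xccv	chai0	3425154
瘤	hv	elki	qv2	342143
癌	sai	wfvs	qai3	141114
管	qas	kfb	ou1	111
素	ed	lgxa	uang1	411
给	fi	gpzz	fin0	21133211
缝	vijs	gy	gian3	12353
者	id	rcsn	yen1	35225442
肝	sogd	paz	gian4	3322542
肺	bqqq	rcx	bui2	2424422
肾	hifq	xr	kuai2	24
胃	vice	mbo	gui3	513222514
胶	moxg	nfzf	ru1	55315124
脑	sqc	vq	zho0	22515
药	sv	ozwg	ai0	41544
行	jw	ommy	qan3	351
超	ycfd	goi	chuang1	55153355
转	bjlz	ew	sui2	2253252
部	xdk	pa	niong0	331541
针	sr	dags	sie3	121142
镜	qlpw	mksc	iu1	31
除	dfb	hzx	chui2	13544353
霉	oz	me	yia4	223122
验	vcu	fide	zhiong4	44
骨	ze	ac	pia2	41
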