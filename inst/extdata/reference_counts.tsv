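pos	conditioner	unit	label	category	count
noun	class	type	o_i	F	2
noun	class	type	o_i	M	11957
noun	class	type	a_e	F	8318
noun	class	type	a_e	M	0
noun	class	type	e_i	F	3268
noun	class	type	e_i	M	3907
noun	class	type	a_i	F	4
noun	class	type	a_i	M	932
noun	class	type	o_a	F	23
noun	class	type	o_a	M	23
noun	class	type	o_a_i	F	14
noun	class	type	o_a_i	M	42
noun	class	type	Inv	F	2
noun	class	type	Inv	M	40
noun	class	type	Other	F	55
noun	class	type	Other	M	89
noun	class	token	o_i	F	442454
noun	class	token	o_i	M	128733286
noun	class	token	a_e	F	81295823
noun	class	token	a_e	M	0
noun	class	token	e_i	F	47533225
noun	class	token	e_i	M	26577783
noun	class	token	a_i	F	207807
noun	class	token	a_i	M	5900697
noun	class	token	o_a	F	405856
noun	class	token	o_a	M	472125
noun	class	token	o_a_i	F	136379
noun	class	token	o_a_i	M	684209
noun	class	token	Inv	F	893
noun	class	token	Inv	M	9004
noun	class	token	Other	F	233392
noun	class	token	Other	M	979046
noun	ending	type	a	F.PL	23
noun	ending	type	a	F.SG	4331
noun	ending	type	a	M.PL	12
noun	ending	type	a	M.SG	477
noun	ending	type	e	F.PL	4286
noun	ending	type	e	F.SG	1715
noun	ending	type	e	M.PL	3
noun	ending	type	e	M.SG	2002
noun	ending	type	i	F.PL	1667
noun	ending	type	i	F.SG	0
noun	ending	type	i	M.PL	8661
noun	ending	type	i	M.SG	4
noun	ending	type	o	F.PL	0
noun	ending	type	o	F.SG	5
noun	ending	type	o	M.PL	7
noun	ending	type	o	M.SG	6205
noun	ending	token	a	F.PL	405856
noun	ending	token	a	F.SG	59533689
noun	ending	token	a	M.PL	8213
noun	ending	token	a	M.SG	4273650
noun	ending	token	e	F.PL	24251151
noun	ending	token	e	F.SG	39817093
noun	ending	token	e	M.PL	134
noun	ending	token	e	M.SG	16710610
noun	ending	token	i	F.PL	11290598
noun	ending	token	i	F.SG	0
noun	ending	token	i	M.PL	53488244
noun	ending	token	i	M.SG	129009
noun	ending	token	o	F.PL	0
noun	ending	token	o	F.SG	289291
noun	ending	token	o	M.PL	5963
noun	ending	token	o	M.SG	90593727
adjective	class	type	a_e o_i	F.PL	5727
adjective	class	type	a_e o_i	F.SG	6068
adjective	class	type	a_e o_i	M.PL	5831
adjective	class	type	a_e o_i	M.SG	6137
adjective	class	type	e_i e_i	F.PL	148
adjective	class	type	e_i e_i	F.SG	148
adjective	class	type	e_i e_i	M.PL	148
adjective	class	type	e_i e_i	M.SG	148
adjective	class	type	NA o_i	F.PL	0
adjective	class	type	NA o_i	F.SG	0
adjective	class	type	NA o_i	M.PL	285
adjective	class	type	NA o_i	M.SG	287
adjective	class	type	a_NA NA	F.PL	0
adjective	class	type	a_NA NA	F.SG	458
adjective	class	type	a_NA NA	M.PL	0
adjective	class	type	a_NA NA	M.SG	0
adjective	class	type	NA o_NA	F.PL	0
adjective	class	type	NA o_NA	F.SG	0
adjective	class	type	NA o_NA	M.PL	0
adjective	class	type	NA o_NA	M.SG	395
adjective	class	type	a_e NA	F.PL	128
adjective	class	type	a_e NA	F.SG	131
adjective	class	type	a_e NA	M.PL	0
adjective	class	type	a_e NA	M.SG	0
adjective	class	type	NA_e NA	F.PL	242
adjective	class	type	NA_e NA	F.SG	0
adjective	class	type	NA_e NA	M.PL	0
adjective	class	type	NA_e NA	M.SG	0
adjective	class	type	NA NA_i	F.PL	0
adjective	class	type	NA NA_i	F.SG	0
adjective	class	type	NA NA_i	M.PL	240
adjective	class	type	NA NA_i	M.SG	0
adjective	class	type	NA e_i	F.PL	0
adjective	class	type	NA e_i	F.SG	0
adjective	class	type	NA e_i	M.PL	19
adjective	class	type	NA e_i	M.SG	19
adjective	class	type	e_NA NA	F.PL	0
adjective	class	type	e_NA NA	F.SG	11
adjective	class	type	e_NA NA	M.PL	0
adjective	class	type	e_NA NA	M.SG	0
adjective	class	type	e_i NA	F.PL	2
adjective	class	type	e_i NA	F.SG	2
adjective	class	type	e_i NA	M.PL	0
adjective	class	type	e_i NA	M.SG	0
adjective	class	type	NA e_NA	F.PL	0
adjective	class	type	NA e_NA	F.SG	0
adjective	class	type	NA e_NA	M.PL	0
adjective	class	type	NA e_NA	M.SG	2
adjective	class	token	a_e o_i	F.PL	12516462
adjective	class	token	a_e o_i	F.SG	24500447
adjective	class	token	a_e o_i	M.PL	15542053
adjective	class	token	a_e o_i	M.SG	27661762
adjective	class	token	e_i e_i	F.PL	49146
adjective	class	token	e_i e_i	F.SG	98955
adjective	class	token	e_i e_i	M.PL	130777
adjective	class	token	e_i e_i	M.SG	157807
adjective	class	token	NA o_i	F.PL	0
adjective	class	token	NA o_i	F.SG	0
adjective	class	token	NA o_i	M.PL	52466
adjective	class	token	NA o_i	M.SG	165194
adjective	class	token	NA_e NA	F.PL	154248
adjective	class	token	NA_e NA	F.SG	0
adjective	class	token	NA_e NA	M.PL	0
adjective	class	token	NA_e NA	M.SG	0
adjective	class	token	NA NA_i	F.PL	0
adjective	class	token	NA NA_i	F.SG	0
adjective	class	token	NA NA_i	M.PL	117487
adjective	class	token	NA NA_i	M.SG	0
adjective	class	token	NA o_NA	F.PL	0
adjective	class	token	NA o_NA	F.SG	0
adjective	class	token	NA o_NA	M.PL	0
adjective	class	token	NA o_NA	M.SG	82563
adjective	class	token	a_e NA	F.PL	35220
adjective	class	token	a_e NA	F.SG	47231
adjective	class	token	a_e NA	M.PL	0
adjective	class	token	a_e NA	M.SG	0
adjective	class	token	a_NA NA	F.PL	0
adjective	class	token	a_NA NA	F.SG	27666
adjective	class	token	a_NA NA	M.PL	0
adjective	class	token	a_NA NA	M.SG	0
adjective	class	token	NA e_i	F.PL	0
adjective	class	token	NA e_i	F.SG	0
adjective	class	token	NA e_i	M.PL	1891
adjective	class	token	NA e_i	M.SG	2530
adjective	class	token	NA e_NA	F.PL	0
adjective	class	token	NA e_NA	F.SG	0
adjective	class	token	NA e_NA	M.PL	0
adjective	class	token	NA e_NA	M.SG	2167
adjective	class	token	e_i NA	F.PL	122
adjective	class	token	e_i NA	F.SG	483
adjective	class	token	e_i NA	M.PL	0
adjective	class	token	e_i NA	M.SG	0
adjective	class	token	e_NA NA	F.PL	0
adjective	class	token	e_NA NA	F.SG	132
adjective	class	token	e_NA NA	M.PL	0
adjective	class	token	e_NA NA	M.SG	0
adjective	ending	type	a	F.PL	0
adjective	ending	type	a	F.SG	6657
adjective	ending	type	a	M.PL	0
adjective	ending	type	a	M.SG	0
adjective	ending	type	e	F.PL	6097
adjective	ending	type	e	F.SG	161
adjective	ending	type	e	M.PL	0
adjective	ending	type	e	M.SG	169
adjective	ending	type	i	F.PL	150
adjective	ending	type	i	F.SG	0
adjective	ending	type	i	M.PL	6523
adjective	ending	type	i	M.SG	0
adjective	ending	type	o	F.PL	0
adjective	ending	type	o	F.SG	0
adjective	ending	type	o	M.PL	0
adjective	ending	type	o	M.SG	6819
adjective	ending	token	a	F.PL	0
adjective	ending	token	a	F.SG	24575344
adjective	ending	token	a	M.PL	0
adjective	ending	token	a	M.SG	0
adjective	ending	token	e	F.PL	12705930
adjective	ending	token	e	F.SG	99570
adjective	ending	token	e	M.PL	0
adjective	ending	token	e	M.SG	162504
adjective	ending	token	i	F.PL	49268
adjective	ending	token	i	F.SG	0
adjective	ending	token	i	M.PL	15844674
adjective	ending	token	i	M.SG	0
adjective	ending	token	o	F.PL	0
adjective	ending	token	o	F.SG	0
adjective	ending	token	o	M.PL	0
adjective	ending	token	o	M.SG	27909519
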