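#id=PP812219
#length=112465
#circular=true
record	name	host	category	start	end	strand	anticodon	start_codon	stop_codon	group	standard_name	note
gene	rnl		rRNA	1	12252	+
intron	rnl-i1	rnl		363	1187			 	 	II	mL432
intron	rnl-i2	rnl		1584	2832				 	IC1	mL849
orf	orf244	rnl-i2		1959	2690			ATG	TAA
intron	rnl-i3	rnl		3040	3073					unknown	mL1057	G
intron	rnl-i4	rnl		3426	4839					IC2	mL1408
orf	orf309	rnl-i4		3842	4768			ATG	TAA
intron	rnl-i5	rnl		5237	7339					unknown	mL1813	L
orf	orf360	rnl-i5		6132	7199			ATA	TAA
intron	rnl-i6	rnl		8010	10313					IA	mL2454	L
orf	rps3	rnl-i6		8255	9616			ATA	TAG
orf	orf225	rnl-i6		10348	11004			GTG	TAA			R
intron	rnl-i7	rnl		10398	11764					IC2	mL2536	L
orf	orf126	rnl-i7		10955	11332			ATA	TAG
orf	orf130	rnl-i7		11310	11699			ATA	TAA			L
gene	trnT-UGU		tRNA	12260	12330	+	UGU
gene	trnE-UUC		tRNA	12983	13055	+	UUC
gene	trnM-CAU-1		tRNA	13092	13162	+	CAU
gene	trnM-CAU-2		tRNA	13718	13789	+	CAU
gene	trnL-TAA		tRNA	13792	13873	+	TAA
gene	trnA-TGC		tRNA	13878	13948	+	TGC
gene	trnF-GAA		tRNA	14925	14997	+	GAA
gene	trnK-UUU		tRNA	14998	15070	+	UUU
gene	orf733		ORF	15154	17355	+		ATG	TAA
gene	trnL-UAG		tRNA	17699	17781	+	UAG
gene	trnQ-UUG		tRNA	18663	18736	+	UUG
gene	trnH-GUG		tRNA	18742	18816	+	GUG
gene	trnM-CAU-3		tRNA	18843	18914	+	CAU
gene	nad2		PCG	18977	30751	+		ATG	TAA
intron	nad2-i1	nad2		19451	21957					II	nad2S474	L
orf	orf798	nad2-i1		19454	21850			GCG	TAA
intron	nad2-i2	nad2		22054	24398					II	nad2S570	H
orf	orf720	nad2-i2		22054	24297			GTG	TAA
intron	nad2-i3	nad2		24594	25984					unknown	nad2U765	H
orf	orf424	nad2-i3		24618	25868			ATC	TAA
intron	nad2-i4	nad2		26225	28624					II	nad2S1005	L
orf	orf765	nad2-i4		26225	28522			GTG	TAA
intron	nad2-i5	nad2		29267	30718					IA	nad2P1647	H
orf	orf170	nad2-i5		29606	30097			ATT	TAA
gene	nad3		PCG	30752	31165	+		ATG	TAA
gene	atp9		PCG	31425	32720	+		ATG	TAA
intron	atp9-i1	atp9		31606	32676					IA	atp9P181	L
orf	orf159	atp9-i1		32151	32630			ATG	TAG
gene	cox2		PCG	32851	41537	+		ATG	TAA
intron	cox2-i1	cox2		32932	34232					IC2	cox2P81	G
orf	orf415	cox2-i1		32959	34179			ATG	TAA
intron	cox2-i2	cox2		34380	35491					IB	cox2P228	L
orf	orf291	cox2-i2		34392	35255			ATG	TAA
intron	cox2-i3	cox2		35525	36834					IC2	cox2P261	G
orf	orf191	cox2-i3		36217	36792			ATG	TAA
intron	cox2-i4	cox2		36931	39212					ID	cox2P357	L
orf	orf642	cox2-i4		36961	38859			ATA	TAA
intron	cox2-i5	cox2		39507	41438					IC1	cox2P651	L
orf	orf308	cox2-i5		40228	41154			ATG	TAA
gene	trnR-ACG		tRNA	41597	41667	+	ACG
gene	nad4L		PCG	41753	42052	+		ATG	TAA
gene	nad5		PCG	43479	50182	+		ATG	TAA
intron	nad5-i1	nad5		43803	45144					IC2	nad5P324	G
orf	orf427	nad5-i1		43803	45086			CGA	TAA
intron	nad5-i2	nad5		45247	47221					ID	nad5P426	L
intron	nad5-i3	nad5		47366	48742					IB	nad5P570
orf	orf354	nad5-i3		47366	48430			AAG	TAA
gene	cob		PCG	50367	61386	+		ATG	TAG
intron	cob-i1	cob		50568	52161					I-derived	cobP201	L
orf	orf116	cob-i1		51095	51445			ATG	TAA
intron	cob-i2	cob		52354	53538					ID	cobP393	L
orf	orf287	cob-i2		52354	53217			TAC	TAA
intron	cob-i3	cob		53583	55327					IB	cobP437	G
orf	orf279	cob-i3		54453	55292			ATG	TAA
intron	cob-i4	cob		55381	56546					I-derived	cobP490	L
orf	orf294	cob-i4		55383	56267			ACA	TAA
intron	cob-i5	cob		56563	57604					IB	cobP506	L
orf	orf315	cob-i5		56564	57511			AAA	TAA
intron	cob-i6	cob		57661	58972					IB	cobP563	L
orf	orf301	cob-i6		57878	58783			ATG	TAA
intron	cob-i7	cob		59234	61036					IB	cobP823	L
gene	trnC-GCA		tRNA	61437	61508	+	GCA
gene	cox1		PCG	61865	81144	+		ATG	TAA
intron	cox1-i1	cox1		62077	63306					I-derived	cox1P212
intron	cox1-i2	cox1		63335	64591					IB	cox1P240
orf	orf321	cox1-i2		63335	64300			AAG	TAA
intron	cox1-i3	cox1		64633	68366					IB	cox1P281	L
orf	orf310	cox1-i3		65237	66169			ATG	TAA
orf	orf291	cox1-i3		66266	67141			ATG	TAA			H
orf	orf290	cox1-i3		67148	68020			ATG	TAA			H
intron	cox1-i4	cox1		68472	69606					IB	cox1P386	L
orf	orf340	cox1-i4		68473	69495			AAA	TAA
intron	cox1-i5	cox1		69836	71997					unknown	cox1U615	L
orf	orf349	cox1-i5		69836	70885			AAA	TAA
orf	orf316	cox1-i5		71012	71962			ATG	TAA			L
intron	cox1-i6	cox1		72092	73503					unknown	cox1U709	L
orf	orf315	cox1-i6		72094	73041			AAA	TAA
intron	cox1-i7	cox1		73526	74556					IB	cox1P731	L
orf	orf315	cox1-i7		73527	74474			AAA	TAA
intron	cox1-i8	cox1		74647	75900					IB	cox1P821	L
orf	orf409	cox1-i8		74648	75877			AAA	TAA
intron	cox1-i9	cox1		75950	78346					IB	cox1P870	L
orf	orf348	cox1-i9		75950	76996			GTA	TAA
orf	orf272	cox1-i9		77118	77936			ATG	TAG			L
intron	cox1-i10	cox1		78602	79666					IB	cox1P1125	L
orf	orf342	cox1-i10		78602	79630			CAA	TAA
intron	cox1-i11	cox1		79804	80819					IB	cox1P1262	L
orf	orf270	cox1-i11		79805	80617			AAA	TAA
gene	trnR-UCU		tRNA	81228	81300	+	UCU
gene	nad1		PCG	81495	86839	+		ATG	TAA
intron	nad1-i1	nad1		81639	83453					I-derived	nad1P144	G
intron	nad1-i2	nad1		83698	85062					unknown	nad1U388
intron	nad1-i3	nad1		85311	86365					IB	nad1P636
gene	nad4		PCG	86936	89761	+		ATG	TAA
intron	nad4-i1	nad4		87441	88808					IC2	nad4P505
orf	orf422	nad4-i1		87443	88711			AAC	TAA
gene	atp8		PCG	89836	89982	+		ATG	TAA
gene	atp6		PCG	90068	95180	+		ATG	TAA
intron	atp6-i1	atp6		90412	91747					IB	atp6P344	L
orf	orf351	atp6-i1		90413	91468			AAA	TAA
intron	atp6-i2	atp6		91976	94972					IC2	atp6P572	L
orf	orf278	atp6-i2		92617	93453			ATG	TAA
orf	orf428	atp6-i2		93577	94863			AAA	TAG			G
gene	rns		rRNA	95910	98783	+
intron	rns-i1	rns		97071	98432					IC2	mS1291	G
orf	orf446	rns-i1		97002	98342			ATT	TAA
gene	trnY-GUA		tRNA	98828	98912	+	GUA
gene	trnD-GUC		tRNA	98921	98993	+	GUC
gene	trnS-GCU		tRNA	98999	99081	+	GCU
gene	trnN-GUU		tRNA	99091	99161	+	GUU
gene	cox3		PCG	99204	105205	+		ATG	TAA
intron	cox3-i1	cox3		99423	100521					IB	cox3P219	H
orf	orf302	cox3-i1		99423	100331			AAA	TAA
intron	cox3-i2	cox3		100636	101969					IC2	cox3P333	L
orf	orf428	cox3-i2		100636	101922			AAA	TAG
intron	cox3-i3	cox3		102187	103730					unknown	cox3U550	L
orf	orf364	cox3-i3		102189	103283			CTT	TAG
intron	cox3-i4	cox3		103812	105026					IA	cox3P631	L
gene	trnG-UCC		tRNA	105241	105311	+	UCC
gene	nad6		PCG	105399	107854	+		ATG	TAA
intron	nad6-i1	nad6		105632	106616					ID	nad6P233
intron	nad6-i2	nad6		106787	107600					II	nad6S384
gene	trnS-AGA		tRNA	108325	108397	+	AGA
gene	trnV-UAC		tRNA	109262	109333	+	UAC
gene	trnI-GAU		tRNA	110927	110997	+	GAU
gene	trnS-UGA		tRNA	111019	111105	+	UGA
gene	trnW-UCA		tRNA	111109	111180	+	UCA
gene	orf151		ORF	111299	111754	-		ATG	TAG
gene	trnP-UGG		tRNA	112307	112378	+	UGG
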