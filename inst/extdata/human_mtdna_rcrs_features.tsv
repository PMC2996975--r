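kind	label	strand	start1	end1	start2	end2	anticodon
control_region	CR	H	16024	16569	1	576	NA
tRNA	Phe	H	577	647	NA	NA	GAA
rRNA	rrnS	H	648	1601	NA	NA	NA
tRNA	Val	H	1602	1670	NA	NA	TAC
rRNA	rrnL	H	1671	3229	NA	NA	NA
tRNA	Leu1	H	3230	3304	NA	NA	TAA
CDS	ND1	H	3307	4262	NA	NA	NA
tRNA	Ile	H	4263	4331	NA	NA	GAT
tRNA	Gln	L	4329	4400	NA	NA	TTG
tRNA	Met	H	4402	4469	NA	NA	CAT
CDS	ND2	H	4470	5511	NA	NA	NA
tRNA	Trp	H	5512	5579	NA	NA	TCA
tRNA	Ala	L	5587	5655	NA	NA	TGC
tRNA	Asn	L	5657	5729	NA	NA	GTT
rep_origin_L	OL	L	5721	5798	NA	NA	NA
tRNA	Cys	L	5761	5826	NA	NA	GCA
tRNA	Tyr	L	5826	5891	NA	NA	GTA
CDS	COX1	H	5904	7445	NA	NA	NA
tRNA	Ser1	L	7446	7514	NA	NA	TGA
tRNA	Asp	H	7518	7585	NA	NA	GTC
CDS	COX2	H	7586	8269	NA	NA	NA
tRNA	Lys	H	8295	8364	NA	NA	TTT
CDS	ATP8	H	8366	8572	NA	NA	NA
CDS	ATP6	H	8527	9207	NA	NA	NA
CDS	COX3	H	9207	9990	NA	NA	NA
tRNA	Gly	H	9991	10058	NA	NA	TCC
CDS	ND3	H	10059	10404	NA	NA	NA
tRNA	Arg	H	10405	10469	NA	NA	TCG
CDS	ND4L	H	10470	10766	NA	NA	NA
CDS	ND4	H	10760	12137	NA	NA	NA
tRNA	His	H	12138	12206	NA	NA	GTG
tRNA	Ser2	H	12207	12265	NA	NA	GCT
tRNA	Leu2	H	12266	12336	NA	NA	TAG
CDS	ND5	H	12337	14148	NA	NA	NA
CDS	ND6	L	14149	14673	NA	NA	NA
tRNA	Glu	L	14674	14742	NA	NA	TTC
CDS	CYTB	H	14747	15887	NA	NA	NA
tRNA	Thr	H	15888	15953	NA	NA	TGT
tRNA	Pro	L	15956	16023	NA	NA	TGG
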