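dataset	predictor	TP	FN	TN	FP
D163	MiPred	162	1	72	96
D163	MIReNA	77	86	162	6
D163	MiRPara	149	14	87	81
D163	ProMiR	124	39	167	1
D163	TripletSVM	149	14	154	14
D1679	MiPred	1538	141	485	189
D1679	MIReNA	785	894	467	207
D1679	MiRPara	1236	443	260	414
D1679	ProMiR	830	849	668	6
D1679	TripletSVM	1424	255	222	452
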