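dataset	side	pred_i	pred_j	overlap	union_count	consistent
D163	positive	MiPred	MiPred	162	163	1
D163	positive	MIReNA	MIReNA	77	163	1
D163	positive	MiRPara	MiRPara	149	163	1
D163	positive	ProMiR	ProMiR	124	163	1
D163	positive	TripletSVM	TripletSVM	149	163	1
D163	positive	MiPred	MIReNA	77	162	1
D163	positive	MiPred	MiRPara	149	162	1
D163	positive	MiPred	ProMiR	77	163	0
D163	positive	MiPred	TripletSVM	149	162	1
D163	positive	MIReNA	MiRPara	65	161	1
D163	positive	MIReNA	ProMiR	60	141	1
D163	positive	MIReNA	TripletSVM	71	155	1
D163	positive	MiRPara	ProMiR	115	158	1
D163	positive	MiRPara	TripletSVM	137	161	1
D163	positive	ProMiR	TripletSVM	118	155	1
D163	negative	MiPred	MiPred	72	168	1
D163	negative	MIReNA	MIReNA	162	168	1
D163	negative	MiRPara	MiRPara	87	168	1
D163	negative	ProMiR	ProMiR	167	168	1
D163	negative	TripletSVM	TripletSVM	154	168	1
D163	negative	MiPred	MIReNA	70	164	1
D163	negative	MiPred	MiRPara	45	141	0
D163	negative	MiPred	ProMiR	72	168	0
D163	negative	MiPred	TripletSVM	68	158	1
D163	negative	MIReNA	MiRPara	87	162	1
D163	negative	MIReNA	ProMiR	161	168	1
D163	negative	MIReNA	TripletSVM	83	166	0
D163	negative	MiRPara	ProMiR	87	168	0
D163	negative	MiRPara	TripletSVM	35	139	0
D163	negative	ProMiR	TripletSVM	86	168	0
D1679	positive	MiPred	MiPred	1538	1679	1
D1679	positive	MIReNA	MIReNA	785	1679	1
D1679	positive	MiRPara	MiRPara	1236	1679	1
D1679	positive	ProMiR	ProMiR	830	1679	1
D1679	positive	TripletSVM	TripletSVM	1424	1679	1
D1679	positive	MiPred	MIReNA	748	1575	1
D1679	positive	MiPred	MiRPara	1166	1608	1
D1679	positive	MiPred	ProMiR	777	1591	1
D1679	positive	MiPred	TripletSVM	1368	1594	1
D1679	positive	MIReNA	MiRPara	553	1468	1
D1679	positive	MIReNA	ProMiR	494	1121	1
D1679	positive	MIReNA	TripletSVM	743	1466	1
D1679	positive	MiRPara	ProMiR	625	1441	1
D1679	positive	MiRPara	TripletSVM	1127	1533	1
D1679	positive	ProMiR	TripletSVM	782	1472	1
D1679	negative	MiPred	MiPred	485	674	1
D1679	negative	MIReNA	MIReNA	467	674	1
D1679	negative	MiRPara	MiRPara	260	674	1
D1679	negative	ProMiR	ProMiR	668	674	1
D1679	negative	TripletSVM	TripletSVM	222	674	1
D1679	negative	MiPred	MIReNA	288	664	1
D1679	negative	MiPred	MiRPara	120	625	1
D1679	negative	MiPred	ProMiR	482	668	0
D1679	negative	MiPred	TripletSVM	171	536	1
D1679	negative	MIReNA	MiRPara	251	476	1
D1679	negative	MIReNA	ProMiR	462	673	1
D1679	negative	MIReNA	TripletSVM	197	492	1
D1679	negative	MiRPara	ProMiR	258	670	1
D1679	negative	MiRPara	TripletSVM	137	345	1
D1679	negative	ProMiR	TripletSVM	221	669	1
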