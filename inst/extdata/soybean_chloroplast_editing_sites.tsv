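gene	position	codon_site	conversion	intron
accD	617	2	S(uCg)→L(uUg)	FALSE
atpF	92	2	P(cCa)→L(cUa)	FALSE
clpP	559	1	H(Cau)→Y(Uau)	FALSE
ndhA	341	2	S(uCa)→L(uUa)	FALSE
ndhA	1073	2	S(uCu)→F(uUu)	FALSE
ndhB	9	3	W(ugG)→stop codon (ugA)	FALSE
ndhB	149	2	S(uCa)→L(uUa)	FALSE
ndhB	542	2	T(aCg)→M(aUg)	FALSE
ndhB	586	1	H(Cau)→Y(Uau)	FALSE
ndhB	737	2	P(cCa)→L(cUa)	FALSE
ndhB	746	2	S(uCu)→F(uUu)	FALSE
ndhB	830	2	S(uCa)→L(uUa)	FALSE
ndhB	836	2	S(uCa)→L(uUa)	FALSE
ndhB	1112	2	S(uCa)→L(uUa)	FALSE
ndhB	1255	1	H(Cau)→Y(Uau)	FALSE
ndhB	1481	2	P(cCa)→L(cUa)	FALSE
ndhC	323	2	S(uCa)→L(uUa)	FALSE
ndhD	2	2	T(aCg)→M(aUg)	FALSE
ndhD	383	2	T(aCa)→I(aUa)	FALSE
ndhD	674	2	S(uCa)→L(uUa)	FALSE
ndhD	878	2	S(uCa)→L(uUa)	FALSE
ndhD	1298	2	S(uCa)→L(uUa)	FALSE
ndhE	233	2	P(cCg)→L(cUg)	FALSE
ndhF	290	2	S(uCa)→L(uUa)	FALSE
petB	611	2	S(uCa)→L(uUa)	FALSE
psaI	79	1	H(Cau)→Y(Uau)	FALSE
psbE	214	2	S(uCc)→F(uUc)	FALSE
psbF	6	3	T(acC)→T(acU)	FALSE
psbF	77	2	S(uCu)→F(uUu)	FALSE
psbL	2	2	T(aCg)→M(aUg)	FALSE
rpl23	89	2	S(uCa)→L(uUa)	FALSE
rpoA	200	2	S(uCa)→L(uUa)	FALSE
rpoB	338	2	S(uCu)→F(uUu)	FALSE
rpoB	551	2	S(uCa)→L(uUa)	FALSE
rpoB	566	2	S(uCg)→L(uUg)	FALSE
rpoB	2000	2	S(uCu)→F(uUu)	FALSE
rpoC1	41	2	S(uCa)→L(uUa)	FALSE
rpoC1	488	2	S(uCa)→L(uUa)	FALSE
rps2	134	2	T(aCa)→I(aUa)	FALSE
rps2	248	2	S(uCa)→L(uUa)	FALSE
rps12	554	NA	NA	TRUE
rps14	80	2	S(uCa)→L(uUa)	FALSE
rps16	499	NA	NA	TRUE
rps16	212	2	S(uCa)→L(uUa)	FALSE
rps18	221	2	S(uCg)→L(uUg)	FALSE
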