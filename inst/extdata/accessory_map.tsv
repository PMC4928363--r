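pfam_accession	label
PF00553	CBM2
PF00942	CBM3
PF02018	CBM4_9
PF02839	CBM5_12
PF03422	CBM6
PF02013	CBM9
PF16990	CBM35
PF00652	Ricin_B_lectin
PF00686	CBM20
PF09212	CBM27
PF00404	Dockerin
PF00963	Cohesin
PF00395	SLH
PF00041	fn3
PF16893	fn3_like
PF00028	Cadherin
PF12733	Cadherin_3
PF16184	Cadherin_4
PF02012	BNR
PF14873	BNR_2
PF01522	Polysacc_deac_1
PF00703	GH2
PF00933	GH3
PF02156	GH26
PF01301	GH35
PF00535	GT2
PF11721	Lectin_like
PF13385	Laminin_G_3
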