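# Sushi sampling in Southern Italy. processed_replicates transcribes the bracketed number of processed samples per product; misdescribed transcribes the bold marking.
# Site codes: NA = Napoli; LE = Lecce; RC = Reggio Calabria; ME = Messina; CAT = Catania; GE = Gela.
# Footnote: declared_not_in_md marks declared species footnoted as "not present in the Italian D.M. 2008".
sample_code	region	retail_type	category	menu_label	declared_name	declared_not_in_md	identified_species	identity_pct	processed_replicates	misdescribed	accession	blast_accession	bold_id
CAT1B	south	restaurant	white_fish	sea bream or common bass	Sparus aurata	FALSE	Sparus aurata	99.08	3	FALSE	MW714949	KC501553	DNATR1582-13
CAT1T	south	restaurant	tuna	Tuna	Thunnus thynnus	FALSE	Thunnus albacares	99.54	3	TRUE	MW714950	MH638785	ANGBF54814-19
CAT1E	south	restaurant	roe	tobiko/flying fish egg	Hirundichthys affinis	TRUE	Mallotus villosus	99.39	3	TRUE	MW714951	FJ205579	GBGC7486-09
CAT3B	south	restaurant	white_fish	sea bream or common bass	Sparus aurata	FALSE	Xiphias gladius	99.54	3	TRUE	MW714952	JN049558	ANGBF7251-12
GE1B	south	restaurant	white_fish	common bass	Dicentrarchus labrax	FALSE	Dicentrarchus labrax	99.53	3	FALSE	MW714953	KP330301	GBMIN94166-17
GE1T	south	restaurant	tuna	Tuna	Thunnus thynnus	FALSE	Thunnus albacares	99.08	3	TRUE	MW714954	MH638785	ANGBF54814-19
GE1E	south	restaurant	roe	tobiko/flying fish egg	Hirundichthys affinis	TRUE	Hirundichthys affinis	99.52	3	FALSE	MW714955	JQ842898	TOBA086-09
GE2B	south	restaurant	white_fish	common bass	Dicentrarchus labrax	FALSE	Dicentrarchus labrax	99.53	3	FALSE	MW714956	KP330301	GBMIN94166-17
ME1B	south	restaurant	white_fish	sea bream	Sparus aurata	FALSE	Sparus aurata	99.85	3	FALSE	MW714957	MF438138	ANGBF45411-19
ME1T	south	restaurant	tuna	Tuna	Thunnus thynnus	FALSE	Thunnus albacares	98.93	3	TRUE	MW714958	MH638762	ANGBF54791-19
ME1E	south	restaurant	roe	lumpfish roe	Cyclopterus lumpus	FALSE	Cyclopterus lumpus	99.54	3	FALSE	MW714959	MG421634	TZAIC166-05
ME2B	south	restaurant	white_fish	sea bream	Sparus aurata	FALSE	Sparus aurata	99.39	3	FALSE	MW714960	MF438138	ANGBF45411-19
ME2E	south	restaurant	roe	Ikura	salmon eggs	FALSE	Oncorhynchus keta	98.93	2	FALSE	MW714961	LC094477	ANGBF41103-19
RC1B	south	takeaway	other	Anago	Anguilla sp	FALSE	Anguilla rostrata	98.31	3	FALSE	MW714962	KX459333	SERCA165-12
RC1T	south	takeaway	tuna	Tuna	Thunnus thynnus	FALSE	Thunnus albacares	99.39	3	TRUE	MW714963	MH638785	ANGBF54814-19
RC1E	south	takeaway	roe	Ikura	salmon eggs	FALSE	Oncorhynchus keta	99.54	2	FALSE	MW714964	LC094477	ANGBF41103-19
RC2E	south	takeaway	roe	lumpfish roe	Cyclopterus lumpus	FALSE	Cyclopterus lumpus	99.07	2	FALSE	MW714965	MG421634	TZAIC166-05
LE1B	south	restaurant	white_fish	sea bream	Sparus aurata	FALSE	Sparus aurata	98.93	3	FALSE	MW714966	MF438138	ANGBF45411-19
LE1E	south	restaurant	roe	tobiko/flying fish egg	Hirundichthys affinis	TRUE	Mallotus villosus	99.39	1	TRUE	MW714967	FJ205579	GBGC7486-09
NA1B	south	takeaway	white_fish	sea bream or common bass	Sparus aurata/Dicentrarchus labrax	FALSE	Sparus aurata	99.24	3	FALSE	MW714968	KC501554	DNATR1599-13
NA2B	south	takeaway	white_fish	sea bream or common bass	Sparus aurata/Dicentrarchus labrax	FALSE	Pomatomus saltatrix	99.39	3	TRUE	MW714969	KC501113	DNATR1143-13
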