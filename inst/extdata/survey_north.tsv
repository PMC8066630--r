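# Sushi sampling in Northern Italy. processed_replicates transcribes the bracketed number of processed samples per product; misdescribed transcribes the bold marking.
# Site codes: MIL = Milano; CES = Cesena Brianza; DAL = Dalmine; VI = Vicenza; FC = Forli Cesena; UD = Udine.
# Footnote: declared_not_in_md marks declared species footnoted as "not present in the Italian D.M. 2008".
sample_code	region	retail_type	category	menu_label	declared_name	declared_not_in_md	identified_species	identity_pct	processed_replicates	misdescribed	accession	blast_accession	bold_id
MIL1B	north	restaurant	white_fish	sea bream or common bass	Sparus aurata/Dicentrarchus labrax	FALSE	Dicentrarchus labrax	99.69	3	FALSE	MW714726	KP330301	GBMIN94166-17
MIL1T	north	restaurant	tuna	tuna	Thunnus thynnus	FALSE	Thunnus albacares	99.54	3	TRUE	MW714727	MH638785	ANGBF54814-19
MIL2B	north	takeaway	white_fish	sea bream or common bass	Sparus aurata/Dicentrarchus labrax	FALSE	Dicentrarchus labrax	99.37	1	FALSE	MW714728	KY176457	GBMIN121550-17
MIL2T	north	takeaway	tuna	tuna	Thunnus thynnus	FALSE	Thunnus albacares	98.47	3	TRUE	MW714729	MH638777	ANGBF54806-19
MIL3B	north	takeaway	white_fish	sea bream	Sparus aurata/Dicentrarchus labrax	FALSE	Dicentrarchus labrax	98.74	3	FALSE	MW714730	KP330301	GBMIN94165-17
MIL4B	north	takeaway	white_fish	common bass	Sparus aurata/Dicentrarchus labrax	FALSE	Sparus aurata	99.54	3	FALSE	MW714731	MF438138	ANGBF45411-19
CES1B	north	takeaway	white_fish	common bass	Dicentrarchus labrax	FALSE	Dicentrarchus labrax	99.06	3	FALSE	MW714732	KP330300	GBMIN94165-17
DAL1B	north	restaurant	white_fish	sea bream	Sparus aurata	FALSE	Sparus aurata	99.24	3	FALSE	MW714733	JQ623999	DNATR096-12
DAL1T	north	restaurant	tuna	tuna	Thunnus thynnus	FALSE	Thunnus albacares	99.24	3	TRUE	MW714734	MH638785	ANGBF54814-19
DAL1E	north	restaurant	roe	tobiko/flying fish egg	Hirundichthys affinis	TRUE	Hirundichthys oxycephalus	99.02	3	FALSE	MW714735	KX769042	GBMIN125981-17
VI1T	north	restaurant	tuna	tuna	Thunnus thynnus	FALSE	Thunnus thynnus	98.92	3	FALSE	MW714736	KP975912	FCSF387-14
VI1B	north	restaurant	white_fish	sea bream	Sparus aurata	FALSE	Sparus aurata	98.78	3	FALSE	MW714737	KC501553	DNATR1582-13
VI1E	north	restaurant	roe	tobiko/flying fish egg	Hirundichthys affinis	TRUE	Hirundichthys affinis	99.52	3	FALSE	MW714738	JQ842898	TOBA086-09
FC1B	north	takeaway	white_fish	sea bream	Sparus aurata	FALSE	Seriola lalandi	99.39	3	TRUE	MW714739	MH211123	GBMNA18700-19
FC1T	north	takeaway	tuna	maguro Yaki (red tuna)	Thunnus thynnus	FALSE	Thunnus thynnus	99.39	3	FALSE	MW714740	KC501694	DNATR1720-13
FC2B	north	takeaway	white_fish	sea bream	Sparus aurata	FALSE	Sparus aurata	99.69	1	FALSE	MW714741	MF438138	ANGBF45411-19
UD1B	north	restaurant	other	kajiki roll (swordfish)	Xiphias gladius	FALSE	Xiphias gladius	99.38	3	FALSE	MW714742	MK295657	ANGBF51916-19
UD1T	north	restaurant	tuna	tuna	Thunnus thynnus	FALSE	Thunnus obesus	99.08	2	TRUE	MW714743	GU451774	GBGCA1353-13
UD1E	north	restaurant	roe	tobiko/flying fish egg	Hirundichthys affinis	TRUE	Mallotus villosus	99.39	3	TRUE	MW714744	HM421773	DSFAL635-09
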