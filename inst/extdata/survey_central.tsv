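# Sushi sampling in Central Italy. processed_replicates transcribes the bracketed number of processed samples per product; misdescribed transcribes the bold marking.
# Site codes: FIR = Firenze; PER = Perugia; ORV = Orvieto; TER = Terni; PE = Pescara; RO = Roma.
# Footnote: declared_not_in_md marks declared species footnoted as "not present in the Italian D.M. 2008".
sample_code	region	retail_type	category	menu_label	declared_name	declared_not_in_md	identified_species	identity_pct	processed_replicates	misdescribed	accession	blast_accession	bold_id
FIR1B	central	takeaway	white_fish	common bass	Dicentrarchus labrax	FALSE	Dicentrarchus labrax	99.21	3	FALSE	MW714657	KP330300	GBMIN94165-17
FIR1T	central	takeaway	tuna	tuna	Thunnus thynnus	FALSE	Thunnus albacares	99.85	3	TRUE	MW714658	MH638777	ANGBF54806-19
FIR1E	central	takeaway	roe	tobiko/flying fish egg	Hirundichthys affinis	TRUE	Hirundichthys affinis	99.52	3	FALSE	MW714659	JQ842898	TOBA9086
PER1B	central	restaurant	white_fish	sea bream or common bass	Sparus aurata/Dicentrarchus labrax	FALSE	Sparus aurata	99.54	3	FALSE	MW714660	MF438138	ANGBF45411-19
PER1T	central	restaurant	tuna	tuna	Thunnus thynnus	FALSE	Thunnus albacares	99.39	3	TRUE	MW714661	MH638785	ANGBF54814-19
PER1E	central	restaurant	roe	tobiko/flying fish egg	Hirundichthys affinis	TRUE	Hirundichthys affinis	99.35	1	FALSE	MW714662	JQ842898	TOBA9086
PER2B	central	takeaway	white_fish	sea bream or common bass	Sparus aurata/Dicentrarchus labrax	FALSE	Dicentrarchus labrax	99.21	3	FALSE	MW714663	KP330301	GBMIN94166-17
ORV1B	central	takeaway	white_fish	common bass	Dicentrarchus labrax	FALSE	Dicentrarchus labrax	98.58	3	FALSE	MW714664	KP330301	GBMIN94166-17
ORV1T	central	takeaway	tuna	tuna	Thunnus thynnus	FALSE	Thunnus albacares	98.17	2	TRUE	MW714665	MH638785	ANGBF54814-19
ORV1E	central	takeaway	roe	tobiko/flying fish egg	Hirundichthys affinis	TRUE	Hirundichthys affinis	99.52	3	FALSE	MW714666	JQ842898	TOBA086-09
ORV2B	central	restaurant	white_fish	sea bream	Sparus aurata	FALSE	Sparus aurata	98.47	3	FALSE	MW714667	KC501553	DNATR1582-13
TER1B	central	takeaway	white_fish	sea bream	Sparus aurata	FALSE	Sparus aurata	99.39	3	FALSE	MW714668	KC501557	DNATR1596-13
TER1T	central	takeaway	tuna	tuna	Thunnus thynnus	FALSE	Thunnus orientalis	99.70	3	TRUE	MW714669	JN097817	GBGCA1390-13
TER1E	central	takeaway	roe	tobiko/flying fish egg	Hirundichthys affinis	TRUE	Hirundichthys affinis	99.52	3	FALSE	MW714670	JQ842898	TOBA9086
PE1B	central	restaurant	white_fish	common bass	Dicentrarchus labrax	FALSE	Dicentrarchus labrax	98.58	3	FALSE	MW714671	KP330301	GBMIN94166-17
PE1T	central	restaurant	tuna	tuna	Thunnus thynnus	FALSE	Thunnus albacares	98.92	3	TRUE	MW714672	MH638785	ANGBF54814-19
PE1E	central	restaurant	roe	tobiko/flying fish egg	Hirundichthys affinis	TRUE	Hirundichthys coromandelensis	98.73	1	FALSE	MW714673	KX379460	ANGBF32076-19
RO1B	central	restaurant	white_fish	sea bream	Sparus aurata	FALSE	Seriola lalandi	99.24	3	TRUE	MW714674	MF069453	ANGBF17684-19
RO1T	central	restaurant	tuna	tuna	Thunnus thynnus	FALSE	Thunnus albacares	99.39	3	TRUE	MW714675	HM007768	ANGBF7098-12
RO1E	central	restaurant	roe	tobiko/flying fish egg	Hirundichthys affinis	TRUE	Mallotus villosus	99.23	1	TRUE	MW714676	FJ205579	GBGC7486-09
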