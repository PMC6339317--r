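product_name	atc_code	alt_names	strengths	unit
Actrapid	A10AB01	Humaninsulin	100	ie
Lantus	A10AE04	Insulin glargin	100	ie
Metformin	A10BA02	Glucophage	500|850|1000	mg
Glibenclamid	A10BB01	Euglucon	1.75|3.5	mg
Janumet	A10BD07	Velmetia	50	mg
Acarbose	A10BF01	Glucobay	50|100	mg
Pioglitazon	A10BG03	Actos	15|30	mg
Januvia	A10BH01	Sitagliptin	25|50|100	mg
Repaglinid	A10BX02	NovoNorm	0.5|1|2	mg
Warfarin	B01AA03	Coumadin	5	mg
Marcumar	B01AA04	Phenprocoumon	3	mg
Clexane	B01AB05	Enoxaparin	20|40	mg
Fraxiparin	B01AB06		2850	ie
Plavix	B01AC04	Clopidogrel	75	mg
Ticlopidin	B01AC05	Tiklyd	250	mg
Efient	B01AC22	Prasugrel	5|10	mg
Brilique	B01AC24	Ticagrelor	60|90	mg
Bayer Aspirin forte 100mg	B01AC06	ASS	100|300	mg
Dipyridamol	B01AC07	Persantin	75	mg
Pradaxa	B01AE07	Dabigatran	75|110|150	mg
Xarelto	B01AF01	Rivaroxaban	10|15|20	mg
Eliquis	B01AF02	Apixaban	2.5|5	mg
Digoxin	C01AA05	Lanicor	0.25	mg
Cordarex	C01BD01	Amiodaron	200	mg
Mono-Mack	C01DA14	Isosorbidmononitrat	20|40	mg
Esidrix	C03AA03	Hydrochlorothiazid|HCT	12.5|25	mg
Lasix	C03CA01	Furosemid	20|40	mg
Dytide	C03EA01	Triamteren	25	mg
Belok zok	C07AB02	Metoprolol	47.5|95	mg
Atenolol	C07AB03	Tenormin	25|50|100	mg
Concor	C07AB07	Bisoprolol	2.5|5|10	mg
Nebilet	C07AB12	Nebivolol	5	mg
Dilatrend	C07AG02	Carvedilol	12.5|25	mg
Norvasc	C08CA01	Amlodipin	5|10	mg
Adalat	C08CA05	Nifedipin	10|20	mg
Isoptin	C08DA01	Verapamil	80|120	mg
Dilzem	C08DB01	Diltiazem	60|90	mg
Lisinopril	C09AA03	Acerbon	5|10|20	mg
Delix	C09AA05	Ramipril	2.5|5|10	mg
Acercomp	C09BA03		10	mg
Lorzaar	C09CA01	Losartan	50|100	mg
Diovan	C09CA03	Valsartan	80|160	mg
Votum	C09CA08	Olmesartan	10|20|40	mg
Levothyroxin-Natrium	H03AA01	Levothyroxin Na|L-Thyroxin	50|75|100	µg
Ibuhexal	M01AE01	Ibuprofen	400|600	mg
Voltaren	M01AB05	Diclofenac	50|75	mg
Paracetamol-Ratiopharm 500mg	N02BE01	Ben-u-ron	500|1000	mg
ACC akut 200mg Hustenlöser	R05CB01	Acetylcystein	200|600	mg
Euphylong	R03DA04	Theophyllin	250|375	mg
Spiriva	R03BB04	Tiotropium	18	µg
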