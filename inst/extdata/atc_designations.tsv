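designation	codes	abbr
Insulin	A10A
Oral antidiabetes medication	A10B
Biguanides	A10BA
Sulfonylureas	A10BB
Antidiabetes combinations	A10BD
Alpha-glucosidase inhibitors	A10BF
Thiazolidinediones	A10BG
DPP-4 inhibitors	A10BH
Meglitinides	A10BX
Vitamin K antagonists	B01AA	VKA
Warfarin	B01AA03
ADP receptor antagonists	B01AC04|B01AC05|B01AC22|B01AC24
Oral anticoagulations	B01AA|B01AE07|B01AF01|B01AF02	OAC
Non-vitamin K antagonist oral anticoagulants	B01AE07|B01AF01|B01AF02	NOAC
Rivaroxaban	B01AF01
Apixaban	B01AF02
Dabigatran	B01AE07
Aspirin	B01AC06	ASS
Dipyridamole	B01AC07
Digoxin	C01AA05
Diuretics	C03
Thiazide diuretics	C03A
Hydrochlorothiazide	C03AA03	HCT
Loop diuretics	C03C
Furosemide	C03CA01
Hydrochlorothiazide; triamterene	C03EA01
Beta blockers	C07
Metoprolol	C07AB02
Atenolol	C07AB03
Carvedilol	C07AG02
Calcium channel blockers	C08	CCB
Amlodipine	C08CA01
Nifedipine	C08CA05
Verapamil	C08DA01
Diltiazem	C08DB01
RAAS	C09
ACE inhibitors	C09A	ACEI
Lisinopril	C09AA03
Lisinopril; hydrochlorothiazide	C09BA03
Angiotensin receptor blockers	C09C	ARB
Losartan	C09CA01
Valsartan	C09CA03
Olmesartan	C09CA08
Non-steroidal antiinflammatory drugs	M01A	NSAID
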