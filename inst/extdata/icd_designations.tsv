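designation	codes	abbr
Abnormal liver function	K77
Alcohol abuse	F10
Atrial fibrillation	I48	AF
Bleeding	R58
Chronic kidney disease	N18	CKD
Deep vein thrombosis	I82
Diabetes mellitus type 2	E11	T2DM
Heart failure	I50
Hypertension	I10	HT
Ischemic heart disease	I20|I21|I22|I23|I24|I25
Myocardial infarction	I21
Peripheral artery disease	I73.9
Pregnant	O00|O10|O20|O30|O40|O50|O60|O70|O80|O90
Pulmonary embolism	I26
Stroke	I63
Valvular disease	I05|I06|I07|I08|I09|I34|I35|I36|I37|Q22|Q23
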