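pattern	label	historical
Diagnosen	diagnoses	0
Diagnoses	diagnoses	0
Diagnosis	diagnoses	0
Medikation	medication	0
Medikation bei Entlassung	medication	0
Medikamente bei Entlassung	medication	0
Entlassmedikation	medication	0
Medikation bei Aufnahme	medication	1
Medikamente bei Aufnahme	medication	1
Vormedikation	medication	1
Medication	medication	0
Medication at discharge	medication	0
Medication on admission	medication	1
Labor	laboratory	0
Laborwerte	laboratory	0
Laboratory	laboratory	0
Befunde	other	0
Anamnese	other	0
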