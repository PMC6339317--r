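phrase	category	direction	terminators
kein	negation	forward	aber
keine	negation	forward	aber
keinen	negation	forward	aber
nicht	negation	forward	aber
ohne	negation	forward	aber
no	negation	forward	but
not	negation	forward	but
denied	negation	backward	but
verneint	negation	backward	aber
abgesetzt	discontinuation	backward	aber
pausiert	discontinuation	backward	aber
beendet	discontinuation	backward	aber
gestoppt	discontinuation	backward	aber
discontinued	discontinuation	backward	but
stopped	discontinuation	backward	but
bei Aufnahme	historical	bidirectional	aber
Vormedikation	historical	forward	aber
zuletzt	historical	forward	aber
bisherige Medikation	historical	forward	aber
on admission	historical	bidirectional	but
previously	historical	forward	but
Familienanamnese	other_subject	forward	aber
Mutter	other_subject	forward	aber
Vater	other_subject	forward	aber
family history	other_subject	forward	but
mother	other_subject	forward	but
father	other_subject	forward	but
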