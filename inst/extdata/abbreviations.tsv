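p	patient
pt	patient
pat	patient
med	medicatie
tel	telefonisch
mdl	maag darm lever
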