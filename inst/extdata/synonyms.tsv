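oesophagus	slokdarm
esophagus	slokdarm
oesofagus	slokdarm
hypertension	hypertensie
obstipatie	verstopping
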