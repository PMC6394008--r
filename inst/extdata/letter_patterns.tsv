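header	^(geachte|beste|dear)\b.*$
header	^aan:.*$
header	^betreft:.*$
footer	^(met vriendelijke groet|hoogachtend|kind regards|regards)\b.*$
footer	^(dr|drs)\..*$
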