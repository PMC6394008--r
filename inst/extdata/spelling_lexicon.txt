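patient
heeft
pijn
klachten
controle
bloeddruk
medicatie
gesprek
onderzoek
been
rug
hoofd
slokdarm
maag
darm
lever
hart
longen
gewicht
moe
koorts
hoest
verwijzing
uitslag
stabiel
goed
vandaag
week
huisarts
recept
afspraak
besproken
terminaal
palliatief
telefonisch
hypertensie
verstopping
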