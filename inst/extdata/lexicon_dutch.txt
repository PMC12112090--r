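# Dutch closed-vocabulary lexicon for future-tense scoring.
# Inflection sets are listed as separate entries (zal/zult/zullen;
# ga/gaat/gaan). "staat op het punt" / "staan op het punt" ('about to')
# are multiword token sequences.
language: dutch

[future]
zal
zult
zullen
ga
gaat
gaan
staat op het punt
staan op het punt

[modal]
kan
kunt
kunnen
zou
zouden
misschien
mogelijk
waarschijnlijk
zeker

[contractions]
z'n => zijn
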