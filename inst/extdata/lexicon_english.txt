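# English closed-vocabulary lexicon for future-tense scoring.
# Sections: [future] markers (one token sequence per line), [modal] markers
# (high- and low-certainty; any of these suppresses both classes), and
# [contractions] rewrite rules applied before tokenization (surface => canonical,
# applied in file order).
language: english

[future]
will
shall
going to
about to

[modal]
can
could
may
might
should
would
possibly
probably
perhaps
maybe
definitely
certainly
likely

[contractions]
won't => will not
shan't => shall not
can't => can not
cannot => can not
'll => will
gonna => going to
n't => not
'm => am
're => are
've => have
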