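lemma	word_class	category	gloss	log_freq
schaatser	noun	sport	skater	NA
wielrenner	noun	sport	cyclist	NA
voetballer	noun	sport	footballer	NA
surfer	noun	sport	surfer	NA
zwemmer	noun	sport	swimmer	NA
atleet	noun	sport	athlete	NA
turner	noun	sport	gymnast	NA
bokser	noun	sport	boxer	NA
cellist	noun	music	cellist	NA
saxofonist	noun	music	saxophonist	NA
violist	noun	music	violinist	NA
gitarist	noun	music	guitarist	NA
pianist	noun	music	pianist	NA
drummer	noun	music	drummer	NA
muzikant	noun	music	musician	NA
zanger	noun	music	singer	NA
vasthouden	verb	contact	hold	NA
aanvallen	verb	contact	attack	NA
wegduwen	verb	contact	push_away	NA
krabben	verb	contact	scratch	NA
schoppen	verb	contact	kick	NA
grijpen	verb	contact	grab	NA
trappen	verb	contact	kick2	NA
knijpen	verb	contact	squeeze	NA
opmerken	verb	perception	notice	NA
zien	verb	perception	see	NA
ontdekken	verb	perception	discover	NA
begluren	verb	perception	peep	NA
herkennen	verb	perception	recognize	NA
bekijken	verb	perception	look	NA
aanstaren	verb	perception	stare	NA
waarnemen	verb	perception	perceive	NA
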