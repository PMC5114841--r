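# Synonym <TAB> primary term. Primaries are never themselves synonyms.
opisthosoma	abdomen
opisthosomum	abdomen
tibial	tibia
femoral	femur
metatarsal	metatarsus
patellar	patella
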