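# Spider measurement glossary: term <TAB> category.
# Roman numerals I-IV are categorized as structures (leg enumerations);
# this is a glossary decision, not a parser rule.
carapace	structure
abdomen	structure
sternum	structure
leg	structure
i	structure
ii	structure
iii	structure
iv	structure
femur	structure
patella	structure
tibia	structure
metatarsus	structure
tarsus	structure
palpal tarsus	structure
coxa	structure
epigastrium	structure
epigastric furrow	structure
spiracle	structure
tracheal spiracle	structure
spinneret	structure
thoracic groove	structure
ocular area	structure
cephalic area	structure
eye	structure
chelicera	structure
globose	shape
oval	shape
elongate	shape
depressed	architecture
protruding	architecture
robust	architecture
present	architecture
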