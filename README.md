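# taxamat

Builds taxon–character matrices from telegraphic morphological
descriptions — the terse, verbless prose of taxonomic treatments
("Carapace globose, length 3.27 mm, width 2.70 mm.") — with a focus on
body-part measurement characters in spider descriptions. It is written
for systematists and biodiversity informaticians who need published
measurement data in matrix form for comparative or phylogenetic work,
and for anyone studying how description conventions (omitted units,
omitted structure words) affect automated character extraction.

## What it does

The pipeline turns a batch of descriptions into a matrix of exemplars
(rows) by characters (columns), where every character is named in the
*character of structure* style (`length of carapace`,
`distance of epigastrium-spiracle`):

1. **normalize** — make text self-contained: restore omitted units
   (`"tibia/metatarsus: I, 0.42/0.32"` →
   `"tibia/metatarsus: leg I, 0.42/0.32 mm"`) and the omitted word
   "leg"; report unmatched brackets and non-ASCII hyphens.
2. **extract** — segment statements and emit
   structure/character/value/unit records using a glossary of
   categorized terms. Character labels follow a specificity ladder: a
   measurement indicator (*length*, *wide*, …) licenses a specific
   label; a bare unit licenses only *size*; neither, only *quantity*.
   Compound expressions are aligned positionally: slash templates
   (`Length of tibia/metatarsus: leg I, 0.52/0.44 mm`), leg
   enumerations, multi-character lists (`Tibial lengths and indices:
   leg II 1.73 mm, 7`), and distance statements (`Epigastric furrow
   0.74 mm from tracheal spiracle`).
3. **matricize** — consolidate records into a matrix; optionally
   inherit values down taxonomic ranks and infer presence of whole
   structures from recorded parts (a part-of graph closure).
4. **edit** — auditable column operations (merge, rename, delete,
   split) with effort accounting: delete and rename cost 1, a merge of
   *k* columns costs *k* − 1, splits are tallied separately.
5. **evaluate** — score against a gold matrix with
   `accuracy = |correct| / |extracted|`,
   `precision = |matched| / |produced non-null items|`,
   `recall = |matched| / |gold items|`, and
   `F1 = 2PR / (P + R)`, overall and per exemplar / per character.

A seeded generator (`synth_generate`) emits spider-style corpora with
known gold records, and `synth_degrade` re-introduces the conventions
(omitted units and "leg", ambiguous clauses, missing values) so the
self-contained-vs-original comparison can be reproduced end to end.

## Worked example

```r
library(taxamat)
g <- default_glossary()
d <- description_doc("Aysha prospera", paste(
  "Total length 7.58 mm. Carapace globose, length 3.27 mm, width 2.70 mm.",
  "Length of tibia/metatarsus: leg I, 0.52/0.44 mm; leg II, 0.50/0.40 mm;",
  "leg III, 0.24 mm; leg IV, 0.40/0.30 mm."), exemplar_tag = "male")
ann <- extract_records(d, g)
ann$records[, c("entity", "character", "value", "unit", "tier")]
#>                entity character value unit     tier
#> 1      whole-organism    length  7.58   mm specific
#> 2            carapace    length  3.27   mm specific
#> 3            carapace     width  2.70   mm specific
#> 4         leg-i tibia    length  0.52   mm specific
#> 5    leg-i metatarsus    length  0.44   mm specific
#> 6        leg-ii tibia    length  0.50   mm specific
#> 7   leg-ii metatarsus    length  0.40   mm specific
#> 8       leg-iii tibia    length  0.24   mm specific
#> 9  leg-iii metatarsus    length  <NA> <NA> specific
#> 10       leg-iv tibia    length  0.40   mm specific
#> 11  leg-iv metatarsus    length  0.30   mm specific

build_matrix(list(ann))
#> <taxon_matrix> 1 taxa x 11 characters, 10 non-empty cells
```

Every value keeps its exact decimal spelling and unit. The compound
statement contributes one record per leg and component; leg III names
only one value, so its metatarsus record is null (the matrix cell stays
empty) rather than silently dropped. "Total length" attaches to the
whole organism, and the bare measurement clauses attach to the sentence
subject (carapace).

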