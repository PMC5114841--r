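---
title: "From telegraphic descriptions to taxon-character matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From telegraphic descriptions to taxon-character matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxamat)
```

## The extraction model

Telegraphic taxonomic descriptions state measurement facts in a small
number of recurring syntactic shapes. `taxamat` models a description as
a sequence of *statements* (sentences), each a set of semicolon groups
of comma clauses, and extracts one record per
structure/character/value/unit observation. The model rests on three
assumptions that hold for measurement-style descriptions and are the
package's scope boundary:

* **Structures are glossary terms.** An anatomical structure is
  whatever the glossary categorizes as `structure`; the parser never
  guesses. This includes domain-specific acts such as categorizing the
  Roman numerals I–IV as structures so that leg enumerations parse even
  when the word "leg" is omitted. Multiword terms ("thoracic groove")
  are matched greedily, longest first, because their single-word parts
  may also be terms.
* **Character labels are licensed by clues.** A measurement indicator
  (*length*, *long*, *width*, *wide*, *distance*, *index*, …) licenses
  the specific label it maps to. Without an indicator a unit token
  licenses only the general label *size*; with neither clue the record
  can only be labelled *quantity*. This ladder is the mechanism by
  which less self-contained text degrades gracefully instead of
  failing: stripping units from a corpus changes labels, never the
  captured values.
* **Compound expressions align positionally.** A slash template
  (`tibia/metatarsus`) maps component-wise onto slash-separated values;
  an enumeration of structures maps index-wise onto its value list; a
  multi-character header (`lengths and indices`) maps onto the
  comma-separated items of each group. Groups that name fewer values
  than the template has components produce *null* records for the
  trailing components — explicit value-less placeholders, so a missing
  measurement is visible rather than silently absent. A trailing unit
  distributes over every value of its list.

One genuinely open choice is where a measurement clause with no
structure of its own attaches. The package attaches it to the
*sentence subject* — the first structure mentioned in the sentence —
because intervening clauses ("Carapace globose, thoracic groove on
depressed area, length 3.27 mm") almost always interpose a sub-part
while the measurements belong to the subject, and because this rule is
simple enough to reason about and test. The alternative,
nearest-preceding-structure, is available as
`extract_config(attachment = "nearest")`; the two rules differ exactly
on such ambiguous sentences. "Total length" is special-cased to the
whole organism (canonical entity `whole-organism`).

Distance statements (`A 0.74 mm from B`) are recognized as a pattern
and labelled `distance` only when a unit licenses the measurement
reading; the entity is the literal hyphenated pair in textual order.
No term approximation is performed (an epigastric furrow is *not*
silently equated with the epigastrium): approximation is a curatorial
decision and belongs in the synonym table or the edit script, where it
is auditable.

## Normalization

Two conventions dominate un-self-contained measurement text: omitted
units and the omitted word "leg" before Roman numerals.

`add_units()` appends the unit after every *maximal run of
decimal-point numbers* (chained by commas or slashes) not already
followed by a unit token. Keying the insertion on decimal numbers is
what makes it both idempotent and exactly invertible on this corpus
style: measurement values are printed with two decimals while indices
and counts are bare integers, so `"leg II 1.73, 7"` becomes
`"leg II 1.73 mm, 7"` and never `"… 7 mm"`. `add_leg()` prefixes bare
upper-case numerals I–IV with `"leg "`, but only in sentences that
show measurement context (decimal values, a measurement indicator, or
a colon-headed list), so prose numerals are left alone. Both
operations preserve every numeric token and its order, and both are
idempotent; the package's tests assert
`normalize(degrade(x)) == x` byte-for-byte on generated corpora.

`preprocess_check()` reports, rather than repairs: unmatched and
mismatched brackets with positions (a closer that skips an opener is
reported once as mismatched, the skipped opener once as unmatched) and
non-ASCII hyphen variants. OCR-style character damage is out of scope.

## Matrix semantics

Records consolidate into a matrix with one row per exemplar document
and one column per canonical character name, spelled
`"<character> of <entity path>"` in lower case with hyphen-joined
multiword terms (`length of leg-i tibia`). Cells hold exact value
strings with their unit (`"0.52 mm"`); trailing zeros are preserved so
CSV output is bit-reproducible. An empty cell means *no data*; the
marker `"?"` is an *explicit-missing* state, kept distinct because a
gold standard may score it. `fullness()` counts `"?"` as empty by
default for the same reason. When two records claim one cell the first
wins and the conflict is logged — descriptions occasionally restate a
measurement, and silently averaging or overwriting would hide the
problem.

Value inheritance (higher rank fills empty lower-rank cells, nearest
ancestor first) and presence inference (a recorded part implies the
presence of its partonomy ancestors) are both off by default, both
idempotent, and never overwrite existing values; presence inference
reports, and refuses to overwrite, an explicit `absent`.

## Edits and effort

Matrix review is an ordered, replayable script of column operations
serialized as JSON lines. Effort accounting follows the
column-operation cost model: delete = 1, rename = 1, merge of *k*
sources = *k* − 1 (merging never double-counts as renaming), and
splits are tallied separately because a split is a repair of compound
extraction rather than a curatorial alignment. Splitting distributes a
compound cell's slash values positionally and the shared unit to every
part; the new column names substitute the slash template when the old
name contains one (`length of tibia/metatarsus` → `length of tibia`)
and otherwise append `"(split, <component>)"`.

## Evaluation

`precision_recall_f1()` compares cells on exact decimal value, unit,
and column identity: `1.35` does not match `1.35 mm`, nor `1.350`, nor
a relabelled column. Precision runs over the machine matrix's non-null
items (a produced `"?"` is not an item); recall runs over gold items,
where any stated gold cell — including an explicit `"?"` — is an item
and an empty gold cell is not. This reading of "including null values"
is the only one consistent with per-character scores near 1 on nearly
full gold columns; treating every empty gold cell as an item would
depress recall toward the fullness of the matrix. Percentages are
rendered half-up at two decimals (`percent()`); all arithmetic is done
on full-precision fractions.

`record_accuracy()` scores extracted records against generator gold by
multiset matching, in two modes: *strict* (entity, label, value, and
unit must all agree — a missing unit makes an item wrong) and *value*
(value multisets only), separating labelling damage from value-capture
damage.

## The synthetic corpus generator

`synth_generate()` emulates the sentence inventory of spider
measurement descriptions: a total-length statement, subject-attached
length/width clauses for carapace and abdomen, a four-leg enumeration,
a slash-compound statement (femur/patella), a multi-character tibial
lengths-and-indices statement, and a distance statement. Defaults are
the study conditions: 188 exemplars, all templates enabled, values
drawn uniformly per character on millimetre ranges a spider worker
would recognize (total length 2–12 mm, carapace length 1–5 mm, leg
articles 0.2–3 mm, tibial indices as integers 5–15) and quantized to
two decimals, matching the printed style of the source corpora. One
seeded RNG stream makes the corpus and gold byte-reproducible.

`synth_degrade()` re-introduces the conventions: `omit_units` strips
the unit after every value, `omit_leg` strips "leg" before numerals
(both exactly inverted by normalization), `ambiguous_clause` interposes
a structure clause between subject and measurements, and
`missing_values` drops one slash-pair component per compound statement.
Degrading with units and "leg" omitted collapses strict record accuracy
to 0 while value-only agreement stays 1, and normalization restores
strict accuracy to 1 — the directionality the original-vs-normalized
comparison is about.

What the generator does *not* emulate bounds what passing tests show:
real descriptions carry categorical characters, spination codes,
typographic noise, non-parallel phrasing, and genuinely ambiguous
sentences whose correct reading needs domain judgment. Perfect recovery
on synthetic corpora demonstrates that the parsing rules implement the
stated conventions exactly, not that those conventions exhaust real
corpora.

## Numerical and procedural choices

* Values are kept as exact decimal strings alongside their numeric
  reading; ranges (`0.42–0.52`) are preserved as ranges.
* Missing markers default to `missing`, `-`, `lost` and are
  configurable.
* Synonym tables resolve in one hop by construction (a primary term may
  not itself be a synonym), which makes `apply_synonyms()` idempotent.
* Validation sizes: property tests run at 5–20 exemplars; the recovery
  and directionality checks at 100 exemplars; partonomy closure is
  cross-checked against graph reachability on random DAGs of up to 20
  nodes.

## Known limitations

* Categorical characters pass through term categorization only; their
  state semantics (is *protruding* an orientation or a relief?) are not
  modelled.
* Attachment uses pattern rules, not syntactic parse trees; sentences
  whose correct attachment needs syntax (or expert knowledge) are
  exactly where the subject/nearest switch matters, and neither rule is
  always right.
* Codified spination strings are not parseable by design.
* The batch format and annotation schema are this package's own
  documented formats; no third-party exchange schema is emulated.
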