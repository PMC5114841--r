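# Shared fixtures, built in code.

spider_glossary <- function() default_glossary()

# minimal glossary for focused parser tests
tiny_glossary <- function() {
  term_glossary(
    c(carapace = "structure", abdomen = "structure", leg = "structure",
      i = "structure", ii = "structure", iii = "structure",
      iv = "structure", tibia = "structure", metatarsus = "structure",
      epigastrium = "structure", spiracle = "structure",
      "epigastric furrow" = "structure",
      "tracheal spiracle" = "structure"),
    synonyms = c(opisthosoma = "abdomen", tibial = "tibia"))
}

# small populated matrix: 2 taxa x 2 characters with one empty cell
toy_matrix <- function() {
  m <- taxon_matrix(c("Taxon_A", "Taxon_B"),
                    c("length of carapace", "width of carapace"))
  m$cells["Taxon_A", "length of carapace"] <- "3.27 mm"
  m$cells["Taxon_A", "width of carapace"] <- "2.70 mm"
  m$cells["Taxon_B", "length of carapace"] <- "2.30 mm"
  m
}

records_of <- function(docs, g = spider_glossary(), ...) {
  ann <- lapply(docs, extract_records, glossary = g, ...)
  do.call(rbind, lapply(ann, `[[`, "records"))
}

core_cols <- c("taxon", "entity", "character", "value", "unit", "tier")

expect_same_records <- function(got, want) {
  a <- got[, core_cols]
  b <- want[, core_cols]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
}
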