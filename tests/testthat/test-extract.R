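g <- tiny_glossary()

test_that("segment splits sentences, semicolon groups, and comma clauses", {
  s <- segment("Carapace globose, length 3.27 mm, width 2.70 mm.")
  expect_length(s, 1L)
  expect_length(s[[1]]$groups, 1L)
  expect_length(s[[1]]$groups[[1]]$clauses, 3L)

  s5 <- segment(paste0("Length of tibia/metatarsus: leg I, 0.52/0.44 mm; ",
                       "leg II, 0.50/0.40 mm; leg III, 0.24 mm; ",
                       "leg IV, 0.40/0.30 mm."))
  expect_length(s5, 1L)
  expect_length(s5[[1]]$groups, 4L)

  two <- segment("Total length 7.58 mm. Carapace globose.")
  expect_length(two, 2L)
  # offsets point back into the original text
  txt <- "Total length 7.58 mm. Carapace globose."
  expect_identical(substr(txt, two[[2]]$start, two[[2]]$end),
                   "Carapace globose.")
  expect_identical(segment(""), list())
})

test_that("the label ladder degrades specific -> size -> quantity", {
  expect_identical(label_character("length", "mm"),
                   list(name = "length", tier = "specific"))
  expect_identical(label_character("wide", NA),
                   list(name = "width", tier = "specific"))
  expect_identical(label_character(NA, "mm"),
                   list(name = "size", tier = "size"))
  expect_identical(label_character(NA, NA),
                   list(name = "quantity", tier = "quantity"))
  expect_error(label_character("girth", "mm"), "unknown")
})

test_that("measurement clauses attach to the sentence subject", {
  r <- extract_measurements(
    paste0("Carapace globose, thoracic groove on depressed area, ",
           "length 3.27 mm, width 2.70 mm."), spider_glossary())
  expect_identical(r$entity, c("carapace", "carapace"))
  expect_identical(r$character, c("length", "width"))
  expect_identical(r$value, c("3.27", "2.70"))
  expect_identical(r$unit, c("mm", "mm"))

  # the alternative attachment rule is a configuration switch
  r2 <- extract_measurements(
    paste0("Carapace globose, thoracic groove on depressed area, ",
           "length 3.27 mm."), spider_glossary(),
    extract_config(attachment = "nearest"))
  expect_identical(r2$entity, "thoracic-groove")
})

test_that("enumerations align structures and values positionally", {
  r <- extract_measurements("I, II, III, IV length: 1.23, 1.35, 1.27, 1.28 mm",
                            g)
  expect_identical(nrow(r), 4L)
  expect_identical(r$value[r$entity == "ii"], "1.35")
  expect_identical(unique(r$unit), "mm")    # trailing unit distributes
  expect_identical(unique(r$character), "length")
  expect_identical(unique(r$tier), "specific")

  expect_warning(
    extract_measurements("I, II length: 1.23, 1.35, 1.27 mm", g),
    "arity mismatch")
})

test_that("Total length attaches to the whole organism", {
  d <- description_doc("A", paste0("Abdomen extremely elongate, legs very ",
                                   "long, including leg III. ",
                                   "Total length 7.58 mm."))
  r <- extract_records(d, g)$records
  expect_identical(nrow(r), 1L)
  expect_identical(r$entity, "whole-organism")
  expect_identical(r$character, "length")
  expect_identical(r$value, "7.58")
})

test_that("statements without numerals yield no measurement records", {
  expect_identical(nrow(extract_measurements("Carapace globose.", g)), 0L)
})

test_that("slash compounds map template components onto value pairs", {
  s5 <- paste0("Length of tibia/metatarsus: leg I, 0.52/0.44 mm; ",
               "leg II, 0.50/0.40 mm; leg III, 0.24 mm; ",
               "leg IV, 0.40/0.30 mm.")
  r <- extract_compound(s5, g)
  expect_identical(nrow(r), 8L)
  expect_identical(r$value[r$entity == "leg-i tibia"], "0.52")
  expect_identical(r$value[r$entity == "leg-i metatarsus"], "0.44")
  # leg III gives only one value: tibia gets it, metatarsus is null
  expect_identical(r$value[r$entity == "leg-iii tibia"], "0.24")
  expect_true(is.na(r$value[r$entity == "leg-iii metatarsus"]))
  expect_identical(length(unique(r$compound_group)), 1L)
  expect_identical(unique(r$character), "length")
  expect_identical(unique(r$unit[!is.na(r$unit)]), "mm")

  # a header without a slash template is not a compound statement
  expect_null(extract_compound("Leg I length: 0.52 mm.", g))
})

test_that("multi-character lists align header characters with value groups", {
  s6 <- paste0("Tibial lengths and indices: leg I missing; ",
               "leg II 1.73 mm, 7; leg III 0.96 mm, 13; leg IV 2.02 mm, 7.")
  r <- extract_multicharacter(s6, g)
  expect_identical(nrow(r), 8L)
  expect_identical(r$value[r$entity == "leg-ii tibia" &
                             r$character == "length"], "1.73")
  expect_identical(r$unit[r$entity == "leg-ii tibia" &
                            r$character == "length"], "mm")
  expect_identical(r$value[r$entity == "leg-ii tibia" &
                             r$character == "index"], "7")
  expect_identical(r$value[r$entity == "leg-iii tibia" &
                             r$character == "index"], "13")
  # "leg I missing" -> null records for both characters
  legi <- r[r$entity == "leg-i tibia", ]
  expect_identical(nrow(legi), 2L)
  expect_true(all(is.na(legi$value)))

  expect_null(extract_multicharacter("Tibial lengths: leg I 1.73 mm.", g))
  expect_warning(
    extract_multicharacter("Tibial lengths and indices: leg I 1.73 mm.", g),
    "arity mismatch")
})

test_that("distance statements capture the structure pair in textual order", {
  r <- extract_distance("Epigastric furrow 0.74 mm from tracheal spiracle.",
                        g)
  expect_identical(r$entity, "epigastric-furrow-tracheal-spiracle")
  expect_identical(r$character, "distance")
  expect_identical(r$value, "0.74")
  expect_identical(r$unit, "mm")

  r2 <- extract_distance("Spiracle 0.60 mm from epigastrium", g)
  expect_identical(r2$entity, "spiracle-epigastrium")

  expect_null(extract_distance("Carapace globose, length 3.27 mm.", g))
})

test_that("extraction is deterministic on identical input", {
  sim <- synth_generate(synth_params(n_exemplars = 4, seed = 2))
  a <- records_of(sim$docs)
  b <- records_of(sim$docs)
  expect_identical(a, b)
})

test_that("stripping units changes labels, never counts or values", {
  sim <- synth_generate(synth_params(n_exemplars = 6, seed = 13))
  full <- records_of(sim$docs)
  deg <- parse_batch(synth_degrade(sim$batch, "omit_units", seed = 13))
  bare <- records_of(deg)
  expect_identical(nrow(bare), nrow(full))
  expect_identical(sort(bare$value[!is.na(bare$value)]),
                   sort(full$value[!is.na(full$value)]))
  expect_identical(bare$entity, full$entity)
  # the distance statement loses its licensing unit: specific -> quantity
  expect_identical(
    unique(full$character[full$entity == "epigastrium-spiracle"]),
    "distance")
  expect_identical(
    unique(bare$character[bare$entity == "epigastrium-spiracle"]),
    "quantity")
  # indicator-bearing clauses keep their specific labels without units
  expect_identical(unique(bare$character[bare$entity == "carapace"]),
                   c("length", "width"))
})
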