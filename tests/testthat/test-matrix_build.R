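test_that("build_matrix keeps one row per exemplar and conserves records", {
  docs <- list(description_doc("A", "Total length 7.58 mm."),
               description_doc("B", "Total length 6.10 mm."))
  ann <- lapply(docs, extract_records, glossary = tiny_glossary())
  m <- build_matrix(ann)
  expect_identical(dim(m), c(2L, 1L))
  expect_identical(colnames(m$cells), "length of whole-organism")
  expect_identical(unname(m$cells[, 1]), c("7.58 mm", "6.10 mm"))

  # docs without records still contribute rows (and no columns)
  empty <- build_matrix(list(annotated_doc(description_doc("C", "x"))))
  expect_identical(dim(empty), c(1L, 0L))
})

test_that("duplicate claims on one cell keep the first value with a warning", {
  d <- description_doc("A", "Total length 7.58 mm. Total length 9.99 mm.")
  ann <- extract_records(d, tiny_glossary())
  expect_warning(m <- build_matrix(list(ann)), "keeping first")
  expect_identical(unname(m$cells[1, "length of whole-organism"]), "7.58 mm")
  expect_identical(attr(m, "conflicts_dropped"), 1L)
})

test_that("non-empty cells plus dropped conflicts equal non-null records", {
  sim <- synth_generate(synth_params(n_exemplars = 12, seed = 4))
  ann <- lapply(sim$docs, extract_records, glossary = spider_glossary())
  m <- build_matrix(ann)
  recs <- do.call(rbind, lapply(ann, `[[`, "records"))
  dropped <- attr(m, "conflicts_dropped")
  if (is.null(dropped)) dropped <- 0L
  expect_identical(sum(nzchar(m$cells)) + dropped,
                   sum(!is.na(recs$value)))
})

test_that("fullness is the populated fraction, explicit-missing excluded", {
  m <- taxon_matrix(paste0("t", 1:188), paste0("c", 1:41))
  m$cells[seq_len(2942)] <- "1.00 mm"
  expect_equal(percent(fullness(m)), 38.17)

  m2 <- taxon_matrix(paste0("t", 1:188), paste0("c", 1:43))
  m2$cells[seq_len(2914)] <- "1.00 mm"
  expect_equal(percent(fullness(m2)), 36.05)

  m3 <- toy_matrix()
  m3$cells[] <- "x"
  expect_identical(fullness(m3), 1)
  m3$cells[1, 1] <- "?"
  expect_identical(fullness(m3), 0.75)
  expect_identical(fullness(m3, count_missing = TRUE), 1)
  expect_error(fullness(taxon_matrix(character(), character())),
               "zero-dimension")
})

test_that("inherit_values fills empty descendants from the nearest ancestor", {
  m <- taxon_matrix(c("Family_X", "Genus_Y", "Species_Z"),
                    "length of carapace")
  m$cells["Family_X", 1] <- "3.00 mm"
  m$cells["Species_Z", 1] <- "2.50 mm"
  lin <- list(Species_Z = c("Genus_Y", "Family_X"),
              Genus_Y = "Family_X")
  out <- inherit_values(m, lin)
  expect_identical(unname(out$cells["Genus_Y", 1]), "3.00 mm")
  # existing values are never overwritten
  expect_identical(unname(out$cells["Species_Z", 1]), "2.50 mm")
  # idempotent; empty lineage is the identity
  expect_identical(inherit_values(out, lin)$cells, out$cells)
  expect_identical(inherit_values(m, list())$cells, m$cells)
})

test_that("presence of a part implies presence of its whole", {
  m <- taxon_matrix("A", "length of leg-cusple")
  m$cells[1, 1] <- "0.10 mm"
  g <- partonomy_graph(child = c("leg-cusple", "leg-article"),
                       parent = c("leg-article", "leg"))
  out <- infer_presence(m, g)
  expect_identical(unname(out$cells[1, "presence of leg"]), "present")
  expect_identical(unname(out$cells[1, "presence of leg-article"]),
                   "present")
  # idempotent; empty graph is the identity
  again <- infer_presence(out, g)
  expect_identical(again$cells, out$cells)
  expect_identical(infer_presence(m, partonomy_graph())$cells, m$cells)
})

test_that("an explicit absence is never overwritten by inference", {
  m <- taxon_matrix("A", c("length of cusple", "presence of leg"))
  m$cells[1, "length of cusple"] <- "0.10 mm"
  m$cells[1, "presence of leg"] <- "absent"
  g <- partonomy_graph("cusple", "leg")
  out <- infer_presence(m, g)
  expect_identical(unname(out$cells[1, "presence of leg"]), "absent")
  expect_match(unlist(out$provenance), "contradiction", all = FALSE)
})

test_that("partonomy cycles are rejected", {
  expect_error(partonomy_graph(c("a", "b"), c("b", "a")), "cycle")
})

test_that("presence closure equals brute-force reachability", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (trial in 1:10) {
    n <- sample(5:20, 1)
    nodes <- paste0("s", seq_len(n))
    # random DAG: edges only from lower to higher index
    from <- integer(); to <- integer()
    for (i in seq_len(n - 1)) {
      k <- sample(0:min(2, n - i), 1)
      if (k > 0) {
        pool <- (i + 1):n
        tgt <- pool[sample.int(length(pool), k)]
        from <- c(from, rep(i, k)); to <- c(to, tgt)
      }
    }
    if (!length(from)) next
    pg <- partonomy_graph(nodes[from], nodes[to])
    seedling <- sample(nodes, 1)
    m <- taxon_matrix("T", paste("length of", seedling))
    m$cells[1, 1] <- "1.00 mm"
    out <- infer_presence(m, pg)
    pres <- grep("^presence of ", colnames(out$cells), value = TRUE)
    inferred <- sub("^presence of ", "",
                    pres[nzchar(out$cells[1, pres])])
    ig <- igraph::graph_from_data_frame(
      data.frame(from = nodes[from], to = nodes[to]),
      vertices = nodes)
    reach <- names(igraph::subcomponent(ig, seedling, mode = "out"))
    expect_setequal(inferred, setdiff(reach, seedling))
  }
})
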