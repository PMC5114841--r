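mk <- function(cols, rows = c("A", "B")) {
  m <- taxon_matrix(rows, names(cols))
  for (cn in names(cols)) {
    v <- cols[[cn]]
    m$cells[seq_along(v), cn] <- v
  }
  m
}

test_that("merge unions source cells into the destination and drops sources", {
  m <- mk(list("length of whole-organism" = c("7.58 mm", ""),
               "length of body" = c("", "6.10 mm")))
  out <- apply_edit(m, edit_op("merge",
                               c("length of whole-organism",
                                 "length of body"),
                               dest = "length of whole-organism"))
  expect_identical(colnames(out$cells), "length of whole-organism")
  expect_identical(unname(out$cells[, 1]), c("7.58 mm", "6.10 mm"))

  # per-taxon conflicts keep the destination value
  m2 <- mk(list(a = c("1 mm", ""), b = c("2 mm", "3 mm")))
  expect_warning(out2 <- apply_edit(m2, edit_op("merge", c("a", "b"),
                                                dest = "a")),
                 "keeping destination")
  expect_identical(unname(out2$cells[, "a"]), c("1 mm", "3 mm"))
})

test_that("rename relabels without touching cells; delete removes a column", {
  m <- mk(list("quantity of i tibia" = c("1.23", "1.40")))
  out <- apply_edit(m, edit_op("rename", "quantity of i tibia",
                               dest = "length of leg i tibia (new)"))
  expect_identical(colnames(out$cells), "length of leg i tibia (new)")
  expect_identical(unname(out$cells[, 1]), c("1.23", "1.40"))

  m2 <- mk(list(a = c("1", "2"), b = c("3", "4")))
  out2 <- apply_edit(m2, edit_op("delete", "a"))
  expect_identical(colnames(out2$cells), "b")
  expect_error(apply_edit(m2, edit_op("delete", "zz")), "unknown column")
})

test_that("split distributes compound cells positionally with the shared unit", {
  m <- mk(list("length of tibia/metatarsus" = c("0.52/0.44 mm", "0.24 mm")))
  out <- apply_edit(m, edit_op("split", "length of tibia/metatarsus",
                               components = c("tibia", "metatarsus")))
  expect_setequal(colnames(out$cells),
                  c("length of tibia", "length of metatarsus"))
  expect_identical(unname(out$cells["A", "length of tibia"]), "0.52 mm")
  expect_identical(unname(out$cells["A", "length of metatarsus"]),
                   "0.44 mm")
  # a single value fills the first component; the rest stay empty
  expect_identical(unname(out$cells["B", "length of tibia"]), "0.24 mm")
  expect_identical(unname(out$cells["B", "length of metatarsus"]), "")

  # names without a slash template gain a "(split, component)" suffix
  m2 <- mk(list("quantity of carapace" = c("3.27/2.70", "")))
  out2 <- apply_edit(m2, edit_op("split", "quantity of carapace",
                                 components = c("length", "width")))
  expect_setequal(colnames(out2$cells),
                  c("quantity of carapace (split, length)",
                    "quantity of carapace (split, width)"))
})

test_that("split conserves non-null component values; merges conserve cells", {
  m <- mk(list("length of tibia/metatarsus" =
                 c("0.52/0.44 mm", "0.24 mm")))
  before <- sum(lengths(regmatches(m$cells[, 1],
                                   gregexpr("\\d+\\.\\d+", m$cells[, 1]))))
  out <- apply_edit(m, edit_op("split", "length of tibia/metatarsus",
                               components = c("tibia", "metatarsus")))
  expect_identical(sum(nzchar(out$cells)), before)

  m2 <- mk(list(a = c("1 mm", ""), b = c("", "2 mm"), c = c("", "")))
  out2 <- apply_edit(m2, edit_op("merge", c("a", "b"), dest = "a"))
  expect_identical(sum(nzchar(out2$cells)),
                   sum(nzchar(m2$cells[, c("a", "b")])))
})

test_that("apply_script folds ops in order and logs affected values", {
  m <- mk(list(a = c("1", "2"), b = c("3", ""), c = c("", "4")))
  s <- edit_script(list(edit_op("rename", "a", dest = "a2"),
                        edit_op("merge", c("a2", "b"), dest = "a2"),
                        edit_op("delete", "c")))
  out <- suppressWarnings(apply_script(m, s))  # the merge conflict is the point
  # equals sequential application
  byhand <- suppressWarnings(
    apply_edit(apply_edit(apply_edit(m, s$ops[[1]]), s$ops[[2]]),
               s$ops[[3]]))
  attr(byhand, "affected") <- NULL
  expect_identical(out$cells, byhand$cells)
  log <- attr(out, "edit_log")
  expect_identical(log$kind, c("rename", "merge", "delete"))
  expect_identical(log$affected, c(2L, 3L, 1L))
  # empty script is the identity
  expect_identical(apply_script(m, edit_script())$cells, m$cells)
})

test_that("edit scripts round-trip through JSON lines", {
  s <- edit_script(list(
    edit_op("split", "quantity of ii", components = c("tibia", "metatarsus")),
    edit_op("rename", "quantity of ii (split, tibia)",
            dest = "length of leg ii tibia (new)"),
    edit_op("merge", c("x", "y", "z"), dest = "x"),
    edit_op("delete", "w")))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_edit_script(s, f)
  expect_equal(read_edit_script(f), s)

  m <- mk(list("quantity of ii" = c("1.1/2.2", ""), x = c("9", ""),
               y = c("", "8"), z = c("", ""), w = c("5", "")))
  expect_identical(apply_script(m, read_edit_script(f))$cells,
                   apply_script(m, s)$cells)
})

test_that("edit effort counts deletes and renames once, merges as k-1", {
  expect_identical(count_effort(edit_script()),
                   c(edits = 0L, splits = 0L))
  six <- edit_script(list(edit_op("merge", paste0("c", 1:6), dest = "c1")))
  expect_identical(count_effort(six)[["edits"]], 5L)
  s <- edit_script(list(
    edit_op("delete", "a"),
    edit_op("rename", "b", dest = "b2"),
    edit_op("merge", c("c", "d", "e"), dest = "c"),
    edit_op("split", "f/g", components = c("f", "g"))))
  expect_identical(count_effort(s), c(edits = 4L, splits = 1L))
})

test_that("malformed edit operations are rejected", {
  expect_error(edit_op("merge", "only-one", dest = "x"), "at least two")
  expect_error(edit_op("rename", "a"), "destination")
  expect_error(edit_op("split", "a", components = "one"), "at least two")
})
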