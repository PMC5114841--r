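#' Accuracy of extracted data items
#'
#' The proportion of extracted data items judged correct, i.e. consistent
#' with the source description (which is a weaker requirement than matching
#' a gold standard: "length of ii = 1.35 mm" is correct for an enumeration
#' over bare numerals even if the gold matrix spells the column "length of
#' leg ii").
#'
#' @param correct,extracted item counts, \code{extracted >= correct >= 0},
#'   \code{extracted > 0}.
#' @return The fraction \code{correct / extracted}.
#' @seealso [percent()] for the 2-decimal half-up percentage rendering.
#' @export
accuracy <- function(correct, extracted) {
  if (extracted <= 0) stop("accuracy is undefined when no items were extracted")
  stopifnot(correct >= 0, correct <= extracted)
  correct / extracted
}

#' Render a fraction as a percentage
#'
#' Rounds half-up to \code{digits} decimals (so 0.98835 renders as 98.84,
#' not bankers-rounded); fractions are kept at full precision internally
#' and only rendered through this helper.
#'
#' @param x fraction(s) in \code{[0, 1]}.
#' @param digits decimal places (default 2).
#' @return Numeric percentage value(s).
#' @export
percent <- function(x, digits = 2) {
  f <- 10^digits
  floor(x * 100 * f + 0.5 + 1e-9) / f
}

#' Do two matrix cells match?
#'
#' Cells match only on full agreement: identical numeric value (exact
#' decimal string comparison, so "1.35" never matches "1.350"), identical
#' unit, in the same character column. A value missing its unit does not
#' match the same value with one. Explicit-missing \code{"?"} cells match
#' only other \code{"?"} cells.
#'
#' @param produced,gold cell strings aligned on the same (taxon, character).
#' @return Logical vector.
#' @export
match_cell <- function(produced, gold) {
  norm <- function(x) gsub("\\s+", " ", trimws(x))
  norm(produced) == norm(gold) & nzchar(norm(gold))
}

#' Precision, recall and F1 of a matrix against a gold standard
#'
#' Precision is the proportion of the machine matrix's data items (its
#' non-null cells) that match the gold standard; recall is the proportion
#' of gold data items -- gold cells carrying any state, explicit-missing
#' \code{"?"} included -- that the machine matrix reproduces; F1 is their
#' harmonic mean. Besides the overall scores the report carries the same
#' metrics restricted to each exemplar row and each character column, with
#' mean, population standard deviation, min and max summaries.
#'
#' @param m the machine \code{taxon_matrix}.
#' @param gold the gold \code{taxon_matrix}; must have the same taxon
#'   labels (any order).
#' @return An object of class \code{eval_report}: a list with
#'   \code{precision}, \code{recall}, \code{f1}, \code{counts},
#'   \code{per_exemplar}, \code{per_character} and \code{summary}.
#' @export
precision_recall_f1 <- function(m, gold) {
  stopifnot(inherits(m, "taxon_matrix"), inherits(gold, "taxon_matrix"))
  unmatched <- c(setdiff(m$taxa, gold$taxa), setdiff(gold$taxa, m$taxa))
  if (length(unmatched))
    stop("taxon labels not shared by both matrices: ",
         paste(unique(unmatched), collapse = ", "))
  chars <- union(colnames(m$cells), colnames(gold$cells))
  pad <- function(x) {
    add <- setdiff(chars, colnames(x$cells))
    if (length(add))
      x$cells <- cbind(x$cells,
                       matrix("", nrow = nrow(x$cells),
                              dimnames = list(NULL, add)))
    x$cells[, chars, drop = FALSE]
  }
  mc <- pad(m)
  gc <- pad(gold)[match(m$taxa, gold$taxa), , drop = FALSE]
  dm <- function(x) array(x, dim = dim(mc), dimnames = dimnames(mc))
  matched <- dm(match_cell(mc, gc) & nzchar(mc))
  prod_items <- dm(is_filled(mc))          # null values excluded
  gold_items <- dm(nzchar(gc))             # "?" included
  matched_nonnull <- matched & prod_items
  prf <- function(mn, ma, p_den, r_den) {
    p <- if (p_den > 0) mn / p_den else NA_real_
    r <- if (r_den > 0) ma / r_den else NA_real_
    f <- if (!is.na(p) && !is.na(r) && (p + r) > 0) 2 * p * r / (p + r)
         else if (!is.na(p) && !is.na(r)) 0
         else NA_real_
    c(precision = p, recall = r, f1 = f)
  }
  overall <- prf(sum(matched_nonnull), sum(matched),
                 sum(prod_items), sum(gold_items))
  by_axis <- function(margin) {
    idx <- if (margin == 1L) seq_len(nrow(mc)) else seq_len(ncol(mc))
    t(vapply(idx, function(i) {
      sl <- function(x) if (margin == 1L) x[i, ] else x[, i]
      prf(sum(sl(matched_nonnull)), sum(sl(matched)),
          sum(sl(prod_items)), sum(sl(gold_items)))
    }, c(precision = 0, recall = 0, f1 = 0)))
  }
  per_ex <- data.frame(taxon = m$taxa, by_axis(1L),
                       stringsAsFactors = FALSE, row.names = NULL)
  per_ch <- data.frame(character = chars, by_axis(2L),
                       stringsAsFactors = FALSE, row.names = NULL)
  summarize <- function(df) {
    do.call(rbind, lapply(c("precision", "recall", "f1"), function(col) {
      v <- df[[col]][!is.na(df[[col]])]
      data.frame(metric = col, mean = mean(v),
                 sd = sqrt(mean((v - mean(v))^2)),  # population sd
                 min = min(v), max = max(v), n = length(v),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    precision = overall[["precision"]], recall = overall[["recall"]],
    f1 = overall[["f1"]],
    counts = c(matched = sum(matched), matched_nonnull = sum(matched_nonnull),
               produced_items = sum(prod_items),
               gold_items = sum(gold_items)),
    per_exemplar = per_ex, per_character = per_ch,
    summary = list(per_exemplar = summarize(per_ex),
                   per_character = summarize(per_ch))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> P = ", percent(x$precision), "%  R = ",
      percent(x$recall), "%  F1 = ", percent(x$f1), "%  (",
      x$counts[["matched"]], "/", x$counts[["gold_items"]],
      " gold items matched)\n", sep = "")
  invisible(x)
}

#' Score extracted records against generator gold records
#'
#' Judges each produced non-null record against a gold record set by
#' multiset matching. \code{mode = "strict"} requires entity path,
#' character name, value and unit all to agree (a missing unit or a
#' label degraded to size/quantity makes the item wrong);
#' \code{mode = "value"} compares the value multisets only, measuring
#' whether the numbers themselves were captured regardless of labelling.
#'
#' @param produced,gold record data frames.
#' @param mode \code{"strict"} or \code{"value"}.
#' @return Fraction of produced non-null records matched.
#' @export
record_accuracy <- function(produced, gold, mode = c("strict", "value")) {
  mode <- match.arg(mode)
  p <- produced[!is.na(produced$value), , drop = FALSE]
  g <- gold[!is.na(gold$value), , drop = FALSE]
  if (!nrow(p)) stop("accuracy is undefined when no items were extracted")
  key <- function(df) {
    if (mode == "strict")
      paste(df$entity, df$character, df$value,
            ifelse(is.na(df$unit), "", df$unit), sep = "\r")
    else df$value
  }
  pk <- key(p); gk <- key(g)
  matched <- 0L
  gt <- table(gk)
  for (k in pk) {
    if (k %in% names(gt) && gt[[k]] > 0) {
      matched <- matched + 1L
      gt[[k]] <- gt[[k]] - 1L
    }
  }
  matched / nrow(p)
}

#' Write an evaluation report to JSON and CSV
#'
#' @param report an \code{eval_report}.
#' @param json_path output JSON path; per-axis tables are written next to
#'   it as \code{*_per_exemplar.csv} and \code{*_per_character.csv}.
#' @export
write_eval_report <- function(report, json_path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(
    list(precision = report$precision, recall = report$recall,
         f1 = report$f1,
         precision_pct = percent(report$precision),
         recall_pct = percent(report$recall),
         f1_pct = percent(report$f1),
         counts = as.list(report$counts)),
    json_path, auto_unbox = TRUE, digits = NA)
  stem <- sub("\\.json$", "", json_path)
  utils::write.csv(report$per_exemplar,
                   paste0(stem, "_per_exemplar.csv"), row.names = FALSE)
  utils::write.csv(report$per_character,
                   paste0(stem, "_per_character.csv"), row.names = FALSE)
  invisible(json_path)
}
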