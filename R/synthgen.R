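#' Parameters for the synthetic description generator
#'
#' The generator emits spider-style telegraphic descriptions in the
#' self-contained (fully unit- and structure-labelled) style, together
#' with the gold records and gold matrix they encode. Defaults mirror the
#' case-study corpus: 188 exemplars, all six sentence patterns enabled,
#' measurement values drawn uniformly on per-character ranges (in mm) and
#' quantized to two decimals, tibial indices as integers.
#'
#' @param n_exemplars number of exemplar documents.
#' @param seed integer seed; the same (params, seed) pair always yields a
#'   byte-identical corpus and gold standard.
#' @param templates subset of \code{c("total_length", "carapace",
#'   "abdomen", "leg_enum", "slash_compound", "multichar", "distance")}.
#' @param ranges named list of \code{c(lo, hi)} value ranges (mm).
#' @return A list of class \code{synth_params}.
#' @export
synth_params <- function(n_exemplars = 188, seed = 1L,
                         templates = c("total_length", "carapace",
                                       "abdomen", "leg_enum",
                                       "slash_compound", "multichar",
                                       "distance"),
                         ranges = list(
                           total_length = c(2, 12),
                           carapace_length = c(1, 5),
                           carapace_width = c(0.8, 4),
                           abdomen_length = c(1, 6),
                           abdomen_width = c(0.5, 3),
                           leg_length = c(0.2, 3),
                           distance = c(0.1, 2),
                           index = c(5, 15))) {
  templates <- match.arg(templates, several.ok = TRUE)
  structure(list(n_exemplars = n_exemplars, seed = as.integer(seed),
                 templates = templates, ranges = ranges),
            class = "synth_params")
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

rv <- function(range) sprintf("%.2f", stats::runif(1, range[1], range[2]))
ri <- function(range)
  as.character(sample(seq(range[1], range[2]), 1L))

gold_row <- function(taxon, entity, character, value, unit, tier)
  data.frame(doc_id = taxon, taxon = taxon, entity = entity,
             character = character, value = value, unit = unit,
             tier = tier, compound_group = NA_character_,
             statement = NA_integer_, start = NA_integer_,
             end = NA_integer_, stringsAsFactors = FALSE)

roman_upper <- c("I", "II", "III", "IV")

#' Generate a synthetic description corpus with its gold standard
#'
#' Each exemplar receives one description assembled from the enabled
#' sentence patterns, e.g.:
#'
#' \preformatted{
#' Total length 7.58 mm. Carapace globose, length 3.27 mm, width 2.70 mm.
#' Length of leg I, leg II, leg III, leg IV: 1.23, 1.35, 1.27, 1.28 mm.
#' Length of femur/patella: leg I, 0.52/0.44 mm; ...
#' Tibial lengths and indices: leg I 1.73 mm, 7; ...
#' Epigastrium 0.74 mm from spiracle.
#' }
#'
#' The gold standard holds every generated value under its canonical
#' character name ("length of leg-i femur"), so an extractor run over the
#' undegraded corpus can be scored for exact recovery.
#'
#' @param params a \code{synth_params}.
#' @return A list with \code{batch} (the batch text), \code{docs}
#'   (parsed \code{description_doc}s), \code{gold_records} (record data
#'   frame) and \code{gold_matrix} (a \code{taxon_matrix}).
#' @export
synth_generate <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, {
    docs <- list()
    gold <- list()
    for (i in seq_len(params$n_exemplars)) {
      taxon <- sprintf("Genus_%04d species_%04d", i, i)
      sex <- sample(c("male", "female"), 1L)
      sentences <- character()
      g <- list()
      rg <- params$ranges
      tpl <- params$templates
      if ("total_length" %in% tpl) {
        v <- rv(rg$total_length)
        sentences <- c(sentences, sprintf("Total length %s mm.", v))
        g <- c(g, list(gold_row(taxon, "whole-organism", "length", v,
                                "mm", "specific")))
      }
      if ("carapace" %in% tpl) {
        l <- rv(rg$carapace_length); w <- rv(rg$carapace_width)
        sentences <- c(sentences,
                       sprintf("Carapace globose, length %s mm, width %s mm.",
                               l, w))
        g <- c(g, list(gold_row(taxon, "carapace", "length", l, "mm",
                                "specific"),
                       gold_row(taxon, "carapace", "width", w, "mm",
                                "specific")))
      }
      if ("abdomen" %in% tpl) {
        l <- rv(rg$abdomen_length); w <- rv(rg$abdomen_width)
        sentences <- c(sentences,
                       sprintf("Abdomen oval, length %s mm, width %s mm.",
                               l, w))
        g <- c(g, list(gold_row(taxon, "abdomen", "length", l, "mm",
                                "specific"),
                       gold_row(taxon, "abdomen", "width", w, "mm",
                                "specific")))
      }
      if ("leg_enum" %in% tpl) {
        v <- vapply(1:4, function(k) rv(rg$leg_length), "")
        sentences <- c(sentences,
                       sprintf("Length of leg I, leg II, leg III, leg IV: %s mm.",
                               paste(v, collapse = ", ")))
        for (k in 1:4)
          g <- c(g, list(gold_row(taxon,
                                  paste0("leg-", tolower(roman_upper[k])),
                                  "length", v[k], "mm", "specific")))
      }
      if ("slash_compound" %in% tpl) {
        grp <- vapply(roman_upper, function(r)
          sprintf("leg %s, %s/%s mm", r, rv(rg$leg_length),
                  rv(rg$leg_length)), "")
        sentences <- c(sentences,
                       sprintf("Length of femur/patella: %s.",
                               paste(grp, collapse = "; ")))
        for (k in 1:4) {
          vals <- regmatches(grp[k],
                             gregexpr("\\d+\\.\\d+", grp[k]))[[1]]
          leg <- paste0("leg-", tolower(roman_upper[k]))
          g <- c(g, list(gold_row(taxon, paste(leg, "femur"), "length",
                                  vals[1], "mm", "specific"),
                         gold_row(taxon, paste(leg, "patella"), "length",
                                  vals[2], "mm", "specific")))
        }
      }
      if ("multichar" %in% tpl) {
        grp <- vapply(roman_upper, function(r)
          sprintf("leg %s %s mm, %s", r, rv(rg$leg_length),
                  ri(rg$index)), "")
        sentences <- c(sentences,
                       sprintf("Tibial lengths and indices: %s.",
                               paste(grp, collapse = "; ")))
        for (k in 1:4) {
          vals <- regmatches(grp[k],
                             gregexpr("\\d+\\.?\\d*", grp[k]))[[1]]
          leg <- paste0("leg-", tolower(roman_upper[k]))
          g <- c(g, list(gold_row(taxon, paste(leg, "tibia"), "length",
                                  vals[1], "mm", "specific"),
                         gold_row(taxon, paste(leg, "tibia"), "index",
                                  vals[2], NA_character_, "specific")))
        }
      }
      if ("distance" %in% tpl) {
        v <- rv(rg$distance)
        sentences <- c(sentences,
                       sprintf("Epigastrium %s mm from spiracle.", v))
        g <- c(g, list(gold_row(taxon, "epigastrium-spiracle", "distance",
                                v, "mm", "specific")))
      }
      docs[[i]] <- description_doc(taxon, paste(sentences, collapse = " "),
                                   rank = "species", exemplar_tag = sex)
      gold[[i]] <- bind_records(g)
    }
    gold_records <- bind_records(gold)
    gold_docs <- lapply(seq_along(docs), function(i)
      annotated_doc(docs[[i]], gold[[i]]))
    list(params = params,
         batch = write_batch(docs),
         docs = docs,
         gold_records = gold_records,
         gold_matrix = build_matrix(gold_docs))
  })
}

#' Degrade a corpus with the conventions of the original descriptions
#'
#' Re-introduces, in a controlled way, the space-saving conventions that
#' make real descriptions less self-contained:
#' \describe{
#'   \item{omit_units}{strips every unit token that follows a measurement
#'     value ("...: leg I, 0.42/0.32 mm" becomes "...: leg I, 0.42/0.32");
#'     [add_units()] inverts this exactly on generated corpora.}
#'   \item{omit_leg}{strips the word "leg" before Roman numerals I-IV;
#'     [add_leg()] inverts this exactly.}
#'   \item{ambiguous_clause}{inserts an intervening structure clause
#'     ("thoracic groove on depressed area") between a sentence subject and
#'     its measurements.}
#'   \item{missing_values}{drops the second component value of one
#'     randomly chosen slash pair per compound statement (seeded).}
#' }
#'
#' @param text batch or description text (character vector).
#' @param flags character vector of degradation names; empty = identity.
#' @param seed integer seed (used by \code{missing_values}).
#' @return The degraded text.
#' @export
synth_degrade <- function(text, flags = character(), seed = 1L) {
  stopifnot(all(flags %in% c("omit_units", "omit_leg", "ambiguous_clause",
                             "missing_values")))
  out <- text
  if ("ambiguous_clause" %in% flags)
    out <- gsub("Carapace globose, ",
                "Carapace globose, thoracic groove on depressed area, ",
                out, fixed = TRUE)
  if ("missing_values" %in% flags) {
    out <- with_seed(seed, vapply(out, function(s) {
      sent <- split_keep(s, "(?<=\\.)\\s+(?=[A-Z>])")
      sent <- vapply(sent, function(x) {
        # drop the "/second" of one slash pair per compound statement
        m <- gregexpr("(\\d+\\.\\d+)/(\\d+\\.\\d+)", x)[[1]]
        if (m[1] == -1L) return(x)
        pick <- sample(seq_along(m), 1L)
        hit <- substr(x, m[pick], m[pick] + attr(m, "match.length")[pick] - 1L)
        paste0(substr(x, 1L, m[pick] - 1L),
               sub("/.*$", "", hit),
               substr(x, m[pick] + attr(m, "match.length")[pick], nchar(x)))
      }, "")
      paste(sent, collapse = "")
    }, "", USE.NAMES = FALSE))
  }
  if ("omit_units" %in% flags)
    out <- vapply(out, function(s)
      gsub("(?<=\\d)\\s*mm\\b", "", s, perl = TRUE),
      "", USE.NAMES = FALSE)
  if ("omit_leg" %in% flags)
    out <- vapply(out, function(s)
      gsub("\\b[Ll]eg (IV|III|II|I)\\b", "\\1", s, perl = TRUE),
      "", USE.NAMES = FALSE)
  out
}
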