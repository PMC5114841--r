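#' Term glossaries
#'
#' A term glossary holds the categorized vocabulary that drives structure
#' recognition and output naming: a term -> category map (e.g. \code{"tibia"}
#' is a \code{"structure"}, \code{"erect"} an \code{"orientation"}), a
#' synonym -> primary-term map used to collapse variant spellings onto one
#' matrix column, and a set of terms marked "not useful" that are ignored
#' during extraction. Categories are a flat list with no hierarchy.
#'
#' Terms are matched case-insensitively after internal-whitespace
#' normalization; multiword terms ("thoracic groove") are matched greedily,
#' longest first. Synonym chains must resolve in one hop: a primary term is
#' never itself listed as a synonym.
#'
#' @param categories named character vector mapping term -> category label.
#' @param synonyms named character vector mapping term -> primary term.
#' @param not_useful character vector of terms to ignore.
#' @return An object of class \code{term_glossary}.
#' @examples
#' g <- term_glossary(c(tibia = "structure", leg = "structure"),
#'                    synonyms = c(opisthosoma = "abdomen"))
#' categorize(g, "Tibia")
#' @export
term_glossary <- function(categories = character(), synonyms = character(),
                          not_useful = character()) {
  categories <- stats::setNames(as.character(categories),
                                norm_term(names2(categories)))
  synonyms <- stats::setNames(norm_term(as.character(synonyms)),
                              norm_term(names2(synonyms)))
  not_useful <- norm_term(as.character(not_useful))
  if (anyDuplicated(names(categories))) {
    dup <- unique(names(categories)[duplicated(names(categories))])
    bad <- dup[vapply(dup, function(t)
      length(unique(categories[names(categories) == t])) > 1L, logical(1))]
    if (length(bad))
      stop("conflicting categories for term(s): ", paste(bad, collapse = ", "))
    categories <- categories[!duplicated(names(categories))]
  }
  # one-hop rule: a synonym's primary must not itself be a synonym key
  bad <- intersect(unname(synonyms), names(synonyms))
  if (length(bad))
    stop("synonym chain/cycle via term(s): ", paste(bad, collapse = ", "))
  structure(list(categories = categories, synonyms = synonyms,
                 not_useful = not_useful),
            class = "term_glossary")
}

names2 <- function(x) if (is.null(names(x))) character(length(x)) else names(x)

# lower-case, squeeze internal whitespace
norm_term <- function(x) gsub("\\s+", " ", trimws(tolower(x)))

#' @export
print.term_glossary <- function(x, ...) {
  cat("<term_glossary> ", length(x$categories), " terms, ",
      length(x$synonyms), " synonyms, ", length(x$not_useful),
      " not-useful\n", sep = "")
  invisible(x)
}

#' Read and write glossary files
#'
#' The on-disk format is two tab-separated two-column tables: the category
#' file holds \code{term<TAB>category} rows and the synonym file
#' \code{term<TAB>primary} rows. Lines starting with \code{#} and blank
#' lines are ignored. A third optional single-column file lists terms marked
#' not useful.
#'
#' @param categories_file,synonyms_file,not_useful_file paths; the latter two
#'   may be \code{NULL}.
#' @return \code{load_glossary} returns a \code{term_glossary}.
#' @export
load_glossary <- function(categories_file, synonyms_file = NULL,
                          not_useful_file = NULL) {
  cats <- read_two_col(categories_file)
  syns <- if (!is.null(synonyms_file)) read_two_col(synonyms_file)
          else character()
  nu <- if (!is.null(not_useful_file))
          grep("^\\s*(#|$)", readLines(not_useful_file, warn = FALSE),
               invert = TRUE, value = TRUE)
        else character()
  term_glossary(cats, syns, nu)
}

read_two_col <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(character())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("malformed glossary line ", bad[1], " in ", path,
         ": expected term<TAB>value")
  stats::setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
}

#' @rdname load_glossary
#' @param g a \code{term_glossary}.
#' @export
save_glossary <- function(g, categories_file, synonyms_file = NULL,
                          not_useful_file = NULL) {
  stopifnot(inherits(g, "term_glossary"))
  writeLines(paste(names(g$categories), g$categories, sep = "\t"),
             categories_file)
  if (!is.null(synonyms_file))
    writeLines(paste(names(g$synonyms), g$synonyms, sep = "\t"),
               synonyms_file)
  if (!is.null(not_useful_file))
    writeLines(g$not_useful, not_useful_file)
  invisible(g)
}

#' Look up the category or primary form of a term
#'
#' Lookup is case-insensitive and applied after synonym resolution, so a
#' synonym inherits the category of its primary term. Unknown terms return
#' \code{NA}.
#'
#' @param g a \code{term_glossary}.
#' @param term character vector of terms.
#' @return \code{categorize}: category labels (\code{NA} where unknown);
#'   \code{primary_of}: the primary spelling of each term (the term itself
#'   when it has no synonym entry).
#' @export
categorize <- function(g, term) {
  t <- primary_of(g, term)
  out <- unname(g$categories[t])
  out[t %in% g$not_useful] <- NA_character_
  out
}

#' @rdname categorize
#' @export
primary_of <- function(g, term) {
  t <- norm_term(term)
  hit <- t %in% names(g$synonyms)
  t[hit] <- unname(g$synonyms[t[hit]])
  t
}

#' Replace synonym terms in extracted records with their primary terms
#'
#' Rewrites every structure term inside each record's entity path (and the
#' character name, should a synonym be registered for it) to the primary
#' spelling, so that variant spellings land in a single matrix column.
#' Values and units are never changed, and the operation is idempotent.
#'
#' @param g a \code{term_glossary}.
#' @param records a record data frame as returned by [extract_records()].
#' @return The records with terms rewritten; row count unchanged.
#' @export
apply_synonyms <- function(g, records) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) return(records)
  records$entity <- vapply(records$entity, function(e) {
    toks <- strsplit(e, " ", fixed = TRUE)[[1]]
    toks <- vapply(toks, resolve_entity_token, "", g = g)
    paste(toks, collapse = " ")
  }, "", USE.NAMES = FALSE)
  records$character <- primary_of(g, records$character)
  records
}

# entity tokens are hyphen-joined canonical terms; resolve each hyphen part
# against the synonym table but keep structural hyphenation intact when the
# whole token is itself a known term
resolve_entity_token <- function(tok, g) {
  whole <- gsub("-", " ", tok, fixed = TRUE)
  p <- primary_of(g, whole)
  if (!identical(p, norm_term(whole))) return(canonical_term(p))
  canonical_term(primary_of(g, tok))
}

# canonical entity spelling: lower case, internal spaces -> hyphens
canonical_term <- function(x) gsub(" ", "-", norm_term(x), fixed = TRUE)
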