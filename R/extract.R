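#' Measurement indicator vocabulary
#'
#' Indicator terms are the lexical cues that license a specific character
#' label: a clause saying "length 3.27 mm" is a *length*, one saying only
#' "3.27 mm" can at best be labelled *size*, and a bare "3.27" only
#' *quantity*. The default set covers the measurement vocabulary of
#' spider-style descriptions; each indicator maps to the canonical
#' character name it licenses.
#'
#' @return \code{measurement_indicators}: the indicator tokens, longest
#'   first (so multiword indicators match greedily).
#' @export
measurement_indicators <- function() names(indicator_map())

indicator_map <- function() c(
  "total length" = "length",
  "lengths" = "length", "length" = "length", "long" = "length",
  "widths" = "width", "width" = "width", "wide" = "width",
  "heights" = "height", "height" = "height", "high" = "height",
  "distances" = "distance", "distance" = "distance",
  "indices" = "index", "index" = "index",
  "diameters" = "diameter", "diameter" = "diameter"
)

unit_rx <- "(?:mm|cm|dm|m|um|µm)"
value_rx <- "\\d+(?:\\.\\d+)?(?:\\s*[–-]\\s*\\d+(?:\\.\\d+)?)?"

#' Default extraction configuration
#'
#' @param attachment where a measurement clause with no structure of its own
#'   attaches: \code{"subject"} (the first structure mention of the
#'   sentence; default) or \code{"nearest"} (nearest preceding structure).
#' @param missing_markers tokens that stand for an explicitly missing value.
#' @param whole_organism canonical term used for organism-level characters
#'   ("Total length").
#' @return A named list of options consumed by the \code{extract_*}
#'   functions.
#' @export
extract_config <- function(attachment = c("subject", "nearest"),
                           missing_markers = c("missing", "-", "lost"),
                           whole_organism = "whole-organism") {
  list(attachment = match.arg(attachment),
       missing_markers = missing_markers,
       whole_organism = whole_organism)
}

#' Segment description text into statements and clauses
#'
#' Sentences are split on a period followed by whitespace and a capital
#' letter (decimal points never qualify). Within a sentence, semicolons
#' delimit clause groups and commas delimit clauses. Character offsets into
#' the original text are preserved.
#'
#' @param text a single description string.
#' @return A list of statements, each a list with \code{text},
#'   \code{start}, \code{end} (1-based character offsets) and
#'   \code{groups}, a list of semicolon groups each holding its
#'   \code{text} and a character vector \code{clauses}.
#' @export
segment <- function(text) {
  stopifnot(length(text) == 1L)
  if (!nzchar(trimws(text))) return(list())
  pieces <- split_keep(text, "(?<=\\.)\\s+(?=[A-Z])")
  out <- list()
  pos <- 1L
  for (p in pieces) {
    start <- pos + (nchar(p) - nchar(sub("^\\s+", "", p)))
    body <- trimws(p)
    if (nzchar(body)) {
      groups <- lapply(strsplit(body, ";", fixed = TRUE)[[1]], function(g) {
        g <- trimws(g)
        list(text = g,
             clauses = trimws(strsplit(g, ",", fixed = TRUE)[[1]]))
      })
      out[[length(out) + 1L]] <-
        list(text = body, start = start, end = start + nchar(body) - 1L,
             groups = groups)
    }
    pos <- pos + nchar(p)
  }
  out
}

#' Label a character from its available clues
#'
#' Implements the label-specificity ladder: a measurement indicator licenses
#' the specific character name it maps to; with no indicator but a unit
#' present the general label \code{"size"} is used; with neither clue only
#' the most general label \code{"quantity"} remains.
#'
#' @param indicator indicator token found in the clause, or \code{NA}.
#' @param unit unit token found, or \code{NA}.
#' @return A list with \code{name} (character label) and \code{tier}
#'   (\code{"specific"}, \code{"size"} or \code{"quantity"}).
#' @examples
#' label_character("length", "mm")  # specific
#' label_character(NA, "mm")        # size
#' label_character(NA, NA)          # quantity
#' @export
label_character <- function(indicator = NA_character_,
                            unit = NA_character_) {
  if (!is.na(indicator)) {
    im <- indicator_map()
    key <- tolower(indicator)
    if (!key %in% names(im))
      stop("unknown measurement indicator: ", indicator)
    list(name = unname(im[key]), tier = "specific")
  } else if (!is.na(unit)) {
    list(name = "size", tier = "size")
  } else {
    list(name = "quantity", tier = "quantity")
  }
}

# ---- token scanning -------------------------------------------------------

# word tokens (letters plus internal hyphens) with character offsets
tokenize_words <- function(text) {
  m <- gregexpr("[A-Za-z][A-Za-z-]*", text)[[1]]
  if (m[1] == -1L)
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  data.frame(token = regmatches(text, list(m))[[1]],
             start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L,
             stringsAsFactors = FALSE)
}

roman_legs <- c("i", "ii", "iii", "iv")

# greedy longest-first scan for glossary structure phrases; adjacent
# "leg" + Roman numeral fuses into one canonical token ("leg-i")
find_structures <- function(text, g, max_words = 3L) {
  toks <- tokenize_words(text)
  found <- data.frame(term = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  i <- 1L
  n <- nrow(toks)
  while (i <= n) {
    hit <- NULL
    for (k in seq(min(max_words, n - i + 1L), 1L)) {
      phrase <- paste(tolower(toks$token[i:(i + k - 1L)]), collapse = " ")
      if (identical(categorize(g, phrase), "structure")) {
        hit <- list(term = canonical_term(primary_of(g, phrase)),
                    start = toks$start[i], end = toks$end[i + k - 1L],
                    len = k)
        break
      }
    }
    if (is.null(hit)) { i <- i + 1L; next }
    # fuse "leg" + numeral
    nxt <- i + hit$len
    if (hit$term == "leg" && nxt <= n &&
        tolower(toks$token[nxt]) %in% roman_legs &&
        identical(categorize(g, tolower(toks$token[nxt])), "structure")) {
      hit$term <- paste0("leg-", tolower(toks$token[nxt]))
      hit$end <- toks$end[nxt]
      hit$len <- hit$len + 1L
    }
    found <- rbind(found, data.frame(term = hit$term, start = hit$start,
                                     end = hit$end,
                                     stringsAsFactors = FALSE))
    i <- i + hit$len
  }
  found
}

# first indicator token in a piece of text (longest indicators first)
find_indicator <- function(text) {
  for (ind in measurement_indicators()) {
    if (grepl(paste0("\\b", ind, "\\b"), text, ignore.case = TRUE))
      return(ind)
  }
  NA_character_
}

find_indicators_all <- function(text) {
  hits <- list()
  for (ind in measurement_indicators()) {
    m <- gregexpr(paste0("\\b", ind, "\\b"), text, ignore.case = TRUE)[[1]]
    if (m[1] != -1L)
      for (p in as.integer(m))
        hits[[length(hits) + 1L]] <- list(ind = ind, pos = p)
  }
  if (!length(hits)) return(character())
  hits <- hits[order(vapply(hits, `[[`, 0L, "pos"))]
  # drop indicators nested inside an earlier, longer match
  out <- character(); last_end <- 0L
  for (h in hits) {
    if (h$pos > last_end) {
      out <- c(out, h$ind)
      last_end <- h$pos + nchar(h$ind) - 1L
    }
  }
  out
}

find_unit <- function(text) {
  m <- regmatches(text, regexpr(paste0("\\b", unit_rx, "\\b"), text,
                                perl = TRUE))
  if (length(m)) m else NA_character_
}

find_values <- function(text) {
  m <- gregexpr(paste0("(?<![\\d.])", value_rx, "(?![\\d.])"), text,
                perl = TRUE)[[1]]
  if (m[1] == -1L) return(character())
  regmatches(text, list(m))[[1]]
}

# decimal-valued measurements only (excludes bare integers such as indices)
find_decimal_values <- function(text)
  grep("\\.", find_values(text), value = TRUE)

make_record <- function(entity, character, value, unit, tier,
                        compound_group = NA_character_,
                        statement = NA_integer_,
                        start = NA_integer_, end = NA_integer_) {
  data.frame(doc_id = NA_character_, taxon = NA_character_,
             entity = entity, character = character,
             value = value, unit = unit, tier = tier,
             compound_group = compound_group, statement = statement,
             start = start, end = end, stringsAsFactors = FALSE)
}

bind_records <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0L, lst)
  if (!length(lst)) return(empty_records())
  do.call(rbind, lst)
}

# ---- statement-level extractors ------------------------------------------

strip_period <- function(x) sub("\\.\\s*$", "", x)

#' Extract simple and enumerated measurements from one statement
#'
#' Handles the two plain measurement shapes: comma-clause statements whose
#' value clauses attach to a structure ("Carapace globose, length 3.27 mm,
#' width 2.70 mm."), and colon-headed enumerations where several structures
#' share one indicator and a positional value list ("I, II, III, IV length:
#' 1.23, 1.35, 1.27, 1.28 mm"). A trailing unit distributes over every
#' value in its list; "Total length" statements attach to the whole
#' organism. A value clause carrying no structure of its own attaches to
#' the sentence subject (or the nearest preceding structure, by
#' configuration).
#'
#' @param statement one statement string.
#' @param glossary a \code{term_glossary}.
#' @param config see [extract_config()].
#' @return A record data frame (possibly empty).
#' @export
extract_measurements <- function(statement, glossary,
                                 config = extract_config()) {
  st <- strip_period(statement)
  if (grepl(":", st, fixed = TRUE)) {
    parts <- strsplit(st, ":", fixed = TRUE)[[1]]
    header <- trimws(parts[1])
    rest <- trimws(paste(parts[-1], collapse = ":"))
    rec <- extract_enumeration(header, rest, glossary, config)
    if (!is.null(rec)) return(rec)
  }
  extract_simple(st, glossary, config)
}

extract_enumeration <- function(header, rest, glossary, config) {
  ind <- find_indicator(header)
  hdr_wo_ind <- if (!is.na(ind))
    trimws(gsub(paste0("\\b", ind, "\\b"), "", header, ignore.case = TRUE))
  else header
  structs <- find_structures(hdr_wo_ind, glossary)
  if (!nrow(structs)) return(NULL)
  # every word in the header must be accounted for by structures/indicator
  leftover <- hdr_wo_ind
  for (i in rev(seq_len(nrow(structs))))
    leftover <- paste0(substr(leftover, 1L, structs$start[i] - 1L),
                       substr(leftover, structs$end[i] + 1L,
                              nchar(leftover)))
  if (grepl("[A-Za-z]", gsub("\\bof\\b", "", leftover))) return(NULL)
  vals <- find_values(rest)
  if (!length(vals)) return(NULL)
  unit <- find_unit(rest)
  lab <- label_character(ind, unit)
  n <- min(nrow(structs), length(vals))
  if (length(vals) != nrow(structs))
    warning("enumeration arity mismatch: ", nrow(structs),
            " structures vs ", length(vals),
            " values; aligning the common prefix")
  bind_records(lapply(seq_len(n), function(i)
    make_record(structs$term[i], lab$name, vals[i], unit, lab$tier)))
}

extract_simple <- function(st, glossary, config) {
  groups <- unlist(lapply(strsplit(st, ";", fixed = TRUE)[[1]],
                          function(g) strsplit(g, ",", fixed = TRUE)[[1]]))
  clauses <- trimws(groups)
  clauses <- clauses[nzchar(clauses)]
  if (!length(clauses)) return(empty_records())
  subject <- NA_character_
  nearest <- NA_character_
  recs <- list()
  for (cl in clauses) {
    structs <- find_structures(cl, glossary)
    if (nrow(structs) && is.na(subject)) subject <- structs$term[1]
    vals <- find_decimal_values(cl)
    if (!length(vals)) {
      if (nrow(structs)) nearest <- structs$term[nrow(structs)]
      next
    }
    ind <- find_indicator(cl)
    unit <- find_unit(cl)
    lab <- label_character(ind, unit)
    entity <- if (!is.na(ind) && tolower(ind) == "total length")
      config$whole_organism
    else if (nrow(structs)) structs$term[1]
    else if (config$attachment == "nearest" && !is.na(nearest)) nearest
    else if (!is.na(subject)) subject
    else config$whole_organism
    for (v in vals)
      recs[[length(recs) + 1L]] <-
        make_record(entity, lab$name, v, unit, lab$tier)
    if (nrow(structs)) nearest <- structs$term[nrow(structs)]
  }
  bind_records(recs)
}

#' Extract a slash-compound measurement statement
#'
#' Parses statements of the form "Length of tibia/metatarsus: leg I,
#' 0.52/0.44 mm; leg II, ...": the slash-joined structure template in the
#' header maps positionally onto the slash-separated values of each leg
#' group, left to right. Groups with fewer values than template components
#' leave the trailing components as null records (explicitly value-less,
#' not dropped). All records born from the statement share a
#' \code{compound_group} id; the entity path is the leg term plus the
#' template component ("leg-i tibia").
#'
#' @inheritParams extract_measurements
#' @return A record data frame, or \code{NULL} when the statement has no
#'   slash-compound header.
#' @export
extract_compound <- function(statement, glossary,
                             config = extract_config()) {
  st <- strip_period(statement)
  if (!grepl(":", st, fixed = TRUE)) return(NULL)
  parts <- strsplit(st, ":", fixed = TRUE)[[1]]
  header <- trimws(parts[1])
  rest <- trimws(paste(parts[-1], collapse = ":"))
  m <- regmatches(header,
                  regexpr("[A-Za-z][A-Za-z-]*(?:/[A-Za-z][A-Za-z-]*)+",
                          header))
  if (!length(m)) return(NULL)
  comps <- strsplit(m, "/", fixed = TRUE)[[1]]
  if (!all(vapply(comps, function(x)
    identical(categorize(glossary, x), "structure"), logical(1))))
    return(NULL)
  comps <- canonical_term(primary_of(glossary, comps))
  ind <- find_indicator(sub(m, "", header, fixed = TRUE))
  # group id is a stable function of the statement itself
  cg <- paste0("cg-", nchar(st), "-", length(comps))
  recs <- list()
  for (grp in trimws(strsplit(rest, ";", fixed = TRUE)[[1]])) {
    structs <- find_structures(grp, glossary)
    leg <- if (nrow(structs)) structs$term[1] else NA_character_
    is_missing <- grepl(paste0("\\b(",
                               paste(config$missing_markers, collapse = "|"),
                               ")\\b"), grp, ignore.case = TRUE)
    vals <- if (is_missing) character() else find_values(grp)
    unit <- find_unit(grp)
    for (j in seq_along(comps)) {
      v <- if (j <= length(vals)) vals[j] else NA_character_
      lab <- label_character(ind, if (!is.na(v)) unit else NA_character_)
      entity <- paste(c(if (!is.na(leg)) leg, comps[j]), collapse = " ")
      recs[[length(recs) + 1L]] <-
        make_record(entity, lab$name, v,
                    if (!is.na(v)) unit else NA_character_,
                    lab$tier, compound_group = cg)
    }
  }
  bind_records(recs)
}

#' Extract a multi-character list statement
#'
#' Parses statements like "Tibial lengths and indices: leg I missing; leg
#' II 1.73 mm, 7; ...": the header names k characters (here length and
#' index) that apply, in order, to the k comma-separated values of every
#' leg group. A group consisting of a missing marker yields null records
#' for all k characters of that structure. Value groups of the wrong arity
#' are aligned on their common prefix with a diagnostic.
#'
#' @inheritParams extract_measurements
#' @return A record data frame, or \code{NULL} when the header does not
#'   name at least two characters.
#' @export
extract_multicharacter <- function(statement, glossary,
                                   config = extract_config()) {
  st <- strip_period(statement)
  if (!grepl(":", st, fixed = TRUE)) return(NULL)
  parts <- strsplit(st, ":", fixed = TRUE)[[1]]
  header <- trimws(parts[1])
  rest <- trimws(paste(parts[-1], collapse = ":"))
  inds <- find_indicators_all(header)
  if (length(inds) < 2L) return(NULL)
  chars <- unname(indicator_map()[tolower(inds)])
  hstructs <- find_structures(header, glossary)
  head_ent <- if (nrow(hstructs)) hstructs$term else character()
  recs <- list()
  for (grp in trimws(strsplit(rest, ";", fixed = TRUE)[[1]])) {
    structs <- find_structures(grp, glossary)
    leg <- if (nrow(structs)) structs$term[1] else NA_character_
    entity <- paste(c(if (!is.na(leg)) leg, head_ent), collapse = " ")
    after <- if (nrow(structs))
      substr(grp, structs$end[1] + 1L, nchar(grp))
    else grp
    if (grepl(paste0("\\b(",
                     paste(config$missing_markers, collapse = "|"),
                     ")\\b"), after, ignore.case = TRUE)) {
      for (ch in chars)
        recs[[length(recs) + 1L]] <-
          make_record(entity, ch, NA_character_, NA_character_, "specific")
      next
    }
    items <- trimws(strsplit(after, ",", fixed = TRUE)[[1]])
    items <- items[nzchar(items)]
    if (length(items) != length(chars))
      warning("multi-character group arity mismatch: expected ",
              length(chars), " values, found ", length(items),
              " in '", grp, "'")
    for (j in seq_len(min(length(items), length(chars)))) {
      v <- find_values(items[j])
      recs[[length(recs) + 1L]] <-
        make_record(entity, chars[j],
                    if (length(v)) v[1] else NA_character_,
                    find_unit(items[j]), "specific")
    }
  }
  bind_records(recs)
}

#' Extract a distance-between-structures statement
#'
#' Parses the pattern "<structure A> <value> [unit] from <structure B>"
#' ("Epigastric furrow 0.74 mm from tracheal spiracle."). The record's
#' character is \code{"distance"} when a unit licenses the measurement
#' reading (falling back down the label ladder otherwise) and its entity is
#' the hyphenated structure pair in textual order; the literal
#' glossary-resolved terms are used with no term approximation.
#'
#' @inheritParams extract_measurements
#' @return A single-row record data frame, or \code{NULL} when the pattern
#'   does not apply.
#' @export
extract_distance <- function(statement, glossary,
                             config = extract_config()) {
  st <- strip_period(statement)
  m <- regexec(paste0("^(.*?)\\s+(", value_rx, ")\\s*(", unit_rx,
                      ")?\\s+from\\s+(.*)$"), st, perl = TRUE)
  g <- regmatches(st, m)[[1]]
  if (!length(g)) return(NULL)
  a <- find_structures(g[2], glossary)
  b <- find_structures(g[5], glossary)
  if (!nrow(a) || !nrow(b)) return(NULL)
  unit <- if (nzchar(g[4])) g[4] else NA_character_
  lab <- label_character(if (!is.na(unit)) "distance" else NA_character_,
                         unit)
  make_record(paste0(a$term[nrow(a)], "-", b$term[1]),
              lab$name, g[3], unit, lab$tier)
}

#' Extract all character records from a description document
#'
#' Segments the document text into statements and dispatches each to the
#' matching statement-level extractor (distance pattern, slash compound,
#' multi-character list, enumeration, plain measurement clauses, in that
#' order of specificity). Identical text and glossary always yield an
#' identical record list.
#'
#' @param doc a \code{description_doc}.
#' @param glossary a \code{term_glossary}.
#' @param config see [extract_config()].
#' @return An \code{annotated_doc} holding the document and its records
#'   with provenance (statement index and character offsets).
#' @export
extract_records <- function(doc, glossary, config = extract_config()) {
  stopifnot(inherits(doc, "description_doc"))
  stmts <- segment(doc$text)
  recs <- list()
  for (i in seq_along(stmts)) {
    s <- stmts[[i]]
    r <- extract_statement(s$text, glossary, config)
    if (!is.null(r) && nrow(r)) {
      r$doc_id <- doc$taxon_name
      r$taxon <- doc$taxon_name
      r$statement <- i
      r$start <- s$start
      r$end <- s$end
      r$compound_group[!is.na(r$compound_group)] <- paste0("s", i)
      recs[[length(recs) + 1L]] <- r
    }
  }
  out <- bind_records(recs)
  out <- apply_synonyms(glossary, out)
  annotated_doc(doc, out)
}

extract_statement <- function(text, glossary, config) {
  r <- extract_distance(text, glossary, config)
  if (!is.null(r)) return(r)
  r <- extract_compound(text, glossary, config)
  if (!is.null(r)) return(r)
  r <- extract_multicharacter(text, glossary, config)
  if (!is.null(r)) return(r)
  extract_measurements(text, glossary, config)
}
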