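#' Description documents and batch files
#'
#' A description document is one taxon exemplar plus the verbatim text of its
#' telegraphic description. Batches of documents travel in a plain-text
#' format, one record per block, blank-line separated:
#'
#' \preformatted{
#' > Genus species | rank=species | exemplar=male | source=Author 1990
#' Carapace globose, length 3.27 mm, width 2.70 mm.
#' Total length 7.58 mm.
#' }
#'
#' The header line starts with \code{">"} followed by the taxon name;
#' optional \code{key=value} fields (\code{rank}, \code{exemplar},
#' \code{source}) follow, pipe-separated. All subsequent non-blank lines up
#' to the next blank line form the description body, preserved byte for
#' byte.
#'
#' @param taxon_name taxon label (non-empty).
#' @param text description body.
#' @param rank,exemplar_tag,source_meta optional header fields.
#' @return An object of class \code{description_doc}.
#' @export
description_doc <- function(taxon_name, text, rank = NA_character_,
                            exemplar_tag = NA_character_,
                            source_meta = NA_character_) {
  if (!is.character(taxon_name) || length(taxon_name) != 1L ||
      !nzchar(trimws(taxon_name)))
    stop("taxon_name must be a non-empty string")
  structure(list(taxon_name = taxon_name, rank = rank,
                 exemplar_tag = exemplar_tag, source_meta = source_meta,
                 text = text),
            class = "description_doc")
}

#' @export
print.description_doc <- function(x, ...) {
  cat("<description_doc> ", x$taxon_name,
      if (!is.na(x$exemplar_tag)) paste0(" [", x$exemplar_tag, "]"),
      ": ", nchar(x$text), " chars\n", sep = "")
  invisible(x)
}

#' Parse a batch of description documents
#'
#' @param blob the batch text (single string) or a character vector of lines.
#' @return A list of \code{description_doc}, in input order; empty input
#'   yields an empty list.
#' @seealso [write_batch()]
#' @export
parse_batch <- function(blob) {
  lines <- if (length(blob) == 1L) strsplit(blob, "\n", fixed = TRUE)[[1]]
           else as.character(blob)
  docs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!startsWith(lines[i], ">"))
      stop("parse error at line ", i,
           ": expected a taxon header line starting with '>'")
    hdr <- parse_header(substring(lines[i], 2L), i)
    i <- i + 1L
    body <- character()
    while (i <= n && nzchar(trimws(lines[i]))) {
      body <- c(body, lines[i])
      i <- i + 1L
    }
    docs[[length(docs) + 1L]] <-
      description_doc(hdr$taxon, paste(body, collapse = "\n"),
                      rank = hdr$rank, exemplar_tag = hdr$exemplar,
                      source_meta = hdr$source)
  }
  docs
}

parse_header <- function(hdr, lineno) {
  parts <- trimws(strsplit(hdr, "|", fixed = TRUE)[[1]])
  if (!length(parts) || !nzchar(parts[1]))
    stop("parse error at line ", lineno, ": empty taxon name in header")
  out <- list(taxon = parts[1], rank = NA_character_,
              exemplar = NA_character_, source = NA_character_)
  for (p in parts[-1]) {
    kv <- regmatches(p, regexec("^(rank|exemplar|source)=(.*)$", p))[[1]]
    if (length(kv) != 3L)
      stop("parse error at line ", lineno, ": bad header field '", p, "'")
    out[[kv[2]]] <- kv[3]
  }
  out
}

#' @rdname parse_batch
#' @param docs list of \code{description_doc}.
#' @param path optional file path; when omitted the batch text is returned.
#' @export
write_batch <- function(docs, path = NULL) {
  blocks <- vapply(docs, function(d) {
    fields <- c(rank = d$rank, exemplar = d$exemplar_tag, source = d$source_meta)
    fields <- fields[!is.na(fields)]
    hdr <- paste(c(paste0("> ", d$taxon_name),
                   if (length(fields)) paste0(names(fields), "=", fields)),
                 collapse = " | ")
    paste(c(hdr, d$text), collapse = "\n")
  }, "")
  out <- paste(blocks, collapse = "\n\n")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}

#' Annotated documents
#'
#' An annotated document pairs a \code{description_doc} with the character
#' records extracted from it. Records are stored as a data frame with one
#' row per structure/character/value observation (see [extract_records()]).
#'
#' @param doc a \code{description_doc}.
#' @param records a record data frame; defaults to an empty one.
#' @return An object of class \code{annotated_doc}.
#' @export
annotated_doc <- function(doc, records = empty_records()) {
  stopifnot(inherits(doc, "description_doc"), is.data.frame(records))
  if (nrow(records)) {
    bad <- !is.na(records$start) &
      (records$start < 1L | records$end > nchar(doc$text))
    if (any(bad))
      stop("record provenance offsets fall outside the document text")
  }
  structure(list(doc = doc, records = records), class = "annotated_doc")
}

#' @export
print.annotated_doc <- function(x, ...) {
  cat("<annotated_doc> ", x$doc$taxon_name, ": ", nrow(x$records),
      " records\n", sep = "")
  invisible(x)
}

record_cols <- c("doc_id", "taxon", "entity", "character", "value", "unit",
                 "tier", "compound_group", "statement", "start", "end")

#' @rdname annotated_doc
#' @export
empty_records <- function() {
  df <- data.frame(doc_id = character(), taxon = character(),
                   entity = character(), character = character(),
                   value = character(), unit = character(),
                   tier = character(), compound_group = character(),
                   statement = integer(), start = integer(),
                   end = integer(), stringsAsFactors = FALSE)
  df
}

#' Serialize annotated documents as XML
#'
#' The schema is a flat mirror of the record table: a root
#' \code{<annotated_doc>} holding a \code{<source>} element with the header
#' fields, a \code{<text>} element with the verbatim description, and one
#' \code{<record>} element per extracted observation with \code{entity},
#' \code{character}, \code{value}, \code{unit}, \code{tier},
#' \code{compound_group}, \code{statement} and offset attributes. Reading a
#' written document restores it field for field.
#'
#' @param ad an \code{annotated_doc}.
#' @param path optional file path; when omitted the XML text is returned.
#' @export
write_annotations <- function(ad, path = NULL) {
  stopifnot(inherits(ad, "annotated_doc"))
  root <- xml2::xml_new_root("annotated_doc")
  src <- xml2::xml_add_child(root, "source")
  xml2::xml_set_attr(src, "taxon", ad$doc$taxon_name)
  for (f in c("rank", "exemplar_tag", "source_meta"))
    if (!is.na(ad$doc[[f]])) xml2::xml_set_attr(src, f, ad$doc[[f]])
  xml2::xml_set_text(xml2::xml_add_child(root, "text"), ad$doc$text)
  recs <- xml2::xml_add_child(root, "records")
  if (nrow(ad$records)) for (i in seq_len(nrow(ad$records))) {
    r <- xml2::xml_add_child(recs, "record")
    for (col in setdiff(record_cols, c("doc_id", "taxon"))) {
      v <- ad$records[[col]][i]
      if (!is.na(v)) xml2::xml_set_attr(r, col, as.character(v))
    }
  }
  txt <- as.character(root)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_annotations
#' @param x XML text or a file path.
#' @export
read_annotations <- function(x) {
  doc <- tryCatch(
    if (length(x) == 1L && !grepl("<", x, fixed = TRUE)) xml2::read_xml(x)
    else xml2::read_xml(paste(x, collapse = "\n")),
    error = function(e) stop("annotation schema violation: ",
                             conditionMessage(e), call. = FALSE))
  if (xml2::xml_name(doc) != "annotated_doc")
    stop("annotation schema violation: root element is <",
         xml2::xml_name(doc), ">, expected <annotated_doc>")
  src <- xml2::xml_find_first(doc, "./source")
  txt <- xml2::xml_find_first(doc, "./text")
  if (inherits(src, "xml_missing") || inherits(txt, "xml_missing"))
    stop("annotation schema violation: missing <source> or <text> element")
  at <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) NA_character_ else v
  }
  d <- description_doc(at(src, "taxon"), xml2::xml_text(txt),
                       rank = at(src, "rank"),
                       exemplar_tag = at(src, "exemplar_tag"),
                       source_meta = at(src, "source_meta"))
  nodes <- xml2::xml_find_all(doc, "./records/record")
  recs <- empty_records()
  if (length(nodes)) {
    get <- function(a) vapply(nodes, at, "", a = a)
    recs <- data.frame(
      doc_id = rep(d$taxon_name, length(nodes)),
      taxon = rep(d$taxon_name, length(nodes)),
      entity = get("entity"), character = get("character"),
      value = get("value"), unit = get("unit"), tier = get("tier"),
      compound_group = get("compound_group"),
      statement = as.integer(get("statement")),
      start = as.integer(get("start")), end = as.integer(get("end")),
      stringsAsFactors = FALSE)
  }
  annotated_doc(d, recs)
}

#' Read and write taxon-character matrices as CSV
#'
#' The first header cell is the fixed label \code{"Taxon"}; remaining header
#' cells are character names. One row follows per exemplar. An empty string
#' is an empty cell; a \code{"?"} cell is an explicit-missing state, kept
#' distinct from empty. Output is UTF-8, comma-separated, minimally quoted.
#'
#' @param m a \code{taxon_matrix} (see [taxon_matrix()]).
#' @param path file path.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "taxon_matrix"))
  header <- paste(csv_quote(c("Taxon", colnames(m$cells))), collapse = ",")
  rows <- vapply(seq_along(m$taxa), function(i)
    paste(csv_quote(c(m$taxa[i], m$cells[i, ])), collapse = ","), "")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

csv_quote <- function(x) {
  x[is.na(x)] <- ""
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (!ncol(df)) return(taxon_matrix(character(), character()))
  chars <- colnames(df)[-1]
  if (anyDuplicated(chars))
    stop("duplicate column names in matrix CSV: ",
         paste(unique(chars[duplicated(chars)]), collapse = ", "))
  m <- taxon_matrix(df[[1]], chars)
  if (nrow(df) && length(chars))
    m$cells[] <- as.matrix(df[, -1, drop = FALSE])
  m
}
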