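#' The bundled spider glossary
#'
#' Loads the term categorization and synonym tables shipped with the
#' package (\code{inst/extdata/spider_categories.tsv} and
#' \code{spider_synonyms.tsv}): the anatomical structure vocabulary of
#' spider measurement descriptions, with Roman numerals I-IV categorized
#' as structures (a glossary act, not a parser rule) and adjectival or
#' variant spellings mapped to primary terms.
#'
#' @return A \code{term_glossary}.
#' @export
default_glossary <- function() {
  load_glossary(
    system.file("extdata", "spider_categories.tsv", package = "taxamat",
                mustWork = TRUE),
    system.file("extdata", "spider_synonyms.tsv", package = "taxamat",
                mustWork = TRUE))
}

#' Run the full matrix-generation pipeline
#'
#' Orchestrates normalize -> extract -> matricize -> edit -> evaluate as
#' one configured run. The configuration is a named list (or a YAML file
#' read with [read_pipeline_config()]) with entries:
#' \describe{
#'   \item{batch}{path to the input batch text (required), or
#'     \code{batch_text} with the text itself.}
#'   \item{glossary, synonyms}{glossary TSV paths; the bundled spider
#'     glossary is used when omitted.}
#'   \item{normalize}{list: \code{unit} (default "mm"), \code{leg}
#'     (default TRUE); set \code{normalize: false} to skip.}
#'   \item{inherit, infer_presence}{logical options with optional
#'     \code{lineage} / \code{partonomy} file paths.}
#'   \item{edits}{path to a JSON-lines edit script, applied after
#'     consolidation.}
#'   \item{gold}{path to a gold matrix CSV; triggers evaluation.}
#'   \item{out_dir}{directory for intermediates and outputs (required).}
#' }
#'
#' @param config named list as above.
#' @param quiet suppress per-stage log messages.
#' @return Invisibly, a list with the \code{matrix}, the \code{report}
#'   (\code{NULL} without gold) and the per-stage \code{log} data frame.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  need <- function(cond, msg) if (!cond) stop("pipeline: ", msg)
  need(!is.null(config$out_dir), "config must name out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- data.frame(stage = character(), detail = character(),
                    stringsAsFactors = FALSE)
  note <- function(stage, detail) {
    if (!quiet) message("[", stage, "] ", detail)
    log <<- rbind(log, data.frame(stage = stage, detail = detail,
                                  stringsAsFactors = FALSE))
  }

  blob <- if (!is.null(config$batch_text)) config$batch_text
          else {
            need(!is.null(config$batch), "config must name a batch input")
            need(file.exists(config$batch),
                 paste0("missing input file: ", config$batch))
            paste(readLines(config$batch, warn = FALSE), collapse = "\n")
          }
  docs <- parse_batch(blob)
  note("input", paste(length(docs), "description documents"))

  g <- if (!is.null(config$glossary))
    load_glossary(config$glossary, config$synonyms)
  else default_glossary()

  norm <- config$normalize
  if (is.null(norm)) norm <- list()
  if (!identical(norm, FALSE)) {
    unit <- if (!is.null(norm$unit)) norm$unit else "mm"
    leg <- if (!is.null(norm$leg)) isTRUE(norm$leg) else TRUE
    docs <- normalize_batch(docs, unit = unit, leg = leg)
    write_batch(docs, file.path(config$out_dir, "normalized_batch.txt"))
    note("normalize", paste0("unit=", unit, " leg=", leg))
  }

  cfg <- extract_config(
    attachment = if (!is.null(config$attachment)) config$attachment
                 else "subject")
  ann <- lapply(docs, extract_records, glossary = g, config = cfg)
  nrec <- sum(vapply(ann, function(a) nrow(a$records), 0L))
  ann_dir <- file.path(config$out_dir, "annotations")
  dir.create(ann_dir, showWarnings = FALSE)
  for (i in seq_along(ann))
    write_annotations(ann[[i]],
                      file.path(ann_dir, sprintf("doc_%04d.xml", i)))
  note("extract", paste(nrec, "records"))

  lineage <- if (!is.null(config$lineage))
    yaml::read_yaml(config$lineage)
  partonomy <- if (!is.null(config$partonomy))
    read_partonomy(config$partonomy)
  m <- build_matrix(ann,
                    inherit = isTRUE(config$inherit),
                    infer_presence = isTRUE(config$infer_presence),
                    lineage = lineage, partonomy = partonomy)
  note("matricize", paste(length(m$taxa), "taxa x", ncol(m$cells),
                          "characters,", sum(nzchar(m$cells)),
                          "non-empty cells"))

  if (!is.null(config$edits)) {
    s <- read_edit_script(config$edits)
    m <- apply_script(m, s)
    eff <- count_effort(s)
    note("edit", paste0(length(s), " ops (effort ", eff[["edits"]],
                        ", splits ", eff[["splits"]], ")"))
  }
  write_matrix_csv(m, file.path(config$out_dir, "matrix.csv"))

  report <- NULL
  if (!is.null(config$gold)) {
    need(file.exists(config$gold),
         paste0("missing input file: ", config$gold))
    gold <- read_matrix_csv(config$gold)
    if (!length(m$taxa) || !ncol(m$cells))
      stop("pipeline: evaluation impossible, the machine matrix has no cells")
    report <- precision_recall_f1(m, gold)
    write_eval_report(report, file.path(config$out_dir, "report.json"))
    note("evaluate", paste0("P=", percent(report$precision),
                            "% R=", percent(report$recall),
                            "% F1=", percent(report$f1), "%"))
  }
  utils::write.csv(log, file.path(config$out_dir, "run_log.csv"),
                   row.names = FALSE)
  invisible(list(matrix = m, report = report, log = log))
}

#' @rdname run_pipeline
#' @param path YAML configuration file.
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)
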