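#' Column edit operations
#'
#' Matrix review is modelled as an ordered script of column-based
#' operations: \code{merge} (union several source columns into one
#' destination, chosen among them or new), \code{rename} (relabel a
#' column), \code{delete} (drop a column) and \code{split} (explode a
#' compound column into per-component columns). Scripts are auditable and
#' replayable.
#'
#' @param kind one of \code{"merge"}, \code{"rename"}, \code{"delete"},
#'   \code{"split"}.
#' @param targets source column name(s); merges need at least two.
#' @param dest destination column name (merge, rename).
#' @param components component names for a split, in slash order.
#' @return An object of class \code{edit_op}.
#' @export
edit_op <- function(kind = c("merge", "rename", "delete", "split"),
                    targets, dest = NULL, components = NULL) {
  kind <- match.arg(kind)
  targets <- as.character(targets)
  if (!length(targets)) stop("edit_op needs at least one target column")
  if (kind == "merge" && length(targets) < 2L)
    stop("merge needs at least two source columns")
  if (kind %in% c("merge", "rename") &&
      (is.null(dest) || !nzchar(dest)))
    stop(kind, " needs a destination column name")
  if (kind == "split" && length(components) < 2L)
    stop("split needs at least two component names")
  structure(list(kind = kind, targets = targets, dest = dest,
                 components = components),
            class = "edit_op")
}

#' @export
print.edit_op <- function(x, ...) {
  cat("<edit_op> ", x$kind, ": ", paste(x$targets, collapse = " + "),
      if (!is.null(x$dest)) paste0(" -> ", x$dest),
      if (!is.null(x$components))
        paste0(" [", paste(x$components, collapse = "/"), "]"),
      "\n", sep = "")
  invisible(x)
}

#' @rdname edit_op
#' @param ops list of \code{edit_op}.
#' @export
edit_script <- function(ops = list()) {
  stopifnot(all(vapply(ops, inherits, logical(1), "edit_op")))
  structure(list(ops = ops), class = "edit_script")
}

#' @export
print.edit_script <- function(x, ...) {
  eff <- count_effort(x)
  cat("<edit_script> ", length(x$ops), " ops (effort ", eff["edits"],
      ", splits ", eff["splits"], ")\n", sep = "")
  invisible(x)
}

#' @export
length.edit_script <- function(x) length(x$ops)

#' Apply one edit operation to a matrix
#'
#' \code{merge}: the destination column receives the union of all source
#' cells; where a taxon has values in several sources the destination's own
#' value wins and the others are dropped with a warning; source columns are
#' removed. \code{rename}: the column is relabelled, cells untouched.
#' \code{delete}: the column is removed. \code{split}: each cell of a
#' compound column ("0.52/0.44 mm") is distributed positionally over the
#' component columns, the shared unit distributing to every part; the
#' column name gains the component either by substituting a slash template
#' it contains ("length of tibia/metatarsus" -> "length of tibia") or by
#' appending "(split, <component>)".
#'
#' @param m a \code{taxon_matrix}.
#' @param op an \code{edit_op}.
#' @return The edited matrix, with attribute \code{"affected"} counting the
#'   values touched by the operation.
#' @export
apply_edit <- function(m, op) {
  stopifnot(inherits(m, "taxon_matrix"), inherits(op, "edit_op"))
  missing_cols <- setdiff(op$targets, colnames(m$cells))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  affected <- 0L
  if (op$kind == "delete") {
    affected <- sum(nzchar(m$cells[, op$targets[1]]))
    m$cells <- m$cells[, setdiff(colnames(m$cells), op$targets[1]),
                       drop = FALSE]
  } else if (op$kind == "rename") {
    affected <- sum(nzchar(m$cells[, op$targets[1]]))
    if (op$dest %in% colnames(m$cells))
      stop("rename destination already exists: ", op$dest)
    colnames(m$cells)[colnames(m$cells) == op$targets[1]] <- op$dest
  } else if (op$kind == "merge") {
    sources <- op$targets
    dest <- op$dest
    if (!dest %in% colnames(m$cells)) {
      # new destination column named by the user
      m$cells <- cbind(m$cells,
                       matrix("", nrow = nrow(m$cells),
                              dimnames = list(NULL, dest)))
    }
    affected <- sum(nzchar(m$cells[, unique(c(sources, dest))]))
    for (src in setdiff(sources, dest)) {
      have <- nzchar(m$cells[, src])
      clash <- have & nzchar(m$cells[, dest])
      if (any(clash))
        warning("merge conflict for ", sum(clash), " taxa in '", src,
                "': keeping destination value")
      take <- have & !nzchar(m$cells[, dest])
      m$cells[take, dest] <- m$cells[take, src]
    }
    m$cells <- m$cells[, setdiff(colnames(m$cells),
                                 setdiff(sources, dest)), drop = FALSE]
  } else if (op$kind == "split") {
    src <- op$targets[1]
    comps <- op$components
    k <- length(comps)
    slash <- paste(comps, collapse = "/")
    newnames <- if (grepl(slash, src, fixed = TRUE))
      vapply(comps, function(cm) sub(slash, cm, src, fixed = TRUE), "")
    else paste0(src, " (split, ", comps, ")")
    cells <- m$cells[, src]
    parts <- matrix("", nrow = nrow(m$cells), ncol = k,
                    dimnames = list(NULL, newnames))
    for (r in which(nzchar(cells))) {
      v <- cells[r]
      if (v == missing_marker) { parts[r, ] <- missing_marker; next }
      unit <- find_unit(v)
      vals <- strsplit(sub(paste0("\\s*", unit_rx, "\\s*$"), "", v,
                           perl = TRUE),
                       "/", fixed = TRUE)[[1]]
      vals <- trimws(vals)
      affected <- affected + sum(nzchar(vals))
      for (j in seq_len(min(k, length(vals))))
        if (nzchar(vals[j]))
          parts[r, j] <- format_cell(vals[j], unit)
    }
    keep <- setdiff(colnames(m$cells), src)
    m$cells <- cbind(m$cells[, keep, drop = FALSE], parts)
  }
  attr(m, "affected") <- affected
  m
}

#' Apply an edit script
#'
#' Folds [apply_edit()] over the script in order and records, per
#' operation, how many values it affected.
#'
#' @param m a \code{taxon_matrix}.
#' @param s an \code{edit_script}.
#' @return The edited matrix; attribute \code{"edit_log"} is a data frame
#'   with one row per op (\code{kind}, \code{targets}, \code{affected}).
#' @export
apply_script <- function(m, s) {
  stopifnot(inherits(s, "edit_script"))
  log <- data.frame(kind = character(), targets = character(),
                    affected = integer(), stringsAsFactors = FALSE)
  for (op in s$ops) {
    m <- apply_edit(m, op)
    log <- rbind(log, data.frame(
      kind = op$kind, targets = paste(op$targets, collapse = " + "),
      affected = attr(m, "affected"), stringsAsFactors = FALSE))
  }
  attr(m, "edit_log") <- log
  attr(m, "affected") <- NULL
  m
}

#' Edit effort of a script
#'
#' Deletions and renames cost one edit each; a merge of k source columns
#' costs k - 1 (merging never counts again as a rename). Split operations
#' are tallied separately from edit effort.
#'
#' @param s an \code{edit_script}.
#' @return Named integer vector \code{c(edits = ..., splits = ...)}.
#' @export
count_effort <- function(s) {
  stopifnot(inherits(s, "edit_script"))
  edits <- 0L
  splits <- 0L
  for (op in s$ops) {
    if (op$kind == "split") splits <- splits + 1L
    else if (op$kind == "merge") edits <- edits + length(op$targets) - 1L
    else edits <- edits + 1L
  }
  c(edits = edits, splits = splits)
}

#' Read and write edit scripts as JSON lines
#'
#' One JSON object per line with fields \code{kind}, \code{targets} and,
#' where applicable, \code{dest} or \code{components}; the format doubles
#' as an audit log and replays to an identical result.
#'
#' @param s an \code{edit_script}.
#' @param path file path.
#' @export
write_edit_script <- function(s, path) {
  stopifnot(inherits(s, "edit_script"))
  lines <- vapply(s$ops, function(op) {
    x <- Filter(Negate(is.null),
                list(kind = op$kind, targets = op$targets,
                     dest = op$dest, components = op$components))
    jsonlite::toJSON(x, auto_unbox = FALSE)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edit_script
#' @export
read_edit_script <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ops <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    edit_op(x$kind, x$targets, dest = x$dest, components = x$components)
  })
  edit_script(ops)
}
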