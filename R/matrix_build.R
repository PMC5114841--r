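#' Taxon-character matrices
#'
#' Rows are exemplars (in document order), columns are canonical character
#' names of the form \code{"<character> of <entity path>"} ("length of
#' leg-i tibia"). Cells are strings: an empty string is an empty cell, the
#' marker \code{"?"} an explicit-missing state (distinct from empty, so it
#' can be scored against a gold standard), and anything else a value with
#' its optional unit ("0.52 mm").
#'
#' @param taxa character vector of exemplar labels.
#' @param characters character vector of unique column names.
#' @return An object of class \code{taxon_matrix} with elements
#'   \code{taxa}, \code{cells} (character matrix) and \code{provenance}
#'   (named list of per-cell notes).
#' @export
taxon_matrix <- function(taxa, characters) {
  taxa <- as.character(taxa)
  characters <- as.character(characters)
  if (anyDuplicated(characters))
    stop("character names must be unique: ",
         paste(unique(characters[duplicated(characters)]), collapse = ", "))
  cells <- matrix("", nrow = length(taxa), ncol = length(characters),
                  dimnames = list(taxa, characters))
  structure(list(taxa = taxa, cells = cells, provenance = list()),
            class = "taxon_matrix")
}

#' @export
print.taxon_matrix <- function(x, ...) {
  cat("<taxon_matrix> ", length(x$taxa), " taxa x ", ncol(x$cells),
      " characters, ", sum(nzchar(x$cells)), " non-empty cells\n", sep = "")
  invisible(x)
}

#' @export
dim.taxon_matrix <- function(x) dim(x$cells)

missing_marker <- "?"

is_filled <- function(cells) nzchar(cells) & cells != missing_marker

format_cell <- function(value, unit) {
  ifelse(is.na(value), "",
         ifelse(is.na(unit), value, paste(value, unit)))
}

#' Canonical character column name for a record
#'
#' @param character character label ("length").
#' @param entity entity path, space-joined canonical terms ("leg-i tibia").
#' @return \code{"<character> of <entity>"}, lower case.
#' @export
character_name <- function(character, entity)
  paste(tolower(character), "of", entity)

#' Consolidate annotated documents into a taxon-character matrix
#'
#' One row per document (exemplar) in input order; one column per distinct
#' canonical character name, in first-appearance order. Records with null
#' values contribute their column but leave the cell empty. When two
#' records claim the same cell the first is kept and a warning names the
#' dropped value.
#'
#' @param docs list of \code{annotated_doc}.
#' @param inherit,infer_presence options applied after consolidation via
#'   [inherit_values()] (needs \code{lineage}) and [infer_presence()]
#'   (needs \code{partonomy}).
#' @param lineage named list mapping taxon -> character vector of ancestor
#'   taxa, nearest first.
#' @param partonomy a part-of edge data frame (see [partonomy_graph()]).
#' @return A \code{taxon_matrix}.
#' @export
build_matrix <- function(docs, inherit = FALSE, infer_presence = FALSE,
                         lineage = NULL, partonomy = NULL) {
  stopifnot(all(vapply(docs, inherits, logical(1), "annotated_doc")))
  taxa <- vapply(docs, function(d) d$doc$taxon_name, "")
  recs <- bind_records(lapply(docs, `[[`, "records"))
  cols <- if (nrow(recs))
    unique(character_name(recs$character, recs$entity))
  else character()
  m <- taxon_matrix(taxa, cols)
  if (nrow(recs)) {
    dropped <- 0L
    for (i in seq_len(nrow(recs))) {
      if (is.na(recs$value[i])) next
      r <- match(recs$taxon[i], m$taxa)
      cn <- character_name(recs$character[i], recs$entity[i])
      if (nzchar(m$cells[r, cn])) {
        dropped <- dropped + 1L
        warning("duplicate value for (", recs$taxon[i], ", ", cn,
                "): keeping first, dropping '",
                format_cell(recs$value[i], recs$unit[i]), "'")
        next
      }
      m$cells[r, cn] <- format_cell(recs$value[i], recs$unit[i])
    }
    attr(m, "conflicts_dropped") <- dropped
  }
  if (inherit && !is.null(lineage)) m <- inherit_values(m, lineage)
  if (infer_presence && !is.null(partonomy))
    m <- infer_presence(m, partonomy)
  m
}

#' Fullness of a matrix
#'
#' The fraction of cells that are populated. Explicit-missing (\code{"?"})
#' cells count as empty by default, so fullness reflects data actually
#' carried by the matrix; set \code{count_missing = TRUE} to count them as
#' populated states instead.
#'
#' @param m a \code{taxon_matrix} with at least one taxon and character.
#' @param count_missing count \code{"?"} cells as populated.
#' @return A fraction in \code{[0, 1]}.
#' @export
fullness <- function(m, count_missing = FALSE) {
  stopifnot(inherits(m, "taxon_matrix"))
  if (!length(m$taxa) || !ncol(m$cells))
    stop("fullness is undefined for a zero-dimension matrix")
  filled <- if (count_missing) nzchar(m$cells) else is_filled(m$cells)
  sum(filled) / length(m$cells)
}

#' Propagate higher-rank values to lower ranks
#'
#' Characters recorded at a higher rank (e.g. a genus row) are propagated
#' to each descendant taxon whose cell is empty; the nearest ancestor with
#' a value wins, existing values are never overwritten, and inherited cells
#' are marked in the matrix provenance. Applying the operation twice
#' changes nothing.
#'
#' @param m a \code{taxon_matrix}.
#' @param lineage named list: taxon -> ancestors present in \code{m},
#'   nearest first.
#' @return The augmented matrix.
#' @export
inherit_values <- function(m, lineage) {
  stopifnot(inherits(m, "taxon_matrix"))
  if (is.null(lineage) || !length(lineage)) return(m)
  for (taxon in names(lineage)) {
    r <- match(taxon, m$taxa)
    if (is.na(r)) next
    anc <- intersect(lineage[[taxon]], m$taxa)
    for (cn in colnames(m$cells)) {
      if (nzchar(m$cells[r, cn])) next
      for (a in anc) {
        v <- m$cells[match(a, m$taxa), cn]
        if (nzchar(v)) {
          m$cells[r, cn] <- v
          m$provenance[[paste(taxon, cn, sep = "\r")]] <-
            paste0("inherited from ", a)
          break
        }
      }
    }
  }
  m
}

#' Part-of graphs
#'
#' A partonomy is a set of directed part-of edges over structure terms
#' (child is part of parent). The graph must be acyclic.
#'
#' @param child,parent character vectors of equal length.
#' @return A data frame of class \code{partonomy_graph}.
#' @export
partonomy_graph <- function(child = character(), parent = character()) {
  g <- data.frame(child = canonical_term(child),
                  parent = canonical_term(parent),
                  stringsAsFactors = FALSE)
  if (has_cycle(g)) stop("partonomy graph contains a cycle")
  class(g) <- c("partonomy_graph", "data.frame")
  g
}

#' @rdname partonomy_graph
#' @param path two-column TSV file (child, parent); \code{#} comments allowed.
#' @export
read_partonomy <- function(path) {
  cols <- read_two_col(path)
  partonomy_graph(names(cols), unname(cols))
}

has_cycle <- function(g) {
  nodes <- unique(c(g$child, g$parent))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  visit <- function(n) {
    if (state[[n]] == 1L) return(TRUE)
    if (state[[n]] == 2L) return(FALSE)
    state[[n]] <<- 1L
    for (p in g$parent[g$child == n]) if (visit(p)) return(TRUE)
    state[[n]] <<- 2L
    FALSE
  }
  any(vapply(nodes, visit, logical(1)))
}

# all partonomy ancestors of a set of terms (BFS over child -> parent edges)
partonomy_ancestors <- function(g, terms) {
  seen <- character()
  frontier <- unique(terms)
  while (length(frontier)) {
    parents <- unique(g$parent[g$child %in% frontier])
    parents <- setdiff(parents, seen)
    seen <- c(seen, parents)
    frontier <- parents
  }
  seen
}

#' Infer presence of whole structures from their parts
#'
#' If any character is recorded for a structure in a taxon (or the
#' structure is explicitly marked present), every partonomy ancestor of
#' that structure must also be present: a leg cusple implies a leg. New
#' \code{"presence of <structure>"} columns are added (or existing ones
#' filled) with the state \code{"present"}. Cells explicitly stating
#' \code{"absent"} are never overwritten; such contradictions are reported
#' in the matrix provenance. The operation is idempotent.
#'
#' @param m a \code{taxon_matrix}.
#' @param g a \code{partonomy_graph}.
#' @return The augmented matrix.
#' @export
infer_presence <- function(m, g) {
  stopifnot(inherits(m, "taxon_matrix"))
  if (!nrow(g)) return(m)
  for (r in seq_along(m$taxa)) {
    col_entity <- sub("^.* of ", "", colnames(m$cells))
    present <- character()
    for (j in seq_len(ncol(m$cells))) {
      if (!is_filled(m$cells[r, j])) next
      if (startsWith(colnames(m$cells)[j], "presence of") &&
          tolower(m$cells[r, j]) != "present") next
      # every term on the entity path counts as observed
      present <- c(present,
                   strsplit(col_entity[j], " ", fixed = TRUE)[[1]])
    }
    for (anc in partonomy_ancestors(g, unique(present))) {
      cn <- paste("presence of", anc)
      if (!cn %in% colnames(m$cells)) {
        m$cells <- cbind(m$cells,
                         matrix("", nrow = nrow(m$cells),
                                dimnames = list(NULL, cn)))
      }
      cur <- m$cells[r, cn]
      if (tolower(cur) == "absent") {
        m$provenance[[paste(m$taxa[r], cn, sep = "\r")]] <-
          "contradiction: part present while ancestor marked absent"
      } else if (!nzchar(cur)) {
        m$cells[r, cn] <- "present"
        m$provenance[[paste(m$taxa[r], cn, sep = "\r")]] <- "inferred"
      }
    }
  }
  m
}
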