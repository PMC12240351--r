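#' Construct a hydrogen-suppressed molecular graph
#'
#' A molecular graph stores the heavy-atom skeleton of a compound: vertices are
#' atoms (opaque string identifiers) and edges are bonds.  Bond orders,
#' aromaticity and charges are deliberately ignored -- every bond contributes a
#' single edge and vertex degrees are taken in this simple graph, which is the
#' convention under which the degree-pair edge partitions of the drug structures
#' treated here are reproducible.
#'
#' @param edges a data frame (or tibble) with two character columns giving the
#'   endpoints of each bond, or a two-column character matrix.
#' @param name optional compound name.
#' @return an object of class `mol_graph` with elements `vertices` (character),
#'   `edges` (tibble with columns `from`, `to`) and `name`.
#' @examples
#' g <- mol_graph(data.frame(from = c("1", "2", "3"), to = c("2", "3", "4")))
#' edge_partition(g)
#' @export
mol_graph <- function(edges, name = NULL) {
  if (is.matrix(edges)) edges <- tibble::tibble(from = edges[, 1], to = edges[, 2])
  edges <- tibble::as_tibble(edges)
  if (ncol(edges) < 2) stop("`edges` needs two endpoint columns", call. = FALSE)
  names(edges)[1:2] <- c("from", "to")
  edges <- dplyr::mutate(edges[1:2],
                         from = as.character(.data$from),
                         to   = as.character(.data$to))
  if (nrow(edges) == 0) stop("molecular graph must have at least one edge", call. = FALSE)
  if (any(edges$from == edges$to)) {
    bad <- which(edges$from == edges$to)[1]
    stop("self-loop at edge ", bad, " (", edges$from[bad], ")", call. = FALSE)
  }
  key <- edge_key(edges$from, edges$to)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop("duplicate edge at line ", bad, " (", edges$from[bad], " ", edges$to[bad], ")",
         call. = FALSE)
  }
  g <- structure(
    list(vertices = sort(unique(c(edges$from, edges$to))), edges = edges, name = name),
    class = "mol_graph"
  )
  if (n_components(g) > 1L) {
    warning("graph", if (!is.null(name)) paste0(" '", name, "'"),
            " is disconnected; indices are edge-local and still defined", call. = FALSE)
  }
  g
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

n_components <- function(g) {
  adj <- split(c(g$edges$to, g$edges$from), c(g$edges$from, g$edges$to))
  seen <- stats::setNames(logical(length(g$vertices)), g$vertices)
  ncomp <- 0L
  for (v in g$vertices) {
    if (seen[[v]]) next
    ncomp <- ncomp + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      if (seen[[u]]) next
      seen[[u]] <- TRUE
      nb <- adj[[u]]
      queue <- c(queue, nb[!seen[nb]])
    }
  }
  ncomp
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph>", if (!is.null(x$name)) x$name else "", "\n")
  cat("  vertices:", length(x$vertices), " edges:", nrow(x$edges), "\n")
  invisible(x)
}

#' Vertex degrees of a molecular graph
#'
#' @param graph a [mol_graph()].
#' @return named integer vector of degrees in the hydrogen-suppressed graph.
#' @export
vertex_degrees <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  tab <- table(factor(c(graph$edges$from, graph$edges$to), levels = graph$vertices))
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a molecular graph from an edge-list document
#'
#' One edge per non-comment line: two whitespace-separated vertex tokens.
#' Lines starting with `#` and blank lines are ignored.  Vertex identifiers are
#' preserved verbatim.
#'
#' @param file path to an edge-list file, or a character vector of lines when
#'   `text = TRUE`.
#' @param name optional compound name.
#' @param text if `TRUE`, `file` is the document content itself.
#' @return a [mol_graph()].
#' @examples
#' read_edge_list(c("1 2", "2 3", "3 4"), text = TRUE)
#' @export
read_edge_list <- function(file, name = NULL, text = FALSE) {
  lines <- if (text) unlist(strsplit(file, "\n", fixed = TRUE)) else readLines(file)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("empty edge-list document", call. = FALSE)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nt <- lengths(toks)
  if (any(nt != 2)) {
    stop("line ", idx[which(nt != 2)[1]], ": expected two vertex tokens", call. = FALSE)
  }
  ends <- do.call(rbind, toks)
  if (any(ends[, 1] == ends[, 2])) {
    stop("line ", idx[which(ends[, 1] == ends[, 2])[1]], ": self-loop", call. = FALSE)
  }
  key <- edge_key(ends[, 1], ends[, 2])
  if (anyDuplicated(key)) {
    stop("line ", idx[which(duplicated(key))[1]], ": duplicate edge", call. = FALSE)
  }
  mol_graph(ends, name = name)
}

#' Read a molecular graph from a SMILES string
#'
#' Parses a SMILES string into its heavy-atom skeleton: hydrogens are
#' suppressed, bond orders and aromaticity collapse to single edges, charges and
#' isotopes are ignored.  Parsing is delegated to the ChemmineR/ChemmineOB
#' toolchain; when that adapter is not installed an explicit error is raised
#' rather than a silent fallback.
#'
#' @param smiles a single SMILES string.
#' @param name optional compound name.
#' @return a [mol_graph()].
#' @export
read_smiles <- function(smiles, name = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("SMILES support not installed (needs the ChemmineR/ChemmineOB adapter)",
         call. = FALSE)
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]],
    error = function(e) stop("unparseable SMILES: ", conditionMessage(e), call. = FALSE)
  )
  atoms <- rownames(ChemmineR::atomblock(sdf))
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb)) || nrow(bb) == 0) stop("SMILES has no bonds between heavy atoms",
                                              call. = FALSE)
  from <- atoms[bb[, 1]]
  to <- atoms[bb[, 2]]
  heavy <- !grepl("^H_", atoms)
  keep <- !grepl("^H_", from) & !grepl("^H_", to)
  ends <- unique(cbind(pmin(from[keep], to[keep]), pmax(from[keep], to[keep])))
  mol_graph(ends, name = name)
}

#' Degree-pair edge partition of a molecular graph
#'
#' Groups the edges of a graph by the unordered pair of endpoint degrees
#' \eqn{(i, j)}, \eqn{i \le j}, computed in the hydrogen-suppressed graph.  The
#' partition is the sole input every degree-based index here needs.
#'
#' @param graph a [mol_graph()].
#' @return a tibble with columns `du`, `dv` (`du <= dv`) and `count`; the total
#'   edge count is `sum(count)`.
#' @examples
#' g <- read_edge_list(c("1 2", "2 3", "3 4"), text = TRUE)
#' edge_partition(g)  # {(1,2): 2, (2,2): 1}
#' @export
edge_partition <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  deg <- vertex_degrees(graph)
  du <- pmin(deg[graph$edges$from], deg[graph$edges$to])
  dv <- pmax(deg[graph$edges$from], deg[graph$edges$to])
  tibble::tibble(du = as.integer(du), dv = as.integer(dv)) |>
    dplyr::count(.data$du, .data$dv, name = "count") |>
    dplyr::arrange(.data$du, .data$dv)
}

#' Build an edge partition from printed degree-pair counts
#'
#' Lets a partition printed in the literature be entered without regenerating
#' the structure.  Keys are normalized so \eqn{i \le j}; cells that coincide
#' after normalization are summed.
#'
#' @param rows a data frame with columns `du`, `dv`, `count` (any order of the
#'   degree pair), or a numeric matrix with three columns.
#' @return a tibble with columns `du`, `dv`, `count`.
#' @examples
#' partition_from_counts(data.frame(
#'   du = c(3, 2, 2, 2, 3), dv = c(1, 3, 2, 4, 3), count = c(2, 6, 3, 4, 2)
#' ))
#' @export
partition_from_counts <- function(rows) {
  if (is.matrix(rows)) rows <- tibble::tibble(du = rows[, 1], dv = rows[, 2], count = rows[, 3])
  rows <- tibble::as_tibble(rows)
  if (!all(c("du", "dv", "count") %in% names(rows))) {
    names(rows)[1:3] <- c("du", "dv", "count")
  }
  rows <- rows[c("du", "dv", "count")]
  if (nrow(rows) == 0) stop("empty partition", call. = FALSE)
  ok <- function(v) all(is.finite(v)) && all(v > 0) && all(v == round(v))
  if (!ok(rows$du) || !ok(rows$dv) || !ok(rows$count)) {
    stop("degrees and counts must be positive integers", call. = FALSE)
  }
  tibble::tibble(
    du = as.integer(pmin(rows$du, rows$dv)),
    dv = as.integer(pmax(rows$du, rows$dv)),
    count = as.integer(rows$count)
  ) |>
    dplyr::count(.data$du, .data$dv, wt = .data$count, name = "count") |>
    dplyr::arrange(.data$du, .data$dv)
}

check_partition <- function(partition) {
  partition <- tibble::as_tibble(partition)
  if (!all(c("du", "dv", "count") %in% names(partition))) {
    stop("a partition needs columns du, dv, count", call. = FALSE)
  }
  partition_from_counts(partition)
}

#' Read a degree-pair partition from CSV
#'
#' Expects the header `du,dv,count`.
#'
#' @param file path to a CSV file.
#' @return a tibble with columns `du`, `dv`, `count`.
#' @export
read_partition_csv <- function(file) {
  partition_from_counts(readr::read_csv(file, show_col_types = FALSE))
}
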