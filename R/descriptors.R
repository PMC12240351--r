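#' Names of the supported degree-based indices
#'
#' ABC (atom-bond connectivity), F (Forgotten), GA (geometric-arithmetic),
#' H (harmonic), ISI (inverse sum indeg), M1/M2 (first/second Zagreb),
#' S (sum-connectivity), SO (Sombor) and R (Randic).
#'
#' @return character vector of the ten index names.
#' @export
index_names <- function() {
  c("ABC", "F", "GA", "H", "ISI", "M1", "M2", "S", "SO", "R")
}

# edge-weight rules phi(i, j); all symmetric and strictly positive for
# i, j >= 1 except ABC at (1, 1), which is 0 (degenerate K2 component)
edge_weight_rules <- list(
  ABC = function(i, j) sqrt((i + j - 2) / (i * j)),
  F   = function(i, j) i^2 + j^2,
  GA  = function(i, j) 2 * sqrt(i * j) / (i + j),
  H   = function(i, j) 2 / (i + j),
  ISI = function(i, j) i * j / (i + j),
  M1  = function(i, j) i + j,
  M2  = function(i, j) i * j,
  S   = function(i, j) 1 / sqrt(i + j),
  SO  = function(i, j) sqrt(i^2 + j^2),
  R   = function(i, j) 1 / sqrt(i * j)
)

#' Edge weight of a degree pair under a named index
#'
#' The weight \eqn{\phi(i, j)} an edge with endpoint degrees \eqn{(i, j)}
#' contributes to a topological index: e.g. \eqn{\phi_F = i^2 + j^2},
#' \eqn{\phi_{ABC} = \sqrt{(i+j-2)/(ij)}}, \eqn{\phi_{GA} = 2\sqrt{ij}/(i+j)}.
#'
#' @param name one of [index_names()].
#' @param i,j endpoint degrees (positive integers, vectorized).
#' @return numeric edge weight(s).  `ABC` on a (1,1) edge returns 0 with a
#'   warning: the corresponding entropy term is taken as \eqn{0 \log 0 = 0}.
#' @examples
#' edge_weight("F", 2, 3)   # 13
#' edge_weight("GA", 2, 2)  # 1
#' @export
edge_weight <- function(name, i, j) {
  name <- match.arg(name, index_names())
  stopifnot(all(i >= 1), all(j >= 1), all(i == round(i)), all(j == round(j)))
  w <- edge_weight_rules[[name]](i, j)
  if (name == "ABC" && any(i == 1 & j == 1)) {
    warning("ABC weight is 0 on a (1,1) edge (degenerate K2 component)", call. = FALSE)
  }
  w
}

#' Degree-based topological index from an edge partition
#'
#' \deqn{T_\phi(G) = \sum_{(i,j)} n_{ij}\, \phi(i, j)}
#' summed over the cells of the degree-pair partition.
#'
#' @param partition tibble with columns `du`, `dv`, `count`
#'   (see [edge_partition()] / [partition_from_counts()]).
#' @param name one of [index_names()].
#' @return the index value (positive real).
#' @examples
#' oxa <- oxaliplatin_partition()
#' topological_index(oxa, "F")    # 238
#' topological_index(oxa, "ABC")  # 12.1587
#' @export
topological_index <- function(partition, name) {
  partition <- check_partition(partition)
  name <- match.arg(name, index_names())
  sum(partition$count * edge_weight(name, partition$du, partition$dv))
}

#' Shannon-type entropy index from an edge partition
#'
#' The entropy of the edge-weight distribution \eqn{p_e = \phi_e / T} with
#' \eqn{T = \sum_e \phi_e}, computed cell-wise from the partition:
#' \deqn{\mathrm{Ent}_\phi(G) = \ln T - \frac{1}{T} \sum_{(i,j)} n_{ij}\,
#'   \phi(i,j) \ln \phi(i,j).}
#' The logarithm is natural.  Cells with \eqn{\phi = 0} (only ABC on a (1,1)
#' edge) contribute 0 by the usual \eqn{0 \ln 0 = 0} convention.
#'
#' @inheritParams topological_index
#' @return the entropy value, in \eqn{[0, \ln m]} where `m = sum(count)`.
#' @examples
#' oxa <- oxaliplatin_partition()
#' entropy_index(oxa, "F")  # 2.7843
#' @export
entropy_index <- function(partition, name) {
  partition <- check_partition(partition)
  name <- match.arg(name, index_names())
  phi <- edge_weight(name, partition$du, partition$dv)
  T <- sum(partition$count * phi)
  if (T <= 0) stop("entropy undefined for zero total weight", call. = FALSE)
  terms <- ifelse(phi > 0, phi * log(phi), 0)
  log(T) - sum(partition$count * terms) / T
}

#' Per-compound descriptor table
#'
#' Computes entropy and/or topological index values for a set of compounds,
#' one row per compound (the layout of published descriptor tables).  Values
#' are kept at full floating precision; rounding happens only when a table is
#' serialized (see [write_descriptor_csv()]).
#'
#' @param partitions a named list of edge partitions (names are compound
#'   labels), or a single partition.
#' @param indices which indices to compute; default all ten.
#' @param type `"entropy"` (columns `Ent_<name>`), `"topological"`, or
#'   `"both"`.
#' @return a tibble with a `compound` column followed by descriptor columns.
#' @examples
#' descriptor_table(list(Oxaliplatin = oxaliplatin_partition()))
#' @export
descriptor_table <- function(partitions, indices = index_names(),
                             type = c("entropy", "topological", "both")) {
  type <- match.arg(type)
  if (is.data.frame(partitions)) partitions <- list(compound = partitions)
  if (length(partitions) == 0) stop("no compounds supplied", call. = FALSE)
  if (length(indices) == 0) stop("empty index-name set", call. = FALSE)
  indices <- vapply(indices, match.arg, "", choices = index_names())
  if (is.null(names(partitions))) {
    names(partitions) <- paste0("compound_", seq_along(partitions))
  }
  rows <- purrr::imap(partitions, function(p, label) {
    p <- tryCatch(check_partition(p),
                  error = function(e) stop("compound '", label, "': ",
                                           conditionMessage(e), call. = FALSE))
    out <- list(compound = label)
    if (type %in% c("entropy", "both")) {
      for (nm in indices) out[[paste0("Ent_", nm)]] <- entropy_index(p, nm)
    }
    if (type %in% c("topological", "both")) {
      for (nm in indices) out[[nm]] <- topological_index(p, nm)
    }
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}

#' Write / read a descriptor table as CSV
#'
#' Serialization rounds to `digits` decimal places (4 by default, the printed
#' precision of the published tables); reading restores a plain tibble.
#'
#' @param table a descriptor tibble (first column `compound`).
#' @param file path to write to / read from.
#' @param digits decimal places used at serialization.
#' @return `write_descriptor_csv()` returns `table` invisibly;
#'   `read_descriptor_csv()` returns a tibble.
#' @export
write_descriptor_csv <- function(table, file, digits = 4) {
  out <- dplyr::mutate(table, dplyr::across(dplyr::where(is.numeric),
                                            ~ round(.x, digits)))
  readr::write_csv(out, file)
  invisible(table)
}

#' @rdname write_descriptor_csv
#' @export
read_descriptor_csv <- function(file) {
  readr::read_csv(file, show_col_types = FALSE)
}
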