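# run code under a local RNG state derived from `seed`, restoring the caller's
with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Generate a chemistry-like random molecular graph
#'
#' Random growth of a degree-capped tree -- each new atom attaches to a
#' uniformly chosen existing atom that still has free valence -- followed by
#' ring closures: candidate edges between non-adjacent, degree-deficient
#' vertex pairs are added one at a time.  The result is a connected simple
#' graph with degrees in `[1, max_degree]`, the qualitative shape of a
#' hydrogen-suppressed small-molecule skeleton.
#'
#' @param n_atoms number of heavy atoms (>= 1; a 1-atom graph is rejected
#'   because indices need at least one edge).
#' @param max_degree valence cap (default 4, the organic-chemistry maximum
#'   for the common heavy atoms).
#' @param ring_prob expected proportion of ring-closing bonds relative to
#'   atoms, in `[0, 1]`; 0 yields a tree.
#' @param seed integer seed; the same seed gives the identical edge set.
#' @return a [mol_graph()].
#' @examples
#' g <- gen_graph(12, seed = 1)
#' edge_partition(g)
#' @export
gen_graph <- function(n_atoms, max_degree = 4, ring_prob = 0.15, seed = 1) {
  if (n_atoms < 1) stop("atom count must be >= 1", call. = FALSE)
  if (n_atoms < 2) stop("a molecular graph needs at least one bond (n_atoms >= 2)",
                        call. = FALSE)
  stopifnot(max_degree >= 1, ring_prob >= 0, ring_prob <= 1)
  if (max_degree == 1 && n_atoms > 2) {
    stop("max_degree 1 cannot host more than 2 atoms in a connected graph",
         call. = FALSE)
  }
  with_rng(seed, {
    deg <- integer(n_atoms)
    from <- integer(0); to <- integer(0)
    for (v in seq(2, n_atoms)) {
      open <- which(deg[seq_len(v - 1)] < max_degree)
      u <- if (length(open) == 1) open else sample(open, 1)
      from <- c(from, u); to <- c(to, v)
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
    }
    adj <- matrix(FALSE, n_atoms, n_atoms)
    adj[cbind(from, to)] <- TRUE; adj[cbind(to, from)] <- TRUE
    n_close <- stats::rbinom(1, n_atoms, ring_prob)
    for (i in seq_len(n_close)) {
      open <- which(deg < max_degree)
      if (length(open) < 2) break
      pairs <- which(!adj[open, open, drop = FALSE] &
                       upper.tri(matrix(TRUE, length(open), length(open))),
                     arr.ind = TRUE)
      if (nrow(pairs) == 0) break
      pick <- pairs[if (nrow(pairs) == 1) 1 else sample(nrow(pairs), 1), ]
      u <- open[pick[1]]; v <- open[pick[2]]
      from <- c(from, u); to <- c(to, v)
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
      adj[u, v] <- TRUE; adj[v, u] <- TRUE
    }
    mol_graph(cbind(paste0("a", from), paste0("a", to)))
  })
}

#' Specification for a synthetic QSPR dataset
#'
#' Bundles the generator settings: how many compounds, their size range, the
#' entropy descriptor, and the ground-truth property model
#' \eqn{y = f(h) + \varepsilon}, \eqn{\varepsilon \sim N(0, \sigma^2)},
#' where \eqn{h} is the chosen entropy index of each generated graph.
#' Defaults mirror the real study: 14 compounds of 8--40 heavy atoms,
#' valence cap 4, and a cubic ground truth with coefficients and residual
#' scale taken from the published molecular-weight model.
#'
#' @param n_compounds number of synthetic compounds.
#' @param atom_range inclusive range of heavy-atom counts.
#' @param max_degree valence cap.
#' @param ring_prob ring-closure intensity, see [gen_graph()].
#' @param index entropy index used as the descriptor.
#' @param family ground-truth family, one of [qspr_families()].
#' @param a,b ground-truth intercept and slope coefficients.
#' @param sigma Gaussian noise standard deviation (property units; >= 0).
#' @param seed integer master seed; per-compound substreams are derived by
#'   counter, so compound order is irrelevant.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 14, atom_range = c(8, 40),
                           max_degree = 4, ring_prob = 0.15, index = "ABC",
                           family = "cubic", a = 323.0,
                           b = c(18.4, -75.9, 24.7), sigma = 65, seed = 1) {
  family <- match.arg(family, qspr_families())
  index <- match.arg(index, index_names())
  if (sigma < 0) stop("noise sd must be nonnegative", call. = FALSE)
  if (n_compounds < family_k(family) + 2) {
    stop("n_compounds must be at least k + 2 = ", family_k(family) + 2,
         " for the ", family, " family", call. = FALSE)
  }
  if (length(b) != family_k(family)) {
    stop("ground truth needs ", family_k(family), " slope coefficient(s)",
         call. = FALSE)
  }
  structure(list(
    n_compounds = as.integer(n_compounds), atom_range = as.integer(atom_range),
    max_degree = max_degree, ring_prob = ring_prob, index = index,
    family = family, a = a, b = as.numeric(b), sigma = sigma,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a synthetic descriptor + property dataset
#'
#' For each synthetic compound: draw a random graph ([gen_graph()]), compute
#' the chosen entropy descriptor \eqn{h}, and simulate the property as
#' \eqn{y = f(h) + N(0, \sigma^2)} under the spec's ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `descriptors` (tibble `compound`,
#'   `Ent_<index>`, `n_atoms`, `n_edges`), `properties` (tibble `compound`,
#'   `y`), `truth` (the generating family, coefficients and sigma) and
#'   `graphs` (list of [mol_graph()]s).
#' @examples
#' d <- gen_dataset(synthetic_spec(n_compounds = 10, sigma = 0, seed = 7))
#' @export
gen_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  col <- paste0("Ent_", spec$index)
  rows <- purrr::map(seq_len(spec$n_compounds), function(i) {
    sub <- (spec$seed + 9973L * i) %% .Machine$integer.max
    n_atoms <- with_rng(sub, sample(seq(spec$atom_range[1], spec$atom_range[2]), 1))
    g <- gen_graph(n_atoms, spec$max_degree, spec$ring_prob, seed = sub + 1L)
    h <- entropy_index(edge_partition(g), spec$index)
    noise <- with_rng(sub + 2L, stats::rnorm(1, 0, spec$sigma))
    y <- eval_family(spec$family, spec$a, spec$b, h) + noise
    list(graph = g,
         desc = tibble::tibble(compound = sprintf("syn_%03d", i),
                               !!col := h, n_atoms = length(g$vertices),
                               n_edges = nrow(g$edges)),
         prop = tibble::tibble(compound = sprintf("syn_%03d", i), y = y))
  })
  list(
    descriptors = dplyr::bind_rows(purrr::map(rows, "desc")),
    properties = dplyr::bind_rows(purrr::map(rows, "prop")),
    truth = list(family = spec$family, a = spec$a, b = spec$b,
                 sigma = spec$sigma, index = spec$index),
    graphs = purrr::map(rows, "graph")
  )
}
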