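# Independent oracles: everything here recomputes quantities from first
# principles (per-edge sums, normal equations) without going through the
# package's partition-based code paths.

# edge-weight formulas restated independently
oracle_phi <- list(
  ABC = function(i, j) sqrt((i + j - 2) / (i * j)),
  F   = function(i, j) i * i + j * j,
  GA  = function(i, j) 2 * sqrt(i * j) / (i + j),
  H   = function(i, j) 2 / (i + j),
  ISI = function(i, j) (i * j) / (i + j),
  M1  = function(i, j) i + j,
  M2  = function(i, j) i * j,
  S   = function(i, j) 1 / sqrt(i + j),
  SO  = function(i, j) sqrt(i * i + j * j),
  R   = function(i, j) 1 / sqrt(i * j)
)

# per-edge degree pairs of a mol_graph, computed directly from the edge list
oracle_edge_degrees <- function(g) {
  deg <- table(c(g$edges$from, g$edges$to))
  cbind(as.numeric(deg[g$edges$from]), as.numeric(deg[g$edges$to]))
}

# per-edge sum form of a topological index
oracle_topological <- function(g, name) {
  dd <- oracle_edge_degrees(g)
  sum(oracle_phi[[name]](dd[, 1], dd[, 2]))
}

# Shannon form: -sum p_e log p_e over individual edges, p_e = phi_e / T
oracle_entropy <- function(g, name) {
  dd <- oracle_edge_degrees(g)
  phi <- oracle_phi[[name]](dd[, 1], dd[, 2])
  p <- phi / sum(phi)
  -sum(ifelse(p > 0, p * log(p), 0))
}

# brute-force least squares through the normal equations
oracle_ols <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# a pool of random chemistry-like graphs for property tests
random_graphs <- function(n = 100, seed0 = 1000) {
  lapply(seq_len(n), function(i) {
    gen_graph(n_atoms = 5 + (i %% 30), max_degree = 2 + (i %% 3),
              ring_prob = (i %% 4) / 10, seed = seed0 + i)
  })
}

crc_joined <- function() {
  dplyr::inner_join(crc_descriptors(), crc_properties(), by = "compound")
}
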