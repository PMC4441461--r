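# Shared fixtures: tiny hierarchies, random reciprocal matrices, and an
# independent eigen-decomposition oracle for priority derivation.

minimal_model <- function() {
  decision_hierarchy("pick one", list("criterion A", "criterion B"),
                     c("alt 1", "alt 2"))
}

# goal -> n_leaves flat criteria -> alternatives
flat_model <- function(n_leaves = 3, alternatives = c("A", "B", "C")) {
  decision_hierarchy("goal",
                     as.list(paste0("crit ", seq_len(n_leaves))),
                     alternatives)
}

random_simplex <- function(n, concentration = 1) {
  g <- rgamma(n, shape = concentration)
  g / sum(g)
}

# positive reciprocal matrix with log-normal upper-triangle entries
random_reciprocal <- function(n, spread = 1) {
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- exp(rnorm(1, sd = spread))
      m[j, i] <- 1 / m[i, j]
    }
  }
  pairwise_matrix(m, items = paste0("it", seq_len(n)))
}

random_consistent <- function(n, concentration = 1) {
  matrix_from_weights(random_simplex(n, concentration),
                      items = paste0("it", seq_len(n)))
}

# independent oracle: direct eigen-decomposition (LAPACK), not power iteration
oracle_eigen <- function(M) {
  ev <- eigen(as.matrix(unclass(M)))
  i <- which.max(Re(ev$values))
  w <- Re(ev$vectors[, i])
  w <- w / sum(w)
  list(weights = abs(w) / sum(abs(w)), lambda = Re(ev$values[i]))
}

# locals for a flat model from a per-leaf matrix of alternative priorities
# (rows = leaves in order, cols = alternatives), plus leaf weights
flat_locals <- function(h, leaf_weights, alt_priorities) {
  leaves <- vapply(Filter(function(g) g$kind == "alternative",
                          comparison_groups(h)),
                   function(g) g$parent, character(1))
  loc <- list()
  loc[[h$goal]] <- stats::setNames(leaf_weights, leaves)
  for (i in seq_along(leaves)) {
    loc[[leaves[i]]] <- stats::setNames(alt_priorities[i, ], h$alternatives)
  }
  loc
}
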