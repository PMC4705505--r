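# Fixture builders and independent brute-force oracles used across tests.

# A model with hand-chosen coefficients, aligned to the feature registry.
stub_model <- function(coefs = numeric(), intercept = 0) {
  beta <- stats::setNames(rep(0, length(feature_registry())),
                          feature_registry())
  beta[names(coefs)] <- coefs
  structure(list(coefficients = beta, intercept = intercept,
                 feature_names = feature_registry(),
                 training_meta = list()),
            class = "slpc_model")
}

# Unit-weight copy of a network (for features that need a weighted input).
unit_weights <- function(net) {
  out <- net
  out$edges$weight <- rep(1, nrow(net$edges))
  out$weighted <- TRUE
  out
}

# Random small network as an edge probability draw over n nodes.
random_network <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  if (n < 2) return(ppi_network(nodes = nodes))
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  ppi_network(pairs[1L, keep], pairs[2L, keep], nodes = nodes)
}

# Random complex set: k complexes of sizes 2..6 over a small protein universe.
random_complex_set <- function(k, universe = sprintf("p%02d", 1:15)) {
  complex_set(lapply(seq_len(k), function(i) {
    sample(universe, sample(2:6, 1L))
  }))
}

# Brute-force maximal-clique oracle: tests every vertex subset.
brute_force_cliques <- function(net, min_size) {
  nodes <- net$nodes
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(net$edges) > 0L) {
    adj[cbind(net$edges$a, net$edges$b)] <- TRUE
    adj[cbind(net$edges$b, net$edges$a)] <- TRUE
  }
  is_clique <- function(idx) {
    if (length(idx) < 2L) return(TRUE)
    sub <- adj[idx, idx, drop = FALSE]
    all(sub[upper.tri(sub)])
  }
  out <- list()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(idx) < min_size || !is_clique(idx)) next
    extendable <- any(vapply(setdiff(seq_len(n), idx),
                             function(v) all(adj[v, idx]), logical(1)))
    if (!extendable) out[[length(out) + 1L]] <- nodes[idx]
  }
  out
}

# All permutations of 1..n (n <= 7), for the assignment oracle.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Brute-force maximum-weight one-to-one assignment over an affinity matrix.
brute_force_matching <- function(w) {
  n <- nrow(w); m <- ncol(w)
  k <- max(n, m)
  padded <- matrix(0, k, k)
  padded[seq_len(n), seq_len(m)] <- w
  best <- 0
  for (perm in all_permutations(k)) {
    best <- max(best, sum(padded[cbind(seq_len(k), unlist(perm))]))
  }
  best
}

# Canonical sort of a list of member sets, for order-insensitive comparison.
sort_sets <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, paste, character(1), collapse = "\t"))]
}

# Three-terms annotation fixture realizing |C(m,n)| = 2, min |Ti| = 10,
# T_max = 100 for the pair (m, n).
two_term_annotation <- function() {
  prot <- c(
    c("m", "n", sprintf("f%02d", 1:8)),            # term TA, size 10
    c("m", "n", sprintf("g%02d", 1:18)),           # term TB, size 20
    sprintf("h%03d", 1:100)                        # broad term, size 100
  )
  term <- c(rep("TA", 10), rep("TB", 20), rep("TBIG", 100))
  go_annotation(prot, term)
}

# m and n share exactly three neighbors (x1, x2, x3) and are not adjacent.
three_shared_neighbors_net <- function() {
  ppi_network(c("m", "m", "m", "n", "n", "n"),
              c("x1", "x2", "x3", "x1", "x2", "x3"))
}
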