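# Feature extraction for candidate complex subgraphs.
#
# All topological features are computed on the subgraph induced by the member
# set: a candidate complex is described by its own internal structure, not by
# how its members behave elsewhere in the network.

# Precomputed lookup structures for a network; every feature function has an
# *_impl variant that takes this index so the detection pipeline can reuse it
# across thousands of candidate evaluations.
net_index <- function(net) {
  list(nbrs = neighbor_map(net), w = weight_map(net), weighted = net$weighted)
}

induced_degrees <- function(members, ix) {
  vapply(members,
         function(m) length(intersect(ix$nbrs[[m]] %||% character(), members)),
         integer(1))
}

graph_density_impl <- function(members, ix) {
  k <- length(members)
  e <- sum(induced_degrees(members, ix)) / 2
  2 * e / (k * (k - 1))
}

#' Graph density of an induced subgraph
#'
#' `2e / (k (k - 1))` where `k` is the number of members and `e` the number of
#' network edges with both endpoints among them; 1 for a clique, 0 for an
#' edgeless set.
#'
#' @param members Character vector of at least two protein identifiers.
#' @param net A [ppi_network()].
#' @return Density in `[0, 1]`.
#' @export
graph_density <- function(members, net) {
  members <- unique(as.character(members))
  if (length(members) < 2L) stop("need at least 2 members", call. = FALSE)
  graph_density_impl(members, net_index(net))
}

clustering_coefficient_impl <- function(members, ix) {
  local_cc <- vapply(members, function(m) {
    vi <- intersect(ix$nbrs[[m]] %||% character(), members)
    k_i <- length(vi)
    if (k_i < 2L) return(0)
    e_i <- sum(vapply(vi, function(u) {
      length(intersect(ix$nbrs[[u]] %||% character(), vi))
    }, integer(1))) / 2
    2 * e_i / (k_i * (k_i - 1))
  }, numeric(1))
  mean(local_cc)
}

#' Mean local clustering coefficient of an induced subgraph
#'
#' Watts-Strogatz local coefficient averaged over the members, computed in
#' the induced subgraph; members with induced degree below 2 contribute 0.
#'
#' @inheritParams graph_density
#' @return Coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(members, net) {
  members <- unique(as.character(members))
  if (length(members) < 2L) stop("need at least 2 members", call. = FALSE)
  clustering_coefficient_impl(members, net_index(net))
}

degree_statistics_impl <- function(members, ix) {
  d <- induced_degrees(members, ix)
  m <- mean(d)
  c(mean = m, max = max(d), min = min(d), var = mean((d - m)^2))
}

#' Induced-subgraph degree statistics
#'
#' Mean, maximum, minimum and population variance of member degrees within
#' the induced subgraph.
#'
#' @inheritParams graph_density
#' @return Named numeric vector `(mean, max, min, var)`.
#' @export
degree_statistics <- function(members, net) {
  members <- unique(as.character(members))
  if (length(members) < 2L) stop("need at least 2 members", call. = FALSE)
  degree_statistics_impl(members, net_index(net))
}

internal_edge_weights <- function(members, ix) {
  out <- numeric()
  for (m in members) {
    nb <- intersect(ix$nbrs[[m]] %||% character(), members)
    nb <- nb[nb > m]  # each edge once, lexicographic order
    if (length(nb)) out <- c(out, unname(ix$w[edge_key(m, nb)]))
  }
  out
}

edge_weight_statistics_impl <- function(members, ix) {
  w <- internal_edge_weights(members, ix)
  if (length(w) == 0L) return(c(sum = 0, mean = 0, max = 0, min = 0))
  c(sum = sum(w), mean = mean(w), max = max(w), min = min(w))
}

#' Internal edge-weight statistics
#'
#' Sum, mean, maximum and minimum of the weights of edges with both endpoints
#' among the members; all four are 0 when there is no internal edge.
#'
#' @param members Character vector of at least two protein identifiers.
#' @param wnet A weighted [ppi_network()].
#' @return Named numeric vector `(sum, mean, max, min)`.
#' @export
edge_weight_statistics <- function(members, wnet) {
  members <- unique(as.character(members))
  if (length(members) < 2L) stop("need at least 2 members", call. = FALSE)
  if (!wnet$weighted) stop("`wnet` must be a weighted network", call. = FALSE)
  edge_weight_statistics_impl(members, net_index(wnet))
}

topologic_change_impl <- function(members, ix) {
  if (length(members) < 3L) return(0)
  d <- induced_degrees(members, ix)
  # hub = highest induced degree, smallest ID on ties (members are sorted)
  hub <- members[which.max(d)]
  graph_density_impl(members, ix) -
    graph_density_impl(setdiff(members, hub), ix)
}

#' Topologic change under hub removal
#'
#' Density of the induced subgraph minus the density after removing the
#' member with the highest induced degree (smallest identifier on ties): how
#' much the densest hub holds the subgraph together. 0 by convention for
#' fewer than 3 members, and 0 for any clique of size 4 or more.
#'
#' @inheritParams graph_density
#' @return A real value.
#' @export
topologic_change <- function(members, net) {
  members <- sort(unique(as.character(members)))
  topologic_change_impl(members, net_index(net))
}

#' Names of the complex features, in model order
#'
#' The fixed, ordered feature registry. A trained model records this list and
#' refuses to score against a mismatched registry, so coefficients always
#' align with the features that produced them.
#'
#' @return Character vector of 11 feature names.
#' @export
feature_registry <- function() {
  c("density",
    "degree_mean", "degree_max", "degree_min", "degree_var",
    "weight_sum", "weight_mean", "weight_max", "weight_min",
    "clustering_coeff", "topologic_change")
}

extract_features_impl <- function(members, ix, wix) {
  ds <- degree_statistics_impl(members, ix)
  ws <- edge_weight_statistics_impl(members, wix)
  stats::setNames(
    c(graph_density_impl(members, ix),
      ds[["mean"]], ds[["max"]], ds[["min"]], ds[["var"]],
      ws[["sum"]], ws[["mean"]], ws[["max"]], ws[["min"]],
      clustering_coefficient_impl(members, ix),
      topologic_change_impl(members, ix)),
    feature_registry()
  )
}

#' Extract the feature vector of a candidate complex
#'
#' Assembles the 11 features of [feature_registry()] for the subgraph induced
#' by `members`: density, degree statistics and clustering coefficient and
#' topologic change from the unweighted network, edge-weight statistics from
#' the weighted (reliability-scored) network.
#'
#' @param members Character vector of at least two protein identifiers.
#' @param net Unweighted [ppi_network()].
#' @param wnet Weighted [ppi_network()] (typically [weight_network()] of
#'   `net`).
#' @return Named numeric vector of length 11.
#' @export
extract_features <- function(members, net, wnet) {
  members <- sort(unique(as.character(members)))
  if (length(members) < 2L) stop("need at least 2 members", call. = FALSE)
  if (!wnet$weighted) stop("`wnet` must be a weighted network", call. = FALSE)
  extract_features_impl(members, net_index(net), net_index(wnet))
}
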