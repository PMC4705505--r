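#' Synthetic benchmark configuration
#'
#' Parameters of the seeded generator that emulates the toolkit's four input
#' kinds: a PPI network with planted dense complexes, the ground-truth
#' complex set, a GO-like annotation, and a weighted literature PPI list. The
#' defaults plant 20 node-disjoint complexes of 4-8 proteins at intra-complex
#' edge probability 0.9 in a background of 100 extra proteins with sparse
#' noise edges (p = 0.02) -- dense modules in a sparse network, the regime
#' complex detectors are built for. Literature weights are Normal: held-out
#' true pairs around 0.2, random noise pairs around -1.0 (both sd 0.4), so
#' sweeping the integrating threshold from 0 down to -1.2 moves from
#' almost-only-true to mostly-noise additions.
#'
#' @param n_complexes Number of planted complexes.
#' @param size_range Integer `(min, max)` complex size, min >= 3.
#' @param p_in Intra-complex edge probability.
#' @param n_background Extra background proteins.
#' @param p_out Edge probability for pairs not inside a common complex.
#' @param holdout_frac Fraction of intra-complex network edges moved to the
#'   literature list (in `[0, 0.5]`).
#' @param w_true `(mean, sd)` of literature weights for held-out true pairs.
#' @param w_noise `(mean, sd)` of literature weights for random non-edges.
#' @param n_noise_pairs Number of random noise pairs in the literature list.
#' @param terms_per_complex Private GO terms generated per complex.
#' @param term_leak Probability that a complex term also annotates any given
#'   outside protein.
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_complexes = 20L, size_range = c(4L, 8L),
                         p_in = 0.9, n_background = 100L, p_out = 0.02,
                         holdout_frac = 0, w_true = c(0.2, 0.4),
                         w_noise = c(-1.0, 0.4), n_noise_pairs = 200L,
                         terms_per_complex = 2L, term_leak = 0.05,
                         seed = 1L) {
  if (size_range[1] < 3L) stop("size_range min must be >= 3", call. = FALSE)
  if (size_range[1] > size_range[2]) stop("bad size_range", call. = FALSE)
  for (p in c(p_in, p_out, term_leak)) {
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  if (holdout_frac < 0 || holdout_frac > 0.5) {
    stop("holdout_frac must be in [0, 0.5]", call. = FALSE)
  }
  structure(list(n_complexes = as.integer(n_complexes),
                 size_range = as.integer(size_range),
                 p_in = p_in, n_background = as.integer(n_background),
                 p_out = p_out, holdout_frac = holdout_frac,
                 w_true = w_true, w_noise = w_noise,
                 n_noise_pairs = as.integer(n_noise_pairs),
                 terms_per_complex = as.integer(terms_per_complex),
                 term_leak = term_leak, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic PPI network with planted complexes
#'
#' Plants `n_complexes` node-disjoint complexes (sizes uniform over
#' `size_range`) with internal edges at `p_in`, adds `n_background` extra
#' proteins, and wires every pair of nodes not inside a common complex with
#' probability `p_out`. A `holdout_frac` sample of the realized intra-complex
#' edges is then removed from the network and emitted in the literature list
#' with weights `Normal(w_true)`, together with `n_noise_pairs` random
#' non-edges weighted `Normal(w_noise)` -- literature pairs are therefore
#' never current network edges. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return List with `network` ([ppi_network()]), `truth` ([complex_set()])
#'   and `literature` (`lit_ppi_list`).
#' @export
generate_network <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    sizes <- sample(seq(cfg$size_range[1], cfg$size_range[2]),
                    cfg$n_complexes, replace = TRUE)
    n_nodes <- sum(sizes) + cfg$n_background
    nodes <- sprintf("P%04d", seq_len(n_nodes))
    assign_id <- rep(0L, n_nodes)  # 0 = background
    assign_id[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)
    truth <- complex_set(unname(split(nodes[assign_id > 0L],
                                      assign_id[assign_id > 0L])))

    pairs <- utils::combn(nodes, 2L)
    pa <- pairs[1L, ]; pb <- pairs[2L, ]
    ga <- assign_id[match(pa, nodes)]; gb <- assign_id[match(pb, nodes)]
    intra <- ga > 0L & ga == gb
    keep <- logical(length(pa))
    keep[intra] <- stats::runif(sum(intra)) < cfg$p_in
    keep[!intra] <- stats::runif(sum(!intra)) < cfg$p_out

    # hold out part of the realized intra-complex edges for the literature list
    intra_kept <- which(keep & intra)
    n_hold <- floor(cfg$holdout_frac * length(intra_kept))
    held <- if (n_hold > 0L) sort(sample(intra_kept, n_hold)) else integer()
    keep[held] <- FALSE

    net <- ppi_network(pa[keep], pb[keep], nodes = nodes)

    non_edges <- which(!keep)
    non_edges <- setdiff(non_edges, held)
    n_noise <- min(cfg$n_noise_pairs, length(non_edges))
    noise <- if (n_noise > 0L) sort(sample(non_edges, n_noise)) else integer()

    lit <- lit_ppi_list(
      c(pa[held], pa[noise]), c(pb[held], pb[noise]),
      c(stats::rnorm(length(held), cfg$w_true[1], cfg$w_true[2]),
        stats::rnorm(length(noise), cfg$w_noise[1], cfg$w_noise[2]))
    )
    list(network = net, truth = truth, literature = lit)
  })
}

#' Generate a GO-like annotation for a planted benchmark
#'
#' Gives every planted complex `terms_per_complex` private terms annotating
#' its members, each independently leaking to every outside protein with
#' probability `term_leak`, plus one broad term annotating every network
#' protein. The broad term fixes the maximum term size at the number of
#' proteins, so the private complex terms are the specific ones and
#' intra-complex pairs score systematically higher reliability than random
#' cross-complex pairs.
#'
#' @param truth A [complex_set()] of planted complexes.
#' @param net The generated [ppi_network()].
#' @param cfg The [synth_config()] used to generate them.
#' @return A [go_annotation()].
#' @export
generate_annotation <- function(truth, net, cfg = synth_config()) {
  with_seed(cfg$seed + 1000003L, {
    protein <- character(); term <- character()
    for (i in seq_along(truth$complexes)) {
      members <- truth$complexes[[i]]
      outside <- setdiff(net$nodes, members)
      for (t in seq_len(cfg$terms_per_complex)) {
        tname <- sprintf("GO:C%03dT%02d", i, t)
        leaked <- outside[stats::runif(length(outside)) < cfg$term_leak]
        annotated <- c(members, leaked)
        protein <- c(protein, annotated)
        term <- c(term, rep(tname, length(annotated)))
      }
    }
    protein <- c(protein, net$nodes)
    term <- c(term, rep("GO:BROAD", length(net$nodes)))
    go_annotation(protein, term)
  })
}

#' Split a complex set into training and test parts
#'
#' Seeded disjoint partition: `floor(train_frac * n)` complexes are drawn for
#' training, the rest form the test set.
#'
#' @param truth A [complex_set()].
#' @param train_frac Fraction in `(0, 1)`.
#' @param seed Integer seed.
#' @return List with `train` and `test` [complex_set()] objects.
#' @export
make_split <- function(truth, train_frac = 0.5, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be in (0, 1)", call. = FALSE)
  }
  n <- length(truth$complexes)
  with_seed(seed, {
    idx <- sort(sample(n, floor(train_frac * n)))
    list(
      train = complex_set(truth$complexes[idx],
                          score = if (is.null(truth$score)) NULL else truth$score[idx]),
      test = complex_set(truth$complexes[-idx],
                         score = if (is.null(truth$score)) NULL else truth$score[-idx])
    )
  })
}
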