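# Desk-scale planted-complex benchmarks: one call runs the full pipeline
# (simulate -> annotate -> weight -> split -> train -> detect -> evaluate)
# on a synthetic network, so recovery performance can be measured without
# external interaction databases.

#' Run the planted-complex recovery benchmark
#'
#' Generates a synthetic network with planted complexes, trains the scorer on
#' half of them (`train_frac`), detects complexes, and evaluates the
#' prediction against the full planted truth. When `int_thred` is given the
#' held-out literature list is first integrated into the network at that
#' threshold (both the depleted and the integrated variants can thus be
#' benchmarked from the same generator draw).
#'
#' @param seed Integer seed driving the generator, split and training.
#' @param cfg A [synth_config()]; its `seed` is overridden by `seed`.
#' @param train_frac Fraction of planted complexes used for training.
#' @param int_thred Optional integrating threshold; `NULL` skips integration.
#' @return An `evaluation_report` (see [evaluate()]), with the number of
#'   network nodes attached as attribute `n_nodes`.
#' @export
run_planted_benchmark <- function(seed, cfg = synth_config(),
                                  train_frac = 0.5, int_thred = NULL) {
  cfg$seed <- as.integer(seed)
  sim <- generate_network(cfg)
  net <- sim$network
  if (!is.null(int_thred)) {
    net <- integrate_network(net, sim$literature, int_thred)
  }
  ann <- generate_annotation(sim$truth, net, cfg)
  wnet <- weight_network(net, ann)
  sp <- make_split(sim$truth, train_frac, seed = seed)
  dc <- detector_config(seed = seed)
  train <- restrict_gold_standard(sp$train, net)
  model <- train_model(build_training_set(train, net, wnet, dc), dc)
  pred <- detect_complexes(net, wnet, model, dc)
  rep <- evaluate(pred, sim$truth)
  attr(rep, "n_nodes") <- length(net$nodes)
  rep
}

#' Mean benchmark metrics over several seeds
#'
#' @param seeds Integer vector of seeds.
#' @inheritParams run_planted_benchmark
#' @return Named numeric vector with mean `f_score`, `acc` and `mmr`, plus
#'   `n_nodes` (mean network size).
#' @export
mean_planted_benchmark <- function(seeds, cfg = synth_config(),
                                   train_frac = 0.5, int_thred = NULL) {
  reps <- lapply(seeds, run_planted_benchmark, cfg = cfg,
                 train_frac = train_frac, int_thred = int_thred)
  c(f_score = mean(vapply(reps, `[[`, numeric(1), "f_score")),
    acc = mean(vapply(reps, `[[`, numeric(1), "acc")),
    mmr = mean(vapply(reps, `[[`, numeric(1), "mmr")),
    n_nodes = mean(vapply(reps, attr, numeric(1), "n_nodes")))
}
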