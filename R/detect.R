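#' Detector configuration
#'
#' Tunable parameters of the clique-seeded supervised detector. Clique seeds
#' below `min_clique_size` are never generated (size-2 cliques are bare edges
#' and would swamp the candidate set). `clique_overlap_thred` controls seed
#' de-duplication after scoring; `merg_thred` controls the final
#' merge-or-remove pass on neighborhood-affinity overlap. Negative training
#' examples are size-matched random connected subgraphs, `negative_ratio` per
#' positive, drawn by a seeded random walk.
#'
#' @param min_clique_size Minimum clique seed size (>= 3).
#' @param clique_overlap_thred Seed overlap threshold in `[0, 1]`
#'   (ratio mode) or a raw count (count mode).
#' @param merg_thred Neighborhood-affinity threshold in `[0, 1]` for the
#'   merge/filter pass.
#' @param negative_ratio Negatives sampled per positive when training.
#' @param seed Integer seed for all stochastic steps.
#' @param overlap_mode `"ratio"` (default): seed overlap measured as
#'   `|A intersect B| / min(|A|, |B|)`; `"count"`: raw intersection size.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(min_clique_size = 3L, clique_overlap_thred = 0.5,
                            merg_thred = 0.25, negative_ratio = 1L, seed = 1L,
                            overlap_mode = c("ratio", "count")) {
  overlap_mode <- match.arg(overlap_mode)
  if (min_clique_size < 3L) stop("min_clique_size must be >= 3", call. = FALSE)
  if (overlap_mode == "ratio" &&
      (clique_overlap_thred < 0 || clique_overlap_thred > 1)) {
    stop("clique_overlap_thred must be in [0, 1]", call. = FALSE)
  }
  if (merg_thred < 0 || merg_thred > 1) {
    stop("merg_thred must be in [0, 1]", call. = FALSE)
  }
  structure(list(min_clique_size = as.integer(min_clique_size),
                 clique_overlap_thred = clique_overlap_thred,
                 merg_thred = merg_thred,
                 negative_ratio = as.integer(negative_ratio),
                 seed = as.integer(seed),
                 overlap_mode = overlap_mode),
            class = "detector_config")
}

# Random connected subgraph of a given size: uniform start among nodes of
# positive degree, then repeatedly absorb a uniformly chosen frontier node.
# Returns NULL when the walk cannot reach the requested size.
sample_connected_subgraph <- function(size, nodes, nbrs, max_restarts = 20L) {
  eligible <- nodes[vapply(nodes, function(n) length(nbrs[[n]]) > 0L,
                           logical(1))]
  if (length(eligible) == 0L) return(NULL)
  for (r in seq_len(max_restarts)) {
    s <- sample(eligible, 1L)
    frontier <- setdiff(nbrs[[s]], s)
    while (length(s) < size && length(frontier) > 0L) {
      v <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
      s <- c(s, v)
      frontier <- setdiff(union(frontier, nbrs[[v]]), s)
    }
    if (length(s) == size) return(sort(s))
  }
  NULL
}

#' Build a labeled training set from known complexes
#'
#' Each known complex contributes its feature vector with label 1. For every
#' positive, `cfg$negative_ratio` random connected subgraphs of the same size
#' are sampled by a seeded random walk and labeled 0; a sample that equals a
#' positive member set is rejected and redrawn (bounded retries). Size
#' matching keeps the negative feature distribution comparable to the
#' positives.
#'
#' @param positives A [complex_set()] whose members are nodes of `net`
#'   (apply [restrict_gold_standard()] first).
#' @param net Unweighted [ppi_network()].
#' @param wnet Weighted [ppi_network()].
#' @param cfg A [detector_config()].
#' @return List with `x` (feature matrix, one row per example), `y` (0/1
#'   labels) and `members` (list of member sets, row-aligned).
#' @export
build_training_set <- function(positives, net, wnet, cfg = detector_config()) {
  stopifnot(inherits(positives, "complex_set"))
  bad <- vapply(positives$complexes,
                function(m) sum(m %in% net$nodes) < 2L, logical(1))
  if (any(bad)) {
    stop("every positive needs >= 2 members present in the network; ",
         "apply restrict_gold_standard() first", call. = FALSE)
  }
  ix <- net_index(net)
  wix <- net_index(wnet)
  pos_keys <- vapply(positives$complexes, member_key, character(1))

  with_seed(cfg$seed, {
    feats <- list(); labels <- numeric(); memb <- list()
    for (p in positives$complexes) {
      feats[[length(feats) + 1L]] <- extract_features_impl(p, ix, wix)
      labels <- c(labels, 1)
      memb[[length(memb) + 1L]] <- p
    }
    for (p in positives$complexes) {
      for (k in seq_len(cfg$negative_ratio)) {
        neg <- NULL
        for (try in seq_len(50L)) {
          cand <- sample_connected_subgraph(length(p), net$nodes, ix$nbrs)
          if (is.null(cand)) break
          if (!(member_key(cand) %in% pos_keys)) { neg <- cand; break }
        }
        if (is.null(neg)) {
          warning("could not sample a negative of size ", length(p),
                  "; skipped", call. = FALSE)
          next
        }
        feats[[length(feats) + 1L]] <- extract_features_impl(neg, ix, wix)
        labels <- c(labels, 0)
        memb[[length(memb) + 1L]] <- neg
      }
    }
    list(x = do.call(rbind, feats), y = labels, members = memb)
  })
}

#' Train the complex-scoring regression model
#'
#' Ridge-regularized least squares on the labeled feature vectors: the small
#' fixed regularizer (`lambda`) only conditions the normal equations (it
#' keeps degenerate, constant features harmless), the intercept is not
#' penalized. The fit is deterministic given the training set.
#'
#' @param training Output of [build_training_set()] (or any list with `x`
#'   and `y`).
#' @param cfg A [detector_config()] (recorded in the model metadata).
#' @param lambda Ridge regularizer (default `1e-6`).
#' @return An object of class `slpc_model`: `coefficients` (named, aligned to
#'   [feature_registry()]), `intercept`, `feature_names`, `training_meta`.
#' @export
train_model <- function(training, cfg = detector_config(), lambda = 1e-6) {
  x <- training$x
  y <- training$y
  if (length(unique(y)) < 2L) {
    stop("training set must contain both labels", call. = FALSE)
  }
  if (nrow(x) != length(y)) stop("x/y size mismatch", call. = FALSE)
  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2L, xm)
  beta <- solve(crossprod(xc) + lambda * diag(ncol(x)), crossprod(xc, y - ym))
  beta <- drop(beta)
  structure(
    list(coefficients = stats::setNames(beta, colnames(x)),
         intercept = ym - sum(xm * beta),
         feature_names = colnames(x),
         training_meta = list(seed = cfg$seed,
                              n_pos = sum(y == 1),
                              n_neg = sum(y == 0),
                              lambda = lambda)),
    class = "slpc_model"
  )
}

#' @export
print.slpc_model <- function(x, ...) {
  cat("<slpc_model> ", length(x$coefficients), " features; trained on ",
      x$training_meta$n_pos, " positives / ", x$training_meta$n_neg,
      " negatives\n", sep = "")
  invisible(x)
}

check_registry <- function(model) {
  if (!identical(model$feature_names, feature_registry())) {
    stop("model feature registry does not match this package's registry",
         call. = FALSE)
  }
}

score_subgraph_impl <- function(members, model, ix, wix) {
  model$intercept +
    sum(model$coefficients * extract_features_impl(members, ix, wix))
}

#' Score a subgraph with a trained model
#'
#' Linear score: intercept plus the dot product of the model coefficients
#' with [extract_features()] of the member set.
#'
#' @param members Character vector of protein identifiers (>= 2).
#' @param model An [train_model()] result.
#' @param net,wnet Unweighted and weighted networks.
#' @return A real score.
#' @export
score_subgraph <- function(members, model, net, wnet) {
  check_registry(model)
  members <- sort(unique(as.character(members)))
  score_subgraph_impl(members, model, net_index(net), net_index(wnet))
}

#' Enumerate maximal cliques
#'
#' All maximal cliques of at least `min_size` nodes, in a deterministic order:
#' decreasing size, then lexicographic member tuple.
#'
#' @param net A [ppi_network()].
#' @param min_size Minimum clique size.
#' @return List of sorted character vectors.
#' @export
enumerate_maximal_cliques <- function(net, min_size = 3L) {
  g <- as_igraph(net)
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  if (length(cl) == 0L) return(list())
  keys <- vapply(cl, member_key, character(1))
  cl[order(-lengths(cl), keys, method = "radix")]
}

overlap_ratio <- function(a, b, mode = "ratio") {
  inter <- length(intersect(a, b))
  if (mode == "count") inter else inter / min(length(a), length(b))
}

#' Score and de-duplicate clique seeds
#'
#' Cliques are scored by the model and sorted in descending score order
#' (ties broken by lexicographic member tuple); scanning down the ranking,
#' each surviving clique removes every lower-scoring clique whose overlap
#' with it exceeds `cfg$clique_overlap_thred` (overlap is
#' `|A intersect B| / min(|A|, |B|)` in ratio mode, the raw intersection size
#' in count mode).
#'
#' @param cliques List of member sets (e.g. [enumerate_maximal_cliques()]).
#' @param model A trained `slpc_model`.
#' @param cfg A [detector_config()].
#' @param net,wnet Unweighted and weighted networks.
#' @return List of candidates, each `list(members, score)`, in rank order.
#' @export
filter_cliques <- function(cliques, model, cfg, net, wnet) {
  check_registry(model)
  ix <- net_index(net); wix <- net_index(wnet)
  filter_cliques_impl(cliques, model, cfg, ix, wix)
}

filter_cliques_impl <- function(cliques, model, cfg, ix, wix) {
  if (length(cliques) == 0L) return(list())
  scores <- vapply(cliques, score_subgraph_impl, numeric(1),
                   model = model, ix = ix, wix = wix)
  keys <- vapply(cliques, member_key, character(1))
  ord <- order(-scores, keys, method = "radix")
  cliques <- cliques[ord]; scores <- scores[ord]
  kept <- list()
  for (i in seq_along(cliques)) {
    dominated <- FALSE
    for (k in kept) {
      if (overlap_ratio(k$members, cliques[[i]], cfg$overlap_mode) >
          cfg$clique_overlap_thred) {
        dominated <- TRUE
        break
      }
    }
    if (!dominated) {
      kept[[length(kept) + 1L]] <- list(members = cliques[[i]],
                                        score = scores[i])
    }
  }
  kept
}

#' Greedily grow a candidate complex
#'
#' Repeatedly evaluates every node adjacent to the candidate and adds the one
#' whose inclusion maximizes the model score, provided it strictly improves
#' on the current score (ties broken by smallest protein identifier); stops
#' when no neighbor improves the score. The score sequence is strictly
#' increasing, so growth terminates.
#'
#' @param candidate `list(members, score)` as produced by [filter_cliques()].
#' @param model A trained `slpc_model`.
#' @param net,wnet Unweighted and weighted networks.
#' @return The grown candidate, `list(members, score)`.
#' @export
grow_clique <- function(candidate, model, net, wnet) {
  check_registry(model)
  grow_clique_impl(candidate, model, net_index(net), net_index(wnet))
}

grow_clique_impl <- function(candidate, model, ix, wix) {
  members <- candidate$members
  score <- candidate$score %||%
    score_subgraph_impl(members, model, ix, wix)
  repeat {
    nc <- setdiff(sort(unique(unlist(ix$nbrs[members], use.names = FALSE))),
                  members)
    if (length(nc) == 0L) break
    cand_scores <- vapply(nc, function(v) {
      score_subgraph_impl(sort(c(members, v)), model, ix, wix)
    }, numeric(1))
    best <- which.max(cand_scores)  # nc sorted => smallest ID on ties
    if (cand_scores[best] > score) {
      members <- sort(c(members, nc[best]))
      score <- unname(cand_scores[best])
    } else break
  }
  list(members = members, score = score)
}

#' Merge or remove overlapping candidate complexes
#'
#' Candidates are ranked by descending score (ties by member tuple) and
#' duplicates dropped. Scanning down the ranking, each surviving candidate is
#' compared with every lower-scoring one; when their neighborhood affinity
#' ([na_score()]) exceeds `cfg$merg_thred`, the pair is merged if the union
#' scores strictly higher than the current candidate (which is then rescored
#' and its scan restarted), otherwise the lower-scoring candidate is removed.
#'
#' @param candidates List of `list(members, score)` candidates.
#' @param model A trained `slpc_model`.
#' @param cfg A [detector_config()].
#' @param net,wnet Unweighted and weighted networks.
#' @return A scored [complex_set()] of predicted complexes.
#' @export
merge_filter_candidates <- function(candidates, model, cfg, net, wnet) {
  check_registry(model)
  merge_filter_impl(candidates, model, cfg, net_index(net), net_index(wnet))
}

merge_filter_impl <- function(candidates, model, cfg, ix, wix) {
  if (length(candidates) == 0L) return(complex_set())
  keys <- vapply(candidates, function(c) member_key(c$members), character(1))
  dup <- duplicated(keys)
  candidates <- candidates[!dup]
  scores <- vapply(candidates, function(c) c$score, numeric(1))
  keys <- keys[!dup]
  ord <- order(-scores, keys, method = "radix")
  cand <- candidates[ord]

  i <- 1L
  while (i <= length(cand)) {
    restart <- TRUE
    while (restart) {
      restart <- FALSE
      j <- i + 1L
      while (j <= length(cand)) {
        if (na_score(cand[[i]]$members, cand[[j]]$members) > cfg$merg_thred) {
          u <- sort(union(cand[[i]]$members, cand[[j]]$members))
          u_score <- score_subgraph_impl(u, model, ix, wix)
          if (u_score > cand[[i]]$score) {
            cand[[i]] <- list(members = u, score = u_score)
            cand[[j]] <- NULL
            restart <- TRUE
            break
          } else {
            cand[[j]] <- NULL
          }
        } else {
          j <- j + 1L
        }
      }
    }
    i <- i + 1L
  }
  # merging can create duplicates; drop them, keeping the first occurrence
  keys <- vapply(cand, function(c) member_key(c$members), character(1))
  cand <- cand[!duplicated(keys)]
  complex_set(lapply(cand, `[[`, "members"),
              score = vapply(cand, `[[`, numeric(1), "score"))
}

#' Detect protein complexes
#'
#' The full supervised pipeline: enumerate maximal cliques of the unweighted
#' network, score and de-duplicate them with the trained model
#' ([filter_cliques()]), grow each survivor greedily ([grow_clique()]), and
#' merge or remove overlapping candidates ([merge_filter_candidates()]).
#' Deterministic given inputs and configuration.
#'
#' @param net Unweighted [ppi_network()].
#' @param wnet Weighted [ppi_network()] (same topology, reliability weights).
#' @param model A trained `slpc_model`.
#' @param cfg A [detector_config()].
#' @return A scored [complex_set()] of predicted complexes.
#' @export
detect_complexes <- function(net, wnet, model, cfg = detector_config()) {
  check_registry(model)
  ix <- net_index(net); wix <- net_index(wnet)
  cliques <- enumerate_maximal_cliques(net, cfg$min_clique_size)
  seeds <- filter_cliques_impl(cliques, model, cfg, ix, wix)
  grown <- lapply(seeds, grow_clique_impl, model = model, ix = ix, wix = wix)
  merge_filter_impl(grown, model, cfg, ix, wix)
}

#' Serialize a trained model to JSON
#'
#' @param model An `slpc_model`.
#' @param path Output file path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(feature_names = model$feature_names,
         coefficients = unname(model$coefficients),
         intercept = model$intercept,
         training_meta = model$training_meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Read a trained model from JSON
#'
#' @param path Path to a model file written by [write_model()].
#' @return An `slpc_model`.
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(coefficients = stats::setNames(as.numeric(m$coefficients),
                                        m$feature_names),
         intercept = as.numeric(m$intercept),
         feature_names = as.character(m$feature_names),
         training_meta = m$training_meta),
    class = "slpc_model"
  )
}
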