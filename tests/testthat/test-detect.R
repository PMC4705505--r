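test_that("maximal clique enumeration matches subset brute force", {
  k4 <- random_network(4, 1)
  expect_equal(enumerate_maximal_cliques(k4, 3), list(k4$nodes))

  path5 <- ppi_network(c("a", "b", "c", "d"), c("b", "c", "d", "e"))
  expect_equal(enumerate_maximal_cliques(path5, 3), list())

  withr::with_seed(17, {
    for (rep in 1:10) {
      net <- random_network(8, 0.5)
      expect_equal(sort_sets(enumerate_maximal_cliques(net, 3)),
                   sort_sets(brute_force_cliques(net, 3)))
    }
  })
})

test_that("clique enumeration order is deterministic: size desc, then lexicographic", {
  net <- ppi_network(c("x", "x", "y", "a", "a", "a", "b", "b", "c"),
                     c("y", "z", "z", "b", "c", "d", "c", "d", "d"))
  cl <- enumerate_maximal_cliques(net, 3)
  expect_equal(cl, list(c("a", "b", "c", "d"), c("x", "y", "z")))
})

test_that("training sets are size-matched, labeled, seeded, and avoid positives", {
  cfg <- synth_config(n_complexes = 8, n_background = 30, seed = 41)
  sim <- generate_network(cfg)
  wnet <- unit_weights(sim$network)
  dc <- detector_config(seed = 41)
  tr <- build_training_set(sim$truth, sim$network, wnet, dc)
  expect_equal(nrow(tr$x), 16L)
  expect_equal(tr$y, rep(c(1, 0), each = 8))
  pos_keys <- vapply(sim$truth$complexes, paste, character(1), collapse = "|")
  neg_keys <- vapply(tr$members[tr$y == 0],
                     function(m) paste(sort(m), collapse = "|"), character(1))
  expect_false(any(neg_keys %in% pos_keys))
  # size matching and determinism
  expect_equal(unname(lengths(tr$members[tr$y == 0])),
               unname(lengths(sim$truth$complexes)))
  tr2 <- build_training_set(sim$truth, sim$network, wnet, dc)
  expect_identical(tr, tr2)
  # positives with members missing from the network are a contract violation
  bad <- complex_set(list(c("nope1", "nope2", "nope3")))
  expect_error(build_training_set(bad, sim$network, wnet, dc),
               "restrict_gold_standard")
})

test_that("ridge training matches an independent least-squares fit", {
  withr::with_seed(13, {
    x <- matrix(stats::rnorm(60 * 11), 60, 11,
                dimnames = list(NULL, feature_registry()))
    y <- as.numeric(stats::runif(60) > 0.5)
    model <- train_model(list(x = x, y = y))
    ref <- stats::lm(y ~ x)
    expect_equal(unname(model$coefficients), unname(stats::coef(ref)[-1]),
                 tolerance = 1e-5)
    expect_equal(model$intercept, unname(stats::coef(ref)[1]),
                 tolerance = 1e-5)
    # duplicating the training set leaves the fit (nearly) unchanged
    model2 <- train_model(list(x = rbind(x, x), y = c(y, y)))
    expect_equal(model2$coefficients, model$coefficients, tolerance = 1e-5)
    # a separable single informative feature scores positives higher
    x1 <- matrix(0, 20, 11, dimnames = list(NULL, feature_registry()))
    y1 <- rep(c(1, 0), 10)
    x1[, "density"] <- y1
    m1 <- train_model(list(x = x1, y = y1))
    expect_gt(m1$intercept + m1$coefficients[["density"]], m1$intercept)
    expect_error(train_model(list(x = x1, y = rep(1, 20))), "both labels")
  })
})

test_that("subgraph scoring is an affine function of the features", {
  tri <- ppi_network(c("a", "a", "b"), c("b", "c", "c"))
  wtri <- unit_weights(tri)
  m0 <- stub_model(intercept = 0.7)
  expect_equal(score_subgraph(c("a", "b", "c"), m0, tri, wtri), 0.7)

  m1 <- stub_model(c(density = 2, weight_sum = 0.5), intercept = 1)
  feats <- extract_features(c("a", "b", "c"), tri, wtri)
  expect_equal(score_subgraph(c("a", "b", "c"), m1, tri, wtri),
               1 + sum(m1$coefficients * feats))
  m2 <- m1; m2$coefficients <- 2 * m2$coefficients
  expect_equal(score_subgraph(c("a", "b", "c"), m2, tri, wtri) - 1,
               2 * (score_subgraph(c("a", "b", "c"), m1, tri, wtri) - 1))
  bad <- m1; bad$feature_names <- rev(bad$feature_names)
  expect_error(score_subgraph(c("a", "b", "c"), bad, tri, wtri), "registry")
})

test_that("clique filtering removes lower-scoring overlapping seeds", {
  # weight_sum model gives {a,b,c} score 2 and {b,c,d} score 1
  net <- ppi_network(c("a", "a", "b", "b", "c"), c("b", "c", "c", "d", "d"))
  wnet <- net
  wnet$edges$weight <- c(1, 0.5, 0.5, 0.25, 0.25)  # ab ac bc bd cd
  wnet$weighted <- TRUE
  model <- stub_model(c(weight_sum = 1))
  cl <- list(c("a", "b", "c"), c("b", "c", "d"))
  kept <- filter_cliques(cl, model, detector_config(clique_overlap_thred = 0.5),
                         net, wnet)
  expect_equal(length(kept), 1L)
  expect_equal(kept[[1]]$members, c("a", "b", "c"))
  expect_equal(kept[[1]]$score, 2)

  # identical cliques collapse; disjoint cliques both survive
  kept2 <- filter_cliques(list(c("a", "b", "c"), c("a", "b", "c")),
                          model, detector_config(), net, wnet)
  expect_equal(length(kept2), 1L)
  net2 <- ppi_network(c("a", "a", "b", "x", "x", "y"),
                      c("b", "c", "c", "y", "z", "z"))
  kept3 <- filter_cliques(list(c("a", "b", "c"), c("x", "y", "z")),
                          stub_model(c(density = 1)),
                          detector_config(clique_overlap_thred = 0.99),
                          net2, unit_weights(net2))
  expect_equal(length(kept3), 2L)
})

test_that("growth requires strict improvement and terminates", {
  # density-only model: a triangle inside K4 cannot strictly improve
  k4 <- random_network(4, 1)
  wk4 <- unit_weights(k4)
  dens <- stub_model(c(density = 1))
  seed <- list(members = k4$nodes[1:3], score = 1)
  expect_equal(grow_clique(seed, dens, k4, wk4)$members, k4$nodes[1:3])

  # weight_sum model: positive weights make growth absorb the full clique
  wsum <- stub_model(c(weight_sum = 1))
  grown <- grow_clique(list(members = k4$nodes[1:3], score = 3),
                       dens, k4, wk4)
  grown_w <- grow_clique(list(members = k4$nodes[1:3], score = 3),
                         wsum, k4, wk4)
  expect_equal(grown_w$members, k4$nodes)
  expect_equal(grown_w$score, 6)

  # no neighbors: unchanged; score never decreases
  iso <- ppi_network(c("a", "a", "b"), c("b", "c", "c"), nodes = "zz")
  g <- grow_clique(list(members = c("a", "b", "c"), score = 1),
                   dens, iso, unit_weights(iso))
  expect_equal(g$members, c("a", "b", "c"))
  expect_gte(g$score, 1)
})

test_that("merge/filter traces the overlap rules", {
  # A = {a,b,c} score 2; B = {b,c,d} score 0; union scores 1.5 < 2 -> B removed
  net <- ppi_network(c("a", "b", "b"), c("b", "c", "d"))
  wnet <- net
  wnet$edges$weight <- c(1.5, 0.5, -0.5)  # ab bc bd
  wnet$weighted <- TRUE
  model <- stub_model(c(weight_sum = 1))
  cand <- list(list(members = c("a", "b", "c"), score = 2),
               list(members = c("b", "c", "d"), score = 0))
  out <- merge_filter_candidates(cand, model, detector_config(), net, wnet)
  expect_equal(out$complexes, list(c("a", "b", "c")))
  expect_equal(out$score, 2)

  # union scoring higher -> merge
  wnet2 <- net
  wnet2$edges$weight <- c(1.5, 0.5, 2)
  wnet2$weighted <- TRUE
  cand2 <- list(list(members = c("a", "b", "c"), score = 2),
                list(members = c("b", "c", "d"), score = 2.5))
  out2 <- merge_filter_candidates(cand2, model, detector_config(), net, wnet2)
  expect_equal(out2$complexes, list(c("a", "b", "c", "d")))
  expect_equal(out2$score, 4)

  # disjoint candidates all retained; duplicates collapse
  cand3 <- list(list(members = c("a", "b"), score = 1),
                list(members = c("c", "d"), score = 0.5),
                list(members = c("a", "b"), score = 1))
  out3 <- merge_filter_candidates(cand3, stub_model(), detector_config(),
                                  net, wnet)
  expect_equal(length(out3), 2L)
})

test_that("the pipeline recovers two disjoint cliques exactly and is deterministic", {
  nodes1 <- sprintf("a%d", 1:5); nodes2 <- sprintf("b%d", 1:5)
  p1 <- utils::combn(nodes1, 2); p2 <- utils::combn(nodes2, 2)
  net <- ppi_network(c(p1[1, ], p2[1, ]), c(p1[2, ], p2[2, ]))
  wnet <- unit_weights(net)
  model <- stub_model(c(density = 1))
  pred <- detect_complexes(net, wnet, model)
  expect_equal(sort_sets(pred$complexes), list(nodes1, nodes2))

  pred2 <- detect_complexes(net, wnet, model)
  expect_identical(pred, pred2)

  # edgeless network: nothing to seed
  empty <- ppi_network(nodes = c("u", "v", "w"))
  expect_equal(length(detect_complexes(empty, unit_weights(empty), model)), 0L)
})

test_that("predicted complexes induce connected subgraphs", {
  cfg <- synth_config(n_complexes = 6, n_background = 40, seed = 53)
  sim <- generate_network(cfg)
  ann <- generate_annotation(sim$truth, sim$network, cfg)
  wnet <- weight_network(sim$network, ann)
  dc <- detector_config(seed = 53)
  model <- train_model(build_training_set(sim$truth, sim$network, wnet, dc), dc)
  pred <- detect_complexes(sim$network, wnet, model, dc)
  expect_gt(length(pred), 0L)
  g <- as_igraph(sim$network)
  for (m in pred$complexes) {
    sub <- igraph::induced_subgraph(g, m)
    expect_true(igraph::is_connected(sub))
  }
})

test_that("models round-trip through JSON", {
  withr::with_seed(3, {
    x <- matrix(stats::rnorm(40 * 11), 40, 11,
                dimnames = list(NULL, feature_registry()))
    y <- rep(c(1, 0), 20)
    model <- train_model(list(x = x, y = y), detector_config(seed = 9))
    f <- withr::local_tempfile()
    write_model(model, f)
    back <- read_model(f)
    expect_equal(back$coefficients, model$coefficients)
    expect_equal(back$intercept, model$intercept)
    expect_equal(back$feature_names, model$feature_names)
  })
})
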