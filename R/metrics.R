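#' Neighborhood affinity between two complexes
#'
#' `NA(A, B) = |A intersect B|^2 / (|A| * |B|)`: 1 iff the sets are equal,
#' 0 iff disjoint, symmetric. Two complexes are conventionally said to match
#' when their affinity reaches 0.25.
#'
#' @param a,b Non-empty character vectors of protein identifiers.
#' @return Affinity in `[0, 1]`.
#' @export
na_score <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("na_score is undefined for empty sets", call. = FALSE)
  }
  length(intersect(a, b))^2 / (length(a) * length(b))
}

# Affinity matrix, gold complexes in rows, predicted in columns.
na_matrix <- function(gold, pred) {
  n <- length(gold$complexes); m <- length(pred$complexes)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      out[i, j] <- na_score(gold$complexes[[i]], pred$complexes[[j]])
    }
  }
  out
}

#' Matched-complex counts
#'
#' `ncb` counts gold complexes whose neighborhood affinity with at least one
#' predicted complex reaches `na_threshold` (inclusive); `ncp` counts
#' predicted complexes matched by at least one gold complex.
#'
#' @param pred,gold [complex_set()] objects.
#' @param na_threshold Match threshold in `(0, 1]` (default 0.25).
#' @return Named integer vector `(ncb, ncp)`.
#' @export
match_counts <- function(pred, gold, na_threshold = 0.25) {
  if (na_threshold <= 0 || na_threshold > 1) {
    stop("na_threshold must be in (0, 1]", call. = FALSE)
  }
  if (length(pred$complexes) == 0L || length(gold$complexes) == 0L) {
    return(c(ncb = 0L, ncp = 0L))
  }
  m <- na_matrix(gold, pred) >= na_threshold
  c(ncb = sum(apply(m, 1L, any)), ncp = sum(apply(m, 2L, any)))
}

#' Precision, recall and F-score of a predicted complex set
#'
#' Precision is the fraction of predicted complexes matching at least one
#' gold complex, recall the fraction of gold complexes matched by at least
#' one prediction, F their harmonic mean (0 when both are 0).
#'
#' @inheritParams match_counts
#' @return Named numeric vector `(precision, recall, f)`.
#' @export
precision_recall_f <- function(pred, gold, na_threshold = 0.25) {
  mc <- match_counts(pred, gold, na_threshold)
  precision <- if (length(pred$complexes)) mc[["ncp"]] / length(pred$complexes) else 0
  recall <- if (length(gold$complexes)) mc[["ncb"]] / length(gold$complexes) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f = f)
}

#' Clustering-wise sensitivity, positive predictive value and accuracy
#'
#' With `T[i, j]` the number of proteins shared by gold complex `i` and
#' predicted complex `j`: `Sn = sum_i max_j T[i, j] / sum_i |gold_i|`,
#' `PPV = sum_j max_i T[i, j] / sum_j T.j` where `T.j = sum_i T[i, j]`
#' (a predicted complex overlapping no gold complex contributes 0 to both
#' sums), and `Acc = sqrt(Sn * PPV)`, the geometric accuracy. An empty
#' prediction yields `(0, 0, 0)`.
#'
#' @param pred,gold [complex_set()] objects; `gold` must be non-empty.
#' @return Named numeric vector `(sn, ppv, acc)`.
#' @export
sn_ppv_acc <- function(pred, gold) {
  if (length(gold$complexes) == 0L) {
    stop("gold standard must be non-empty", call. = FALSE)
  }
  if (length(pred$complexes) == 0L) return(c(sn = 0, ppv = 0, acc = 0))
  tij <- matrix(0L, length(gold$complexes), length(pred$complexes))
  for (i in seq_along(gold$complexes)) {
    for (j in seq_along(pred$complexes)) {
      tij[i, j] <- length(intersect(gold$complexes[[i]], pred$complexes[[j]]))
    }
  }
  sn <- sum(apply(tij, 1L, max)) / sum(lengths(gold$complexes))
  tdot <- sum(tij)
  ppv <- if (tdot > 0) sum(apply(tij, 2L, max)) / tdot else 0
  c(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

# Brute-force-free maximum-weight one-to-one assignment via igraph.
matching_weight <- function(w) {
  n <- nrow(w); m <- ncol(w)
  ii <- which(w > 0, arr.ind = TRUE)
  if (nrow(ii) == 0L) return(0)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, n), rep(TRUE, m)),
                                    edges = rbind(ii[, 1L], n + ii[, 2L]),
                                    directed = FALSE)
  igraph::max_bipartite_match(g, weights = w[ii])$matching_weight
}

#' Maximum matching ratio
#'
#' Compares a predicted complex set against the gold standard through
#' neighborhood affinities. In `matching` mode (default) a maximum-weight
#' one-to-one assignment between gold and predicted complexes is computed and
#' its total affinity divided by the number of gold complexes, so a gold
#' complex split across several predictions is credited only once. In
#' `rowmax` mode each gold complex independently takes its best affinity:
#' `sum_i max_j NA(gold_i, pred_j) / n_gold`. Row-max is always at least the
#' matching value.
#'
#' @inheritParams sn_ppv_acc
#' @param mode `"matching"` or `"rowmax"`.
#' @return A value in `[0, 1]`; 0 for an empty prediction.
#' @export
mmr <- function(pred, gold, mode = c("matching", "rowmax")) {
  mode <- match.arg(mode)
  if (length(gold$complexes) == 0L) {
    stop("gold standard must be non-empty", call. = FALSE)
  }
  if (length(pred$complexes) == 0L) return(0)
  w <- na_matrix(gold, pred)
  total <- if (mode == "rowmax") sum(apply(w, 1L, max)) else matching_weight(w)
  total / length(gold$complexes)
}

#' Evaluate predicted complexes against a gold standard
#'
#' Assembles the full evaluation report: match counts, precision/recall/F at
#' the affinity threshold, clustering-wise Sn/PPV and geometric accuracy, and
#' the maximum matching ratio.
#'
#' @inheritParams match_counts
#' @param mmr_mode Passed to [mmr()].
#' @return An object of class `evaluation_report` (a list of all metric
#'   fields plus `n_gold`, `n_pred`, `na_threshold`, `mmr_mode`).
#' @export
evaluate <- function(pred, gold, na_threshold = 0.25,
                     mmr_mode = c("matching", "rowmax")) {
  mmr_mode <- match.arg(mmr_mode)
  if (length(gold$complexes) == 0L) {
    stop("gold standard must be non-empty", call. = FALSE)
  }
  mc <- match_counts(pred, gold, na_threshold)
  prf <- precision_recall_f(pred, gold, na_threshold)
  spa <- sn_ppv_acc(pred, gold)
  structure(
    list(ncb = unname(mc[["ncb"]]), ncp = unname(mc[["ncp"]]),
         precision = unname(prf[["precision"]]),
         recall = unname(prf[["recall"]]),
         f_score = unname(prf[["f"]]),
         sn = unname(spa[["sn"]]), ppv = unname(spa[["ppv"]]),
         acc = unname(spa[["acc"]]),
         mmr = mmr(pred, gold, mmr_mode),
         n_gold = length(gold$complexes), n_pred = length(pred$complexes),
         na_threshold = na_threshold, mmr_mode = mmr_mode),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d predicted vs %d gold (NA >= %.2f)\n",
              x$n_pred, x$n_gold, x$na_threshold))
  cat(sprintf("  precision %.4f  recall %.4f  F %.4f  (ncp %d, ncb %d)\n",
              x$precision, x$recall, x$f_score, x$ncp, x$ncb))
  cat(sprintf("  Sn %.4f  PPV %.4f  Acc %.4f\n", x$sn, x$ppv, x$acc))
  cat(sprintf("  MMR (%s) %.4f\n", x$mmr_mode, x$mmr))
  invisible(x)
}
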