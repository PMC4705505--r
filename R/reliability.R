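#' Construct a GO annotation container
#'
#' Bidirectional protein/term incidence built from parallel vectors of
#' (protein, term) pairs. The container also carries `t_max`, the size of the
#' largest term (number of proteins it annotates), which calibrates term
#' specificity in reliability scoring: a term annotating few proteins relative
#' to `t_max` is specific, one annotating many is broad.
#'
#' @param protein Character vector of protein identifiers.
#' @param term Character vector of GO term identifiers (same length).
#' @return An object of class `go_annotation`: list with `term_to_proteins`
#'   (named list, term -> sorted protein vector), `protein_to_terms` (named
#'   list, protein -> sorted term vector) and `t_max` (integer; 0 when empty).
#' @export
go_annotation <- function(protein = character(), term = character()) {
  protein <- as.character(protein)
  term <- as.character(term)
  if (length(protein) != length(term)) {
    stop("`protein` and `term` must have the same length", call. = FALSE)
  }
  if (any(!nzchar(c(protein, term)))) {
    stop("protein and term identifiers must be non-empty", call. = FALSE)
  }
  key <- paste(protein, term, sep = "\r")
  dup <- duplicated(key)
  protein <- protein[!dup]; term <- term[!dup]
  t2p <- lapply(split(protein, term), function(v) sort(v))
  p2t <- lapply(split(term, protein), function(v) sort(v))
  structure(
    list(
      term_to_proteins = t2p,
      protein_to_terms = p2t,
      t_max = if (length(t2p)) max(lengths(t2p)) else 0L
    ),
    class = "go_annotation"
  )
}

#' @export
print.go_annotation <- function(x, ...) {
  cat("<go_annotation> ", length(x$protein_to_terms), " proteins, ",
      length(x$term_to_proteins), " terms, t_max = ", x$t_max, "\n", sep = "")
  invisible(x)
}

#' Read GO annotations
#'
#' Two formats: `tsv` is a two-column `protein<TAB>term` table ('#' comments
#' allowed); `gaf` is a GAF 2.x file, using the DB object ID (column 2) and
#' GO ID (column 5), skipping rows whose qualifier (column 4) contains `NOT`.
#' All three GO aspects are kept by default; pass `aspects` (a subset of
#' `c("P","F","C")`, GAF column 9) to restrict.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @param aspects Optional character vector of GAF aspect codes to retain.
#' @return A [go_annotation()].
#' @export
read_annotation <- function(path, format = c("tsv", "gaf"), aspects = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "tsv") {
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 2L)) {
      stop("tsv annotation must have exactly two tab-separated columns",
           call. = FALSE)
    }
    go_annotation(vapply(fields, `[[`, character(1), 1L),
                  vapply(fields, `[[`, character(1), 2L))
  } else {
    lines <- lines[!grepl("^\\s*(!|$)", lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(fields) >= 5L
    if (any(!ok)) {
      warning(sum(!ok), " malformed GAF line(s) skipped", call. = FALSE)
      fields <- fields[ok]
    }
    qual <- vapply(fields, `[[`, character(1), 4L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
    if (!is.null(aspects)) {
      asp <- vapply(fields, function(f) if (length(f) >= 9L) f[[9L]] else "",
                    character(1))
      keep <- keep & asp %in% aspects
    }
    fields <- fields[keep]
    go_annotation(vapply(fields, `[[`, character(1), 2L),
                  vapply(fields, `[[`, character(1), 5L))
  }
}

#' Reliability scoring parameters
#'
#' @param log_base `"natural"` (default) or `"base10"`; the base of the log
#'   in the term-specificity summand. Changing it only rescales scores (and
#'   hence thresholds) monotonically.
#' @param no_shared_term_value Value of the semantic summand when two proteins
#'   share no GO term (default 0: the score falls back to the shared-neighbor
#'   count, the limit of a maximally unspecific shared term).
#' @return A list of class `reliability_params`.
#' @export
reliability_params <- function(log_base = c("natural", "base10"),
                               no_shared_term_value = 0) {
  log_base <- match.arg(log_base)
  stopifnot_scalar_number(no_shared_term_value, "no_shared_term_value")
  structure(list(log_base = log_base,
                 no_shared_term_value = no_shared_term_value),
            class = "reliability_params")
}

#' GO terms shared by two proteins
#'
#' @param m,n Protein identifiers.
#' @param ann A [go_annotation()].
#' @return Character vector of terms annotating both proteins (empty if
#'   either is unannotated).
#' @export
shared_terms <- function(m, n, ann) {
  tm <- ann$protein_to_terms[[m]]
  tn <- ann$protein_to_terms[[n]]
  if (is.null(tm) || is.null(tn)) return(character())
  intersect(tm, tn)
}

#' Number of network neighbors shared by two proteins
#'
#' Counts nodes adjacent to both `m` and `n`, excluding `m` and `n`
#' themselves.
#'
#' @param m,n Protein identifiers.
#' @param net A [ppi_network()].
#' @param nbrs Optional precomputed neighbor map (internal fast path).
#' @return Integer count.
#' @export
shared_neighbors <- function(m, n, net, nbrs = NULL) {
  if (is.null(nbrs)) nbrs <- neighbor_map(net)
  common <- intersect(nbrs[[m]] %||% character(), nbrs[[n]] %||% character())
  length(setdiff(common, c(m, n)))
}

rel_log <- function(x, params) {
  if (params$log_base == "natural") log(x) else log10(x)
}

# Core scorer used by the exported wrappers; takes precomputed neighbor map.
reliability_score_impl <- function(m, n, nbrs, ann, params) {
  cmn <- shared_terms(m, n, ann)
  ne <- length(setdiff(
    intersect(nbrs[[m]] %||% character(), nbrs[[n]] %||% character()),
    c(m, n)
  ))
  if (length(cmn) == 0L) {
    return(params$no_shared_term_value + ne)
  }
  if (ann$t_max < 1L) {
    stop("annotation invariant violated: shared terms exist but t_max = 0",
         call. = FALSE)
  }
  t_min <- min(lengths(ann$term_to_proteins[cmn]))
  -length(cmn) * rel_log(t_min / ann$t_max, params) + ne
}

#' Interaction reliability score
#'
#' Scores the reliability of the interaction between proteins `m` and `n` as
#' the sum of a GO term-specificity summand and the shared-neighbor count:
#' \deqn{rel(m,n) = -|C(m,n)| \log\left(\frac{\min_i |T_i(m,n)|}{T_{max}}\right) + NE(m,n)}
#' where \eqn{C(m,n)} is the set of GO terms annotating both proteins,
#' \eqn{|T_i(m,n)|} the number of proteins annotated to shared term
#' \eqn{g_i}, \eqn{T_{max}} the size of the largest term, and \eqn{NE(m,n)}
#' the number of shared network neighbors. More shared terms, more specific
#' shared terms (small \eqn{|T_i|/T_{max}}), and more shared neighbors all
#' increase the score. With no shared term the semantic summand is
#' `params$no_shared_term_value` (default 0).
#'
#' @param m,n Protein identifiers.
#' @param net A [ppi_network()].
#' @param ann A [go_annotation()].
#' @param params A [reliability_params()].
#' @return A real score, at least `NE(m,n) + no_shared_term_value`.
#' @export
reliability_score <- function(m, n, net, ann,
                              params = reliability_params()) {
  reliability_score_impl(m, n, neighbor_map(net), ann, params)
}

#' Weight a network by interaction reliability
#'
#' Returns a network with identical topology whose edge weights are the
#' [reliability_score()] of each interaction.
#'
#' @inheritParams reliability_score
#' @return A weighted [ppi_network()].
#' @export
weight_network <- function(net, ann, params = reliability_params()) {
  stopifnot(inherits(net, "ppi_network"), inherits(ann, "go_annotation"))
  nbrs <- neighbor_map(net)
  w <- if (nrow(net$edges) > 0L) {
    mapply(reliability_score_impl, net$edges$a, net$edges$b,
           MoreArgs = list(nbrs = nbrs, ann = ann, params = params),
           USE.NAMES = FALSE)
  } else numeric()
  out <- net
  out$edges$weight <- as.numeric(w)
  out$weighted <- TRUE
  out
}

#' Remove low-reliability interactions
#'
#' Retains exactly the edges whose [reliability_score()] is greater than or
#' equal to `den_thred`; nodes left without any incident edge are removed, so
#' node counts shrink as the threshold rises.
#'
#' @inheritParams reliability_score
#' @param den_thred Denoising threshold (inclusive).
#' @return A [ppi_network()] with the same weighting status as `net`.
#' @export
denoise_network <- function(net, ann, den_thred,
                            params = reliability_params()) {
  stopifnot(inherits(net, "ppi_network"))
  stopifnot_scalar_number(den_thred, "den_thred")
  nbrs <- neighbor_map(net)
  if (nrow(net$edges) == 0L) {
    return(ppi_network(nodes = character()))
  }
  scores <- mapply(reliability_score_impl, net$edges$a, net$edges$b,
                   MoreArgs = list(nbrs = nbrs, ann = ann, params = params),
                   USE.NAMES = FALSE)
  keep <- scores >= den_thred
  ppi_network(net$edges$a[keep], net$edges$b[keep],
              weight = if (net$weighted) net$edges$weight[keep] else NULL)
}

#' Integrate literature-extracted PPIs into a network
#'
#' A literature pair becomes a candidate edge when its extractor weight is at
#' least `int_thred`, both endpoints are already nodes of the base network,
#' and the pair is not already an edge. When `den_thred` is supplied each
#' candidate must additionally reach that reliability score, evaluated
#' against the base (pre-integration) network's neighbor structure so the
#' result does not depend on the order candidates are added. The output keeps
#' the base node set; added edges carry their literature weight when the base
#' network is weighted.
#'
#' @param base A [ppi_network()].
#' @param lit A `lit_ppi_list` (see [read_literature_ppis()]).
#' @param int_thred Integrating threshold on the literature weight (inclusive).
#' @param den_thred Optional reliability threshold for candidates; requires
#'   `ann`.
#' @param ann A [go_annotation()] (required with `den_thred`).
#' @param params A [reliability_params()].
#' @return A [ppi_network()].
#' @export
integrate_network <- function(base, lit, int_thred, den_thred = NULL,
                              ann = NULL, params = reliability_params()) {
  stopifnot(inherits(base, "ppi_network"))
  stopifnot_scalar_number(int_thred, "int_thred")
  if (!is.null(den_thred) && is.null(ann)) {
    stop("`den_thred` requires a GO annotation (`ann`)", call. = FALSE)
  }
  cand <- lit$weight >= int_thred &
    lit$a %in% base$nodes & lit$b %in% base$nodes
  if (any(cand)) {
    existing <- edge_key(base$edges$a, base$edges$b)
    cand[cand] <- !(edge_key(lit$a[cand], lit$b[cand]) %in% existing)
  }
  if (!is.null(den_thred) && any(cand)) {
    nbrs <- neighbor_map(base)
    rel <- mapply(reliability_score_impl, lit$a[cand], lit$b[cand],
                  MoreArgs = list(nbrs = nbrs, ann = ann, params = params),
                  USE.NAMES = FALSE)
    cand[cand] <- rel >= den_thred
  }
  a <- c(base$edges$a, lit$a[cand])
  b <- c(base$edges$b, lit$b[cand])
  w <- if (base$weighted) c(base$edges$weight, lit$weight[cand]) else NULL
  ppi_network(a, b, weight = w, nodes = base$nodes)
}
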