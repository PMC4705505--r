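#' Construct a PPI network
#'
#' Builds a canonical undirected protein-protein interaction network from
#' parallel vectors of edge endpoints. Canonical form: no self-loops, each
#' edge stored with its endpoints in lexicographic order, at most one record
#' per pair (duplicate weighted edges keep the maximum weight, the optimistic
#' merge for confidence-like weights), edges sorted by endpoint pair. The node
#' set is the union of all endpoints and any extra `nodes`, so isolated nodes
#' are first-class.
#'
#' @param from,to Character vectors of protein identifiers (equal length).
#' @param weight Optional numeric vector of per-edge weights.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node identifiers.
#' @return An object of class `ppi_network`: a list with elements `nodes`
#'   (sorted character vector), `edges` (data.frame with columns `a`, `b` and,
#'   when weighted, `weight`) and `weighted` (logical).
#' @export
ppi_network <- function(from = character(), to = character(), weight = NULL,
                        nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("`from` and `to` must have the same length", call. = FALSE)
  }
  weighted <- !is.null(weight)
  if (weighted) {
    weight <- as.numeric(weight)
    if (length(weight) != length(from)) {
      stop("`weight` must match the number of edges", call. = FALSE)
    }
    if (anyNA(weight)) stop("edge weights must not be NA", call. = FALSE)
  }
  ids <- c(from, to, as.character(nodes %||% character()))
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop("protein identifiers must be non-empty strings", call. = FALSE)
  }

  keep <- from != to
  n_loops <- sum(!keep)
  if (n_loops > 0L) {
    message(n_loops, " self-loop(s) dropped")
  }
  a <- pmin(from[keep], to[keep])
  b <- pmax(from[keep], to[keep])
  w <- if (weighted) weight[keep] else NULL

  if (length(a) > 0L) {
    key <- edge_key(a, b)
    if (anyDuplicated(key)) {
      if (weighted) {
        w <- tapply(w, key, max)
        ord_keys <- names(w)
        parts <- strsplit(ord_keys, "\t", fixed = TRUE)
        a <- vapply(parts, `[[`, character(1), 1L)
        b <- vapply(parts, `[[`, character(1), 2L)
        w <- as.numeric(w)
      } else {
        dup <- duplicated(key)
        a <- a[!dup]; b <- b[!dup]
      }
      message("duplicate edge record(s) collapsed")
    }
    ord <- order(a, b, method = "radix")
    a <- a[ord]; b <- b[ord]
    if (weighted) w <- w[ord]
  }

  edges <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  if (weighted) edges$weight <- w
  structure(
    list(
      nodes = sort(unique(c(a, b, as.character(nodes %||% character())))),
      edges = edges,
      weighted = weighted
    ),
    class = "ppi_network"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges",
      if (x$weighted) " (weighted)" else "", "\n", sep = "")
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

# Named list: node -> sorted character vector of neighbors.
neighbor_map <- function(net) {
  nb <- vector("list", length(net$nodes))
  names(nb) <- net$nodes
  for (i in seq_along(nb)) nb[[i]] <- character()
  if (nrow(net$edges) > 0L) {
    sp_a <- split(net$edges$b, net$edges$a)
    sp_b <- split(net$edges$a, net$edges$b)
    for (nm in names(sp_a)) nb[[nm]] <- c(nb[[nm]], sp_a[[nm]])
    for (nm in names(sp_b)) nb[[nm]] <- c(nb[[nm]], sp_b[[nm]])
    nb <- lapply(nb, function(v) sort(unique(v)))
  }
  nb
}

# Named numeric: edge key -> weight (NULL for unweighted networks).
weight_map <- function(net) {
  if (!net$weighted) return(NULL)
  stats::setNames(net$edges$weight, edge_key(net$edges$a, net$edges$b))
}

#' Convert a PPI network to an igraph object
#'
#' @param net A [ppi_network()].
#' @return An undirected `igraph` graph whose vertex names are the protein
#'   identifiers; edge attribute `weight` is set for weighted networks.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges) > 0L) {
    ends <- rbind(match(net$edges$a, net$nodes), match(net$edges$b, net$nodes))
    g <- igraph::add_edges(g, as.vector(ends))
    if (net$weighted) igraph::E(g)$weight <- net$edges$weight
  }
  g
}

#' Read a PPI network from a tab-separated edge list
#'
#' Accepts lines of the form `protA<TAB>protB[<TAB>weight]`; lines starting
#' with `#` are comments and blank lines are ignored. Single-column lines
#' declare isolated nodes, so node counts survive write/read round-trips.
#' Self-loops are dropped (with a message) and duplicate edges collapsed,
#' keeping the maximum weight.
#'
#' @param path Path to the TSV file.
#' @param weighted If `TRUE`, a third numeric column is required on edge lines.
#' @return A [ppi_network()].
#' @export
read_network <- function(path, weighted = FALSE) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body) == 0L) stop("empty network file: ", path, call. = FALSE)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  ncol_exp <- if (weighted) 3L else 2L
  nf <- lengths(fields)
  singles <- nf == 1L
  bad <- !singles & nf != ncol_exp
  if (any(bad)) {
    stop("malformed line ", body[which(bad)[1]], " in ", path,
         ": expected ", ncol_exp, " tab-separated fields", call. = FALSE)
  }
  iso <- unlist(fields[singles])
  ef <- fields[!singles]
  from <- vapply(ef, `[[`, character(1), 1L)
  to <- vapply(ef, `[[`, character(1), 2L)
  w <- NULL
  if (weighted && length(ef) > 0L) {
    w_raw <- vapply(ef, `[[`, character(1), 3L)
    w <- suppressWarnings(as.numeric(w_raw))
    if (anyNA(w)) {
      bad_line <- body[!singles][which(is.na(w))[1]]
      stop("malformed line ", bad_line, " in ", path,
           ": non-numeric weight", call. = FALSE)
    }
  }
  ppi_network(from, to, weight = w, nodes = iso)
}

#' Write a PPI network as a tab-separated edge list
#'
#' Emits one line per edge (`a<TAB>b[<TAB>weight]`) plus one single-column
#' line per isolated node, so `read_network(write_network(net))` reproduces
#' `net` exactly.
#'
#' @param net A [ppi_network()].
#' @param path Output file path.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  lines <- if (net$weighted) {
    paste(net$edges$a, net$edges$b,
          formatC(net$edges$weight, format = "g", digits = 17), sep = "\t")
  } else {
    paste(net$edges$a, net$edges$b, sep = "\t")
  }
  iso <- setdiff(net$nodes, unique(c(net$edges$a, net$edges$b)))
  writeLines(c(lines, sort(iso)), path)
  invisible(NULL)
}

#' Construct a complex set
#'
#' @param complexes List of character vectors, each the member proteins of
#'   one complex. Members are deduplicated and sorted.
#' @param score Optional numeric vector of per-complex scores.
#' @return An object of class `complex_set` with elements `complexes` (list
#'   of sorted character vectors) and `score` (numeric or `NULL`).
#' @export
complex_set <- function(complexes = list(), score = NULL) {
  complexes <- lapply(complexes, function(m) {
    m <- as.character(m)
    if (any(!nzchar(m)) || anyNA(m)) {
      stop("complex members must be non-empty strings", call. = FALSE)
    }
    sort(unique(m))
  })
  if (!is.null(score)) {
    score <- as.numeric(score)
    if (length(score) != length(complexes)) {
      stop("`score` must have one value per complex", call. = FALSE)
    }
  }
  structure(list(complexes = complexes, score = score), class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  sizes <- lengths(x$complexes)
  cat("<complex_set> ", length(sizes), " complexes",
      if (length(sizes)) paste0(", sizes ", min(sizes), "-", max(sizes)) else "",
      if (!is.null(x$score)) ", scored" else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.complex_set <- function(x) length(x$complexes)

#' Read complexes from a flat file
#'
#' One complex per line, members tab-separated (MIPS/SGD-style flat export;
#' no complex identifiers, order is file order). A trailing `score=<float>`
#' field is read as the complex score. Complexes with fewer than `min_size`
#' distinct members are dropped.
#'
#' @param path Path to the file.
#' @param min_size Minimum number of distinct members to retain a complex.
#' @return A [complex_set()].
#' @export
read_complexes <- function(path, min_size = 2L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stop("empty complex file: ", path, call. = FALSE)
  empty <- !nzchar(trimws(lines))
  if (any(empty)) {
    warning(sum(empty), " empty line(s) skipped in ", path, call. = FALSE)
    lines <- lines[!empty]
  }
  if (length(lines) == 0L) stop("empty complex file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  scores <- rep(NA_real_, length(fields))
  for (i in seq_along(fields)) {
    last <- fields[[i]][length(fields[[i]])]
    if (grepl("^score=", last)) {
      scores[i] <- as.numeric(sub("^score=", "", last))
      fields[[i]] <- fields[[i]][-length(fields[[i]])]
    }
  }
  members <- lapply(fields, function(f) sort(unique(f[nzchar(f)])))
  keep <- lengths(members) >= min_size
  if (any(!keep)) {
    message(sum(!keep), " complex(es) below min_size dropped")
  }
  score <- if (all(is.na(scores))) NULL else scores[keep]
  complex_set(members[keep], score = score)
}

#' Write complexes to a flat file
#'
#' One complex per line, members tab-separated; when the set carries scores a
#' final `score=<float>` field is appended.
#'
#' @param cs A [complex_set()].
#' @param path Output file path.
#' @export
write_complexes <- function(cs, path) {
  stopifnot(inherits(cs, "complex_set"))
  lines <- vapply(cs$complexes, paste, character(1), collapse = "\t")
  if (!is.null(cs$score)) {
    lines <- paste0(lines, "\tscore=",
                    formatC(cs$score, format = "g", digits = 17))
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' Restrict a gold standard to the proteins of a network
#'
#' Members absent from the network are removed from every complex, and
#' complexes falling below `min_size` distinct members afterwards are dropped
#' -- the standard preparation of a reference complex set for evaluation
#' against a specific interaction network.
#'
#' @param gold A [complex_set()].
#' @param net A [ppi_network()].
#' @param min_size Minimum surviving size.
#' @return A [complex_set()] (possibly empty).
#' @export
restrict_gold_standard <- function(gold, net, min_size = 2L) {
  stopifnot(inherits(gold, "complex_set"), inherits(net, "ppi_network"))
  restricted <- lapply(gold$complexes, function(m) m[m %in% net$nodes])
  keep <- lengths(restricted) >= min_size
  score <- if (is.null(gold$score)) NULL else gold$score[keep]
  complex_set(restricted[keep], score = score)
}

#' Read a literature-extracted PPI list
#'
#' Tab-separated triples `protA<TAB>protB<TAB>weight`; weights are extractor
#' confidences and may be negative. Pairs are canonicalized (lexicographic
#' order), self-pairs dropped, and duplicate pairs collapsed keeping the
#' maximum weight.
#'
#' @param path Path to the TSV file.
#' @return An object of class `lit_ppi_list`: a data.frame with columns `a`,
#'   `b`, `weight`.
#' @export
read_literature_ppis <- function(path) {
  net <- read_network(path, weighted = TRUE)
  lit_ppi_list(net$edges$a, net$edges$b, net$edges$weight)
}

#' Construct a literature PPI list
#'
#' @param a,b Character vectors of protein identifiers.
#' @param weight Numeric extractor-confidence weights (may be negative).
#' @return A `lit_ppi_list` data.frame with columns `a`, `b`, `weight`.
#' @export
lit_ppi_list <- function(a = character(), b = character(), weight = numeric()) {
  net <- ppi_network(a, b, weight = weight)
  structure(net$edges, class = c("lit_ppi_list", "data.frame"))
}

#' Write a literature PPI list
#'
#' @param lit A `lit_ppi_list`.
#' @param path Output file path.
#' @export
write_literature_ppis <- function(lit, path) {
  writeLines(paste(lit$a, lit$b,
                   formatC(lit$weight, format = "g", digits = 17), sep = "\t"),
             path)
  invisible(NULL)
}

#' Read an alias-to-systematic-name map
#'
#' Two-column TSV `alias<TAB>systematic`. The map must be a function: one
#' systematic name per alias. Mapping is idempotent for names that are
#' already systematic.
#'
#' @param path Path to the TSV file.
#' @return A named character vector (names = aliases, values = systematic
#'   names) of class `alias_map`.
#' @export
read_alias_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    stop("alias map must have exactly two tab-separated columns", call. = FALSE)
  }
  alias <- vapply(fields, `[[`, character(1), 1L)
  sysn <- vapply(fields, `[[`, character(1), 2L)
  alias_map(stats::setNames(sysn, alias))
}

#' Construct an alias map
#'
#' @param mapping Named character vector, names = aliases, values =
#'   systematic names.
#' @return The validated mapping, class `alias_map`.
#' @export
alias_map <- function(mapping = character()) {
  if (length(mapping) > 0L && anyDuplicated(names(mapping))) {
    dups <- unique(names(mapping)[duplicated(names(mapping))])
    conflicting <- vapply(dups, function(d) {
      length(unique(mapping[names(mapping) == d])) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stop("alias map is not a function: alias(es) ",
           paste(dups[conflicting], collapse = ", "),
           " map to multiple systematic names", call. = FALSE)
    }
    mapping <- mapping[!duplicated(names(mapping))]
  }
  structure(mapping, class = "alias_map")
}

apply_alias <- function(ids, aliases) {
  hit <- ids %in% names(aliases)
  ids[hit] <- unname(aliases[ids[hit]])
  ids
}

#' Map protein aliases to systematic names
#'
#' Replaces every identifier present in the alias map by its systematic name
#' and re-canonicalizes; edges that collide after renaming are merged and
#' renamed self-loops dropped with a warning.
#'
#' @param x A [ppi_network()], [complex_set()] or `lit_ppi_list`.
#' @param aliases An [alias_map()].
#' @return An object of the same class as `x`.
#' @export
map_aliases <- function(x, aliases) {
  stopifnot(inherits(aliases, "alias_map"))
  if (inherits(x, "ppi_network")) {
    from <- apply_alias(x$edges$a, aliases)
    to <- apply_alias(x$edges$b, aliases)
    if (any(from == to)) {
      warning(sum(from == to), " edge(s) became self-loops after alias mapping",
              call. = FALSE)
    }
    nodes <- apply_alias(x$nodes, aliases)
    w <- if (x$weighted) x$edges$weight else NULL
    suppressMessages(ppi_network(from, to, weight = w, nodes = nodes))
  } else if (inherits(x, "lit_ppi_list")) {
    a <- apply_alias(x$a, aliases)
    b <- apply_alias(x$b, aliases)
    if (any(a == b)) {
      warning(sum(a == b), " pair(s) became self-pairs after alias mapping",
              call. = FALSE)
    }
    suppressMessages(lit_ppi_list(a, b, x$weight))
  } else if (inherits(x, "complex_set")) {
    complex_set(lapply(x$complexes, apply_alias, aliases = aliases),
                score = x$score)
  } else {
    stop("unsupported type for map_aliases", call. = FALSE)
  }
}
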