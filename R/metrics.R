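as_profile <- function(x) {
  if (igraph::is_igraph(x)) x <- local_clustering(x)
  if (!is.numeric(x) || length(x) < 1L) {
    stop("expected a graph or a non-empty clustering profile", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("clustering coefficients must lie in [0, 1]", call. = FALSE)
  }
  x
}

#' Per-node clustering coefficients
#'
#' `C_i` is the number of closed triplets centred on node `i` divided by the
#' number of triplets centred on it, `deg_i * (deg_i - 1) / 2`; nodes of
#' degree below 2 get `C_i = 0`.
#'
#' @param g An igraph undirected graph.
#' @return Numeric vector of `C_i` in `[0, 1]`, one per node, in node order.
#' @export
local_clustering <- function(g) {
  stopifnot(igraph::is_igraph(g))
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  cc
}

#' Average clustering coefficient
#'
#' Arithmetic mean of the per-node clustering coefficients, zeros included.
#'
#' @param x An igraph graph or a numeric clustering profile from
#'   [local_clustering()].
#' @return A number in `[0, 1]`.
#' @export
average_clustering <- function(x) {
  mean(as_profile(x))
}

#' Clustering coefficient entropy
#'
#' Shannon entropy (natural log) of the distribution obtained by normalizing
#' the strictly positive clustering coefficients:
#' `p_i = C_i / sum_j C_j` over nodes with `C_i > 0`, and
#' `E_C = -sum p_i log p_i`. An all-zero profile gives `E_C = 0`. The value
#' is bounded above by `log` of the number of nodes with positive `C_i`.
#'
#' @inheritParams average_clustering
#' @return A non-negative number.
#' @export
clustering_entropy <- function(x) {
  cc <- as_profile(x)
  pos <- cc[cc > 0]
  if (length(pos) == 0L) return(0)
  p <- pos / sum(pos)
  -sum(p * log(p))
}

#' Degree sequence and mean degree
#'
#' @param g An igraph graph.
#' @return A list with `degrees` (integer vector in node order) and
#'   `mean_degree` (`2 * |E| / n`).
#' @export
degree_stats <- function(g) {
  stopifnot(igraph::is_igraph(g))
  deg <- igraph::degree(g)
  list(degrees = as.integer(deg), mean_degree = mean(deg))
}

#' Multiscale clustering features of a series
#'
#' Builds the LPHVG at each scale and summarizes it by the two-dimensional
#' feature pair used for classification: the average clustering coefficient
#' and the clustering coefficient entropy.
#'
#' @inheritParams build_mlphvg
#' @param signal_id Identifier copied into the output rows.
#' @return A data frame with columns `signal_id`, `scale`, `avg_clustering`,
#'   `clustering_entropy`; one row per scale. Deterministic given
#'   `(x, scales, L)`.
#' @export
extract_features <- function(x, scales = 1:5, L = 1L, signal_id = "signal") {
  mg <- build_mlphvg(x, scales = scales, L = L)
  rows <- lapply(mg$graphs, function(g) {
    cc <- local_clustering(g)
    data.frame(
      signal_id = signal_id,
      scale = igraph::graph_attr(g, "scale"),
      avg_clustering = mean(cc),
      clustering_entropy = clustering_entropy(cc),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature table for a batch of signals
#'
#' @param series Named list of numeric series; names become `signal_id`s.
#' @inheritParams build_mlphvg
#' @return Feature data frame with `length(series) * length(scales)` rows.
#' @seealso [extract_features()]
#' @export
features_table <- function(series, scales = 1:5, L = 1L) {
  if (!is.list(series) || length(series) == 0L) {
    stop("series must be a non-empty list", call. = FALSE)
  }
  ids <- names(series) %||% as.character(seq_along(series))
  if (is.null(names(series))) names(series) <- ids
  out <- do.call(rbind, lapply(ids, function(id) {
    extract_features(series[[id]], scales = scales, L = L, signal_id = id)
  }))
  rownames(out) <- NULL
  out
}
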