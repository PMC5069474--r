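# Construct a visibility graph as an igraph object with provenance attributes.
new_vgraph <- function(n, edges, L, scale = 1L) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  igraph::V(g)$t <- seq_len(n)
  g <- igraph::set_graph_attr(g, "L", as.integer(L))
  g <- igraph::set_graph_attr(g, "scale", as.integer(scale))
  g
}

#' Coarse-grain a time series
#'
#' Reduces a series of length `N` to `floor(N/s)` points at scale factor `s`
#' by averaging consecutive non-overlapping windows of `s` samples; trailing
#' samples beyond `s * floor(N/s)` are discarded, following the standard
#' multiscale-entropy convention. At `s = 1` the series is returned unchanged.
#'
#' @param x Numeric vector of finite values.
#' @param s Positive integer scale factor, `1 <= s <= length(x)`.
#' @return Numeric vector of length `floor(length(x) / s)`.
#' @examples
#' coarse_grain(c(1, 2, 3, 4), 2)    # 1.5 3.5
#' coarse_grain(c(1, 2, 3, 4, 5), 2) # 1.5 3.5 (5th sample dropped)
#' @export
coarse_grain <- function(x, s) {
  check_series(x, min_len = 1L)
  s <- check_count(s, "scale s", min = 1L)
  n <- length(x)
  if (s > n) {
    stop("invalid scale: s = ", s, " exceeds series length N = ", n,
         call. = FALSE)
  }
  if (s == 1L) return(as.numeric(x))
  m <- n %/% s
  colMeans(matrix(x[seq_len(m * s)], nrow = s))
}

#' Horizontal visibility graph of a series
#'
#' Nodes are the time-ordered samples; samples `i < j` are linked iff every
#' in-between sample is strictly lower than both endpoints
#' (`y(n) < min(y(i), y(j))` for all `i < n < j`). Ties block: an in-between
#' sample equal to the lower endpoint obstructs the horizontal line, so a
#' constant series yields the path graph. Equivalent to
#' `build_lphvg(x, L = 0)`.
#'
#' @param x Numeric vector, length >= 2, finite values.
#' @return An [igraph][igraph::igraph-package] undirected graph with vertex
#'   attribute `t` (original sample index) and graph attributes `L` (0) and
#'   `scale`.
#' @examples
#' igraph::ecount(build_hvg(c(3, 1, 2)))  # 3: the middle value hides nothing
#' igraph::ecount(build_hvg(c(1, 3, 2)))  # 2: the peak blocks 1 <-> 3
#' @export
build_hvg <- function(x) {
  build_lphvg(x, L = 0L)
}

#' Limited penetrable horizontal visibility graph
#'
#' Relaxation of the horizontal visibility criterion: samples `i < j` are
#' linked iff at most `L` in-between samples block the horizontal line, where
#' a blocker is a sample `y(n) >= min(y(i), y(j))`. At `L = 0` the edge set
#' equals [build_hvg()] exactly, and the HVG edge set is always a subset of
#' any LPHVG edge set (monotone in `L`). Consecutive samples are always
#' linked, so the graph is connected.
#'
#' @param x Numeric vector, length >= 2, finite values.
#' @param L Non-negative integer penetrable distance (default 1, the setting
#'   used for the EEG analysis).
#' @param scale Integer recorded as the graph's `scale` attribute
#'   (provenance only; no coarse-graining is performed here).
#' @return An igraph undirected graph; see [build_hvg()] for attributes.
#' @examples
#' igraph::ecount(build_lphvg(c(1, 3, 2), L = 1))  # 3: one blocker allowed
#' @export
build_lphvg <- function(x, L = 1L, scale = 1L) {
  check_series(x, min_len = 2L)
  L <- check_count(L, "penetrable distance L", min = 0L)
  edges <- lphvg_edges(as.numeric(x), L)
  new_vgraph(length(x), edges, L = L, scale = scale)
}

#' Reference LPHVG construction (literal blocker enumeration)
#'
#' Same contract as [build_lphvg()], implemented as the direct double loop
#' over ordered pairs with a full count of in-between blockers for each pair
#' — no early termination and no incremental bookkeeping. Quadratic and
#' intended for small inputs; it serves as an independent correctness
#' reference for the fast construction.
#'
#' @inheritParams build_lphvg
#' @return An igraph undirected graph identical in edge set to
#'   `build_lphvg(x, L)`.
#' @export
build_lphvg_oracle <- function(x, L = 1L, scale = 1L) {
  check_series(x, min_len = 2L)
  L <- check_count(L, "penetrable distance L", min = 0L)
  x <- as.numeric(x)
  n <- length(x)
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      blockers <- if (j - i == 1L) {
        0L
      } else {
        sum(x[(i + 1L):(j - 1L)] >= min(x[i], x[j]))
      }
      if (blockers <= L) {
        from <- c(from, i)
        to <- c(to, j)
      }
    }
  }
  new_vgraph(n, cbind(from, to), L = L, scale = scale)
}

#' Multiscale limited penetrable horizontal visibility graphs
#'
#' Coarse-grains the series at each scale factor and builds the LPHVG of each
#' coarse-grained series, yielding the per-scale network family on which the
#' multiscale features are computed.
#'
#' @param x Numeric vector, finite values.
#' @param scales Strictly increasing positive integers (default `1:5`); every
#'   scale must leave at least 2 coarse-grained points.
#' @param L Non-negative integer penetrable distance shared by all scales.
#' @return An object of class `"mlphvg"`: a list with `graphs` (named list of
#'   igraph objects keyed by scale), `scales`, `L` and `n` (source length).
#'   The graph at scale `s` has exactly `floor(n / s)` nodes.
#' @examples
#' m <- build_mlphvg(runif(100), scales = c(1, 2, 5), L = 1)
#' vapply(m$graphs, igraph::vcount, integer(1))  # 100 50 20
#' @export
build_mlphvg <- function(x, scales = 1:5, L = 1L) {
  check_series(x, min_len = 2L)
  if (length(scales) < 1L) stop("at least one scale is required", call. = FALSE)
  scales <- vapply(scales, check_count, integer(1), name = "scale", min = 1L)
  if (any(diff(scales) <= 0)) {
    stop("scales must be strictly increasing", call. = FALSE)
  }
  n <- length(x)
  for (s in scales) {
    if (n %/% s < 2L) {
      stop("invalid scale: s = ", s, " leaves fewer than 2 points from N = ",
           n, " samples", call. = FALSE)
    }
  }
  graphs <- lapply(scales, function(s) {
    build_lphvg(coarse_grain(x, s), L = L, scale = s)
  })
  names(graphs) <- as.character(scales)
  structure(
    list(graphs = graphs, scales = scales, L = as.integer(L), n = n),
    class = "mlphvg"
  )
}

#' @export
print.mlphvg <- function(x, ...) {
  cat("Multiscale LPHVG: series of length", x$n, "| L =", x$L, "\n")
  for (s in names(x$graphs)) {
    g <- x$graphs[[s]]
    cat(sprintf("  scale %s: %d nodes, %d edges\n",
                s, igraph::vcount(g), igraph::ecount(g)))
  }
  invisible(x)
}
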