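#' Read a time series from a single-column text or CSV file
#'
#' One sample per row; a single non-numeric header row is auto-detected and
#' skipped; blank lines are ignored. Any non-finite or non-numeric body value
#' (including `nan`/`inf` tokens) aborts with the offending line number.
#'
#' @param path Path to the file.
#' @return Numeric vector of finite samples.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- which(lines != "")
  if (length(keep) == 0L) stop("empty series file: ", path, call. = FALSE)
  vals <- sub("[,;\t ].*$", "", lines[keep])  # first field of each row
  num <- suppressWarnings(as.numeric(vals))
  nanlike <- toupper(vals) %in%
    c("NA", "NAN", "INF", "-INF", "+INF", "INFINITY", "-INFINITY")
  start <- 1L
  if (!is.finite(num[1]) && !nanlike[1]) start <- 2L  # header row
  if (start > length(num)) {
    stop("no data rows in ", path, call. = FALSE)
  }
  body <- num[start:length(num)]
  body_lines <- keep[start:length(num)]
  bad <- which(!is.finite(body))
  if (length(bad)) {
    stop("non-finite or non-numeric value at line ", body_lines[bad[1]],
         " of ", path, call. = FALSE)
  }
  body
}

canonical_edgelist <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L) return(matrix(integer(0), ncol = 2))
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

#' Write a graph as a plain-text edge list
#'
#' Two whitespace-separated 1-based node indices per line, `i < j`, sorted
#' lexicographically — a diff-stable serialization.
#'
#' @param g An igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  el <- canonical_edgelist(g)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Read an edge list written by [write_edgelist()]
#'
#' @param path Input path.
#' @param n_nodes Node count; defaults to the largest index seen.
#' @param L,scale Provenance attributes to record on the graph.
#' @return An igraph undirected graph.
#' @export
read_edgelist <- function(path, n_nodes = NULL, L = NA_integer_,
                          scale = NA_integer_) {
  el <- as.matrix(read.table(path, col.names = c("i", "j")))
  n <- n_nodes %||% max(el)
  new_vgraph(n, el, L = L, scale = scale)
}

#' Export a visibility graph as GraphML
#'
#' Carries the node attribute `t` (original sample index) and graph
#' attributes `scale` and `L`.
#'
#' @inheritParams write_edgelist
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write / read a multiscale feature table as CSV
#'
#' Columns: `signal_id`, `scale`, `avg_clustering`, `clustering_entropy`.
#'
#' @param features Data frame from [extract_features()] / [features_table()].
#' @param path File path.
#' @return `write_features`: `path`, invisibly; `read_features`: the data
#'   frame.
#' @export
write_features <- function(features, path) {
  need <- c("signal_id", "scale", "avg_clustering", "clustering_entropy")
  if (!all(need %in% names(features))) {
    stop("feature table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  write.csv(features[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("signal_id", "scale", "avg_clustering", "clustering_entropy")
  if (!all(need %in% names(df))) {
    stop("feature table ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a labels CSV (`signal_id,label`)
#'
#' @param path File path.
#' @return Named integer vector of 0/1 labels keyed by `signal_id`.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("signal_id", "label") %in% names(df))) {
    stop("labels file ", path, " must have columns signal_id,label",
         call. = FALSE)
  }
  labels <- as.integer(df$label)
  names(labels) <- as.character(df$signal_id)
  labels
}

#' Read a dataset manifest CSV (`path,label,...`)
#'
#' @param path Manifest path; the `path` column is resolved relative to the
#'   manifest's directory when not absolute.
#' @return Data frame with resolved `path` and any further columns.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"path" %in% names(df) || nrow(df) == 0L) {
    stop("manifest ", path, " must be a non-empty CSV with a 'path' column",
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  abs <- grepl("^(/|[A-Za-z]:)", df$path)
  df$path[!abs] <- file.path(base, df$path[!abs])
  missing <- !file.exists(df$path)
  if (any(missing)) {
    stop("manifest row ", which(missing)[1], ": file not found: ",
         df$path[which(missing)[1]], call. = FALSE)
  }
  df
}
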