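# Canonical "i j" edge-set representation for graph comparisons.
edge_set <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L) return(character(0))
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

# Brute-force local clustering: enumerate every neighbor pair and test
# adjacency directly on the adjacency matrix.
brute_clustering <- function(g) {
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  vapply(seq_len(nrow(adj)), function(i) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2L) return(0)
    closed <- 0L
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        if (adj[nb[a], nb[b]]) closed <- closed + 1L
      }
    }
    closed / (k * (k - 1L) / 2)
  }, numeric(1))
}

# Run the installed CLI script in a child Rscript that can see this library.
run_cli <- function(args) {
  script <- system.file("scripts", "mlphvg.R", package = "mlphvg")
  libs <- paste(.libPaths(), collapse = ":")
  out <- suppressWarnings(system2(
    "Rscript", c("--vanilla", shQuote(script), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", shQuote(libs))
  ))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
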