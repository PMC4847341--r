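# hand-built activity table: levels matrix -> activity_table
make_activity <- function(levels) {
  structure(levels, class = c("activity_table", class(levels)))
}

# DPPN from an edge list and a levels matrix (rows = proteins)
make_dppn <- function(edges, levels) {
  suppressMessages(build_dppn(ppi_network(edges), make_activity(levels)))
}

# DPPN in which every listed protein is active at level `level` at every
# time point: isolates the topology arithmetic from the activity layer
uniform_dppn <- function(edges, n_tp = 4L, level = 0.99) {
  ids <- sort(unique(c(edges)))
  lev <- matrix(level, length(ids), n_tp, dimnames = list(ids, NULL))
  make_dppn(edges, lev)
}

# independent maximal-clique oracle: exhaustive subset enumeration over
# an adjacency matrix (vertex names in dimnames)
brute_force_cliques <- function(adj, min_size = 3L) {
  n <- nrow(adj)
  ids <- rownames(adj)
  out <- list()
  for (k in seq(min_size, n)) {
    sets <- utils::combn(n, k)
    for (c_i in seq_len(ncol(sets))) {
      s <- sets[, c_i]
      if (sum(adj[s, s]) != k * (k - 1L)) next       # not complete
      others <- setdiff(seq_len(n), s)
      if (length(others) &&
          any(colSums(adj[s, others, drop = FALSE]) == k)) next  # not maximal
      out[[length(out) + 1L]] <- sort(ids[s])
    }
  }
  keys <- vapply(out, paste, character(1L), collapse = "|")
  out[order(keys)]
}

# random symmetric 0/1 adjacency matrix with named vertices
random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1L) / 2) < p)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("V%02d", seq_len(n)),
                      sprintf("V%02d", seq_len(n)))
  a
}

adjacency_to_edges <- function(adj) {
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  cbind(rownames(adj)[idx[, 1L]], colnames(adj)[idx[, 2L]])
}

# canonical string form of a clique list for set comparison
clique_keys <- function(cliques) {
  sort(vapply(cliques, function(x) paste(sort(x), collapse = "|"),
              character(1L)))
}

# run the whole pipeline from an expression matrix + ppi network
run_pipeline <- function(net, expr_mat, cycles = 3L, ppc = 12L,
                         config = detector_config()) {
  mat <- collapse_cycles(expr_mat, cycles, ppc)
  act <- suppressWarnings(build_activity_table(mat))
  dp <- suppressMessages(build_dppn(net, act))
  identify_complexes(dp, config)
}
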