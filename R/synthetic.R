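# run expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification for a synthetic PPI + expression world
#'
#' Describes a ground-truth world the generator emits: a background
#' Erdos-Renyi interactome, planted complexes realised as (optionally
#' density-thinned) cliques, and a time-course expression matrix over
#' `n_cycles` replicate cycles in which planted members receive an
#' expression pulse at their complex's active time point.
#'
#' @param n_proteins Total number of proteins.
#' @param n_timepoints Time points per cycle (default 12).
#' @param n_cycles Replicate cycles in the emitted matrix (default 3).
#' @param planted List of planted complexes, each a list with `size`,
#'   `time` (active time point in `1..n_timepoints`) and optional
#'   `density` (within-complex edge retention probability, default 1).
#' @param background_edge_prob Edge probability between pairs not joined
#'   by a planted complex.
#' @param noise_sd Per-time-point expression noise standard deviation.
#' @param amplitude Pulse height for planted members at their active
#'   time, in units of `noise_sd` (>= 3 so the pulse clears the
#'   three-sigma threshold; default 4).
#' @param wave_amplitude Amplitude (in `noise_sd` units) of the periodic
#'   baseline oscillation given to background genes (default 1).
#' @param baseline_range Range of per-gene baseline means (uniform draw).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_proteins = 200L, n_timepoints = 12L,
                           n_cycles = 3L,
                           planted = list(list(size = 8L, time = 10L,
                                               density = 1)),
                           background_edge_prob = 0.01, noise_sd = 1,
                           amplitude = 4, wave_amplitude = 1,
                           baseline_range = c(5, 10)) {
  stopifnot(n_proteins >= 2L, n_timepoints >= 2L, n_cycles >= 1L,
            background_edge_prob >= 0, background_edge_prob <= 1,
            noise_sd >= 0, amplitude >= 0)
  sizes <- vapply(planted, function(p) as.integer(p$size), integer(1L))
  times <- vapply(planted, function(p) as.integer(p$time), integer(1L))
  if (any(sizes < 2L)) stop("planted complex sizes must be >= 2")
  if (any(times < 1L | times > n_timepoints))
    stop("planted complex time points must lie in 1..n_timepoints")
  if (sum(sizes) > n_proteins)
    stop("planted complexes require ", sum(sizes),
         " proteins but n_proteins = ", n_proteins)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_timepoints = as.integer(n_timepoints),
                 n_cycles = as.integer(n_cycles), planted = planted,
                 background_edge_prob = background_edge_prob,
                 noise_sd = noise_sd, amplitude = amplitude,
                 wave_amplitude = wave_amplitude,
                 baseline_range = baseline_range),
            class = "synthetic_spec")
}

#' Generate a synthetic PPI network, expression course and benchmark
#'
#' Planted complexes occupy disjoint blocks of proteins and are realised
#' as cliques (thinned to `density`); remaining pairs receive background
#' edges independently.  Expression is baseline plus Gaussian noise;
#' background genes additionally oscillate with a random phase, and
#' planted members receive an `amplitude * noise_sd` pulse at their
#' complex's time point in every cycle, so that after cycle collapsing
#' the pulse clears the member's own three-sigma threshold.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @return List with paths `ppi`, `expression`, `benchmark`, `truth_json` and
#'   the in-memory `network`, `expression_matrix` and `truth` objects.
#' @export
generate_synthetic <- function(spec, dir, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(seed, {
    n <- spec$n_proteins
    ids <- sprintf("P%04d", seq_len(n))
    # disjoint member blocks for planted complexes
    offset <- 0L
    members <- lapply(spec$planted, function(p) {
      out <- ids[offset + seq_len(p$size)]
      offset <<- offset + as.integer(p$size)
      out
    })
    # edges: planted cliques (density-thinned), then background pairs
    edges <- matrix(character(0L), 0L, 2L)
    for (ci in seq_along(members)) {
      pr <- utils::combn(members[[ci]], 2L)
      dens <- spec$planted[[ci]]$density
      if (is.null(dens)) dens <- 1
      keep <- stats::runif(ncol(pr)) <= dens
      edges <- rbind(edges, t(pr[, keep, drop = FALSE]))
    }
    planted_key <- paste(edges[, 1L], edges[, 2L])
    all_pairs <- utils::combn(ids, 2L)
    bg <- stats::runif(ncol(all_pairs)) <= spec$background_edge_prob
    bg_pairs <- all_pairs[, bg, drop = FALSE]
    bg_new <- !(paste(bg_pairs[1L, ], bg_pairs[2L, ]) %in% planted_key)
    edges <- rbind(edges, t(bg_pairs[, bg_new, drop = FALSE]))
    net <- ppi_network(edges)
    # expression: baseline + optional periodic wave + noise + pulses
    n_col <- spec$n_cycles * spec$n_timepoints
    mu <- stats::runif(n, spec$baseline_range[1L], spec$baseline_range[2L])
    phase <- stats::runif(n, 0, 2 * pi)
    planted_ids <- unlist(members)
    is_planted <- ids %in% planted_ids
    tp_of_col <- rep(seq_len(spec$n_timepoints), times = spec$n_cycles)
    wave <- outer(phase, tp_of_col, function(ph, t)
      sin(2 * pi * t / spec$n_timepoints + ph))
    wave[is_planted, ] <- 0          # planted genes: flat baseline + pulse
    expr <- mu + spec$wave_amplitude * spec$noise_sd * wave +
      matrix(stats::rnorm(n * n_col, 0, spec$noise_sd), n, n_col)
    for (ci in seq_along(members)) {
      rows <- match(members[[ci]], ids)
      cols <- which(tp_of_col == spec$planted[[ci]]$time)
      expr[rows, cols] <- expr[rows, cols] +
        spec$amplitude * spec$noise_sd
    }
    dimnames(expr) <- list(ids, paste0("T", seq_len(n_col)))
    truth <- list(seed = seed,
                  n_timepoints = spec$n_timepoints,
                  n_cycles = spec$n_cycles,
                  complexes = lapply(seq_along(members), function(ci)
                    list(members = members[[ci]],
                         time = spec$planted[[ci]]$time)))
    paths <- list(ppi = file.path(dir, "ppi.tsv"),
                  expression = file.path(dir, "expression.tsv"),
                  benchmark = file.path(dir, "benchmark.tsv"),
                  truth_json = file.path(dir, "truth.json"))
    utils::write.table(net$edges, paths$ppi, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_expression_tsv(expr, paths$expression)
    writeLines(vapply(truth$complexes,
                      function(x) paste(x$members, collapse = "\t"),
                      character(1L)), paths$benchmark)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                         digits = NA)
    c(paths, list(network = net, expression_matrix = expr, truth = truth))
  })
}

#' Write an expression matrix as TSV
#'
#' Header row of time labels, first column `gene_id`; the format read
#' back by [read_expression()].
#'
#' @param mat Numeric matrix with gene rownames and time colnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  writeLines(paste(rownames(mat),
                   apply(mat, 1L, function(r)
                     paste(format(r, digits = 15, trim = TRUE,
                                  scientific = FALSE), collapse = "\t")),
               sep = "\t"), con)
  invisible(path)
}

#' Shuffle expression values across time points within each gene
#'
#' The randomisation control: each gene's row is independently permuted
#' across the time columns, preserving its multiset of values (hence its
#' mean, SD and activity thresholds) while destroying temporal structure.
#'
#' @param mat Expression matrix (genes x time points).
#' @param seed Integer seed.
#' @return Matrix of the same shape and dimnames.
#' @export
shuffle_expression <- function(mat, seed) {
  .with_seed(seed, {
    out <- mat
    for (i in seq_len(nrow(mat)))
      out[i, ] <- mat[i, sample.int(ncol(mat))]
    out
  })
}

#' File-to-file variant of [shuffle_expression()]
#'
#' @param path Input expression TSV.
#' @param out Output TSV path.
#' @param seed Integer seed.
#' @export
shuffle_expression_file <- function(path, out, seed) {
  write_expression_tsv(shuffle_expression(read_expression(path), seed),
                       out)
  invisible(out)
}
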