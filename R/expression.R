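#' Active probability levels used by the k-sigma tiers
#'
#' The three probability levels assigned to a protein at an active time
#' point, corresponding to the normal-distribution masses of the one-, two-
#' and three-sigma intervals (0.6827, 0.9545, 0.9973) truncated to two
#' decimals.
#'
#' @format Named numeric vector with elements `P1` (0.99), `P2` (0.95) and
#'   `P3` (0.68).
#' @export
ACTIVITY_LEVELS <- c(P1 = 0.99, P2 = 0.95, P3 = 0.68)

#' Read a time-course gene-expression matrix
#'
#' Parses a TSV file with a header row of time-point labels and gene
#' identifiers in the first column.  Lines starting with `!` (GEO
#' series-matrix comment lines) are skipped.  Gene identifiers are
#' uppercased; duplicate gene rows are averaged element-wise with a warning.
#'
#' @param path Path to a tab-separated expression file.
#' @return Numeric matrix, rows = genes (rownames are uppercased IDs),
#'   columns = time points in file order.
#' @export
read_expression <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("no expression records in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_tp <- length(header) - 1L
  if (n_tp < 1L)
    stop("expression header must contain at least one time-point column")
  body <- fields[-1L]
  bad <- which(lengths(body) != n_tp + 1L)
  if (length(bad))
    stop("malformed expression row at line ", bad[1L] + 1L,
         ": expected ", n_tp + 1L, " columns, found ",
         length(body[[bad[1L]]]))
  ids <- toupper(vapply(body, `[[`, character(1L), 1L))
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(n_tp)))
  if (n_tp == 1L) vals <- matrix(vals, nrow = 1L)
  if (anyNA(vals)) {
    bad_row <- which(colSums(is.na(vals)) > 0L)[1L]
    stop("non-numeric expression value at line ", bad_row + 1L,
         " (gene ", ids[bad_row], ")")
  }
  mat <- t(vals)
  rownames(mat) <- ids
  colnames(mat) <- header[-1L]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("averaging duplicate expression rows for ",
            length(dup), " gene(s): ",
            paste(utils::head(dup, 5L), collapse = ", "),
            if (length(dup) > 5L) ", ..." else "")
    mat <- rowsum(mat, group = ids) / as.vector(table(ids)[unique(ids)])
    mat <- mat[unique(ids), , drop = FALSE]
  }
  mat
}

#' Collapse replicate expression cycles
#'
#' Time courses recorded over several successive cycles (e.g. three yeast
#' metabolic cycles of 12 intervals each) are reduced to a single cycle of
#' `points_per_cycle` time points by averaging, position-wise, across
#' cycles.
#'
#' @param mat Expression matrix, genes x (cycles * points_per_cycle).
#' @param cycles Number of successive cycles in the data.
#' @param points_per_cycle Time points per cycle.
#' @param method `"mean"` (default) averages positions across cycles;
#'   `"first"` keeps the first cycle only; `"none"` returns the input.
#' @return Matrix with `points_per_cycle` columns (unless `method = "none"`).
#' @export
collapse_cycles <- function(mat, cycles, points_per_cycle,
                            method = c("mean", "first", "none")) {
  method <- match.arg(method)
  if (method == "none") return(mat)
  if (ncol(mat) != cycles * points_per_cycle) {
    bad <- rownames(mat)[1L]
    stop("expression profile length ", ncol(mat), " for gene ",
         if (is.null(bad)) "<unnamed>" else bad,
         " does not equal cycles * points_per_cycle = ",
         cycles * points_per_cycle)
  }
  if (method == "first" || cycles == 1L) {
    out <- mat[, seq_len(points_per_cycle), drop = FALSE]
  } else {
    out <- matrix(0, nrow(mat), points_per_cycle,
                  dimnames = list(rownames(mat), NULL))
    for (c_i in seq_len(cycles))
      out <- out + mat[, (c_i - 1L) * points_per_cycle +
                         seq_len(points_per_cycle), drop = FALSE]
    out <- out / cycles
  }
  colnames(out) <- paste0("T", seq_len(points_per_cycle))
  out
}

#' Per-gene mean, standard deviation and k-sigma activity thresholds
#'
#' For each gene with expression values \eqn{G_1..G_n} the mean
#' \eqn{\alpha} and sample standard deviation \eqn{\sigma} (divisor
#' \eqn{n-1}) define three activity thresholds
#' \deqn{Ge\_thresh_k = \alpha + k \sigma (1 - 1/(1+\sigma^2)), k = 1,2,3.}
#' The damping factor pulls the threshold towards the mean for
#' low-variance genes and towards \eqn{\alpha + k\sigma} for noisy ones.
#'
#' @param x Numeric matrix (genes x time points) or a single numeric
#'   profile vector.
#' @return Data frame with columns `gene_id`, `mean`, `sd`, `thresh1`,
#'   `thresh2`, `thresh3`.
#' @export
gene_stats <- function(x) {
  if (is.vector(x) && is.numeric(x))
    x <- matrix(x, nrow = 1L, dimnames = list("gene", NULL))
  if (ncol(x) < 2L)
    stop("at least 2 time points required to compute a standard deviation")
  m <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  damp <- s * (1 - 1 / (1 + s^2))
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(x)))
  data.frame(gene_id = ids, mean = m, sd = s,
             thresh1 = m + 1 * damp,
             thresh2 = m + 2 * damp,
             thresh3 = m + 3 * damp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Active probability level of an expression value
#'
#' Assigns the tiered active probability: 0.99 if the value reaches the
#' three-sigma threshold, 0.95 if it reaches the two-sigma threshold,
#' 0.68 if it reaches the one-sigma threshold, else 0.  Boundaries are
#' inclusive from above (`value >= thresh_k`).
#'
#' @param value Numeric vector of expression values.
#' @param thresh1,thresh2,thresh3 Thresholds, recycled against `value`.
#' @return Numeric vector of levels in `{0, 0.68, 0.95, 0.99}`.
#' @export
active_probability <- function(value, thresh1, thresh2, thresh3) {
  ifelse(value >= thresh3, ACTIVITY_LEVELS[["P1"]],
  ifelse(value >= thresh2, ACTIVITY_LEVELS[["P2"]],
  ifelse(value >= thresh1, ACTIVITY_LEVELS[["P3"]], 0)))
}

#' Build the per-protein activity table
#'
#' Applies the k-sigma tiers to every (gene, time point) cell of a
#' collapsed expression matrix.  The nonzero entries of a gene's row are
#' its active-time-attribute set.  Zero-variance genes are active at level
#' 0.99 everywhere (their value always equals all three thresholds); they
#' are reported with a warning because they carry no temporal information.
#'
#' @param mat Collapsed expression matrix (genes x time points).
#' @return An `activity_table`: numeric matrix of levels with the same
#'   dimnames as `mat` (columns renamed `T1..Tn`), class
#'   `"activity_table"`.
#' @export
build_activity_table <- function(mat) {
  st <- gene_stats(mat)
  flat <- st$sd == 0
  if (any(flat))
    warning(sum(flat), " zero-variance gene(s) are active at level 0.99 ",
            "at every time point: ",
            paste(utils::head(st$gene_id[flat], 5L), collapse = ", "),
            if (sum(flat) > 5L) ", ..." else "")
  lev <- matrix(0, nrow(mat), ncol(mat))
  for (j in seq_len(ncol(mat)))
    lev[, j] <- active_probability(mat[, j], st$thresh1, st$thresh2,
                                   st$thresh3)
  dimnames(lev) <- list(rownames(mat), paste0("T", seq_len(ncol(mat))))
  structure(lev, class = c("activity_table", class(lev)))
}

#' Active-time sets of an activity table
#'
#' @param activity An `activity_table`.
#' @return Named list: for each protein the integer vector of time points
#'   (1-based) with level > 0.
#' @export
active_sets <- function(activity) {
  m <- unclass(activity)
  sets <- lapply(seq_len(nrow(m)), function(i) unname(which(m[i, ] > 0)))
  names(sets) <- rownames(m)
  sets
}

#' Write an activity table as long-format TSV
#'
#' Columns: `protein_id`, `time_point` (`T1..Tn`), `probability_level`;
#' one row per (protein, time point) pair with a nonzero level.
#'
#' @param activity An `activity_table`.
#' @param path Output file path.
#' @export
write_activity_tsv <- function(activity, path) {
  m <- unclass(activity)
  idx <- which(m > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(protein_id = rownames(m)[idx[, 1L]],
                   time_point = paste0("T", idx[, 2L]),
                   probability_level = m[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
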