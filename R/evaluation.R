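#' Read a benchmark complex set
#'
#' One complex per line, whitespace-separated protein IDs; lines starting
#' with `#` are ignored.  IDs are uppercased; empty complexes and exact
#' duplicates are dropped.
#'
#' @param path Path to the benchmark file.
#' @param name Label for the set (defaults to the file name).
#' @return A `benchmark_set`: list with `complexes` (list of character
#'   vectors) and `name`.
#' @export
read_benchmark <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  cx <- lapply(strsplit(trimws(lines), "[ \t]+"),
               function(x) sort(unique(toupper(x))))
  cx <- cx[lengths(cx) > 0L]
  cx <- cx[!duplicated(vapply(cx, paste, character(1L), collapse = "|"))]
  structure(list(complexes = cx, name = name), class = "benchmark_set")
}

#' Neighborhood affinity between two protein sets
#'
#' \deqn{NA(P,B) = |P \cap B|^2 / (|P| |B|)}
#' 1 for identical sets, 0 for disjoint sets; `NA > 0.2` is the
#' conventional match criterion for complex prediction.
#'
#' @param p,b Nonempty character vectors of protein IDs.
#' @return Scalar in `[0, 1]`.
#' @export
neighborhood_affinity <- function(p, b) {
  p <- unique(p); b <- unique(b)
  if (length(p) == 0L || length(b) == 0L)
    stop("neighborhood affinity undefined for empty protein sets")
  length(intersect(p, b))^2 / (length(p) * length(b))
}

#' Match predicted complexes to a benchmark and compute the six metrics
#'
#' A predicted complex P and benchmark complex B match when
#' `NA(P,B) > na_thresh` (many-to-many matching).  Precision is the
#' fraction of predicted complexes matching at least one benchmark
#' complex, recall the fraction of benchmark complexes matched, F the
#' harmonic mean.  With `T[i,j]` the protein overlap between benchmark
#' complex i and predicted complex j, `Sn = sum_i max_j T[i,j] / sum_i
#' N_i`, `PPV = sum_j max_i T[i,j] / sum_ij T[i,j]` (0 when the
#' denominator is 0), and `Acc = sqrt(Sn * PPV)`.
#'
#' @param predicted List of character vectors (or complex records with a
#'   `members` element).
#' @param benchmark A `benchmark_set` or list of character vectors.
#' @param na_thresh Match threshold on the affinity score (default 0.2,
#'   strictly exceeded).
#' @return An `evaluation_report`: list with `precision`, `recall`,
#'   `f_score`, `sn`, `ppv`, `accuracy`, `n_cp`, `n_cb`, `n_predicted`,
#'   `n_benchmark` and `match_pairs` (data frame of matched index pairs
#'   with their affinity).
#' @export
match_and_score <- function(predicted, benchmark, na_thresh = 0.2) {
  pred <- lapply(predicted, function(x)
    if (is.list(x) && !is.null(x$members)) x$members else x)
  pred <- lapply(pred, function(x) unique(as.character(x)))
  bench <- if (inherits(benchmark, "benchmark_set")) benchmark$complexes
           else benchmark
  bench <- lapply(bench, function(x) unique(as.character(x)))
  if (length(bench) == 0L) stop("empty benchmark set")
  m <- length(pred)
  n <- length(bench)
  if (m == 0L) {
    warning("no predicted complexes: precision reported as 0")
    return(structure(list(precision = 0, recall = 0, f_score = 0,
                          sn = 0, ppv = 0, accuracy = 0,
                          n_cp = 0L, n_cb = 0L, n_predicted = 0L,
                          n_benchmark = n,
                          match_pairs = data.frame(predicted = integer(0),
                                                   benchmark = integer(0),
                                                   na = numeric(0))),
                     class = "evaluation_report"))
  }
  t_ij <- matrix(0L, n, m)            # benchmark rows, predicted columns
  for (i in seq_len(n))
    for (j in seq_len(m))
      t_ij[i, j] <- length(intersect(bench[[i]], pred[[j]]))
  na_ij <- t_ij^2 /
    outer(lengths(bench), lengths(pred))
  matched <- na_ij > na_thresh
  pairs <- which(matched, arr.ind = TRUE)
  match_pairs <- data.frame(predicted = as.integer(pairs[, 2L]),
                            benchmark = as.integer(pairs[, 1L]),
                            na = na_ij[pairs])
  match_pairs <- match_pairs[order(match_pairs$predicted,
                                   match_pairs$benchmark), , drop = FALSE]
  rownames(match_pairs) <- NULL
  n_cp <- sum(colSums(matched) > 0L)
  n_cb <- sum(rowSums(matched) > 0L)
  precision <- n_cp / m
  recall <- n_cb / n
  f_score <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  sn <- sum(apply(t_ij, 1L, max)) / sum(lengths(bench))
  denom <- sum(t_ij)
  ppv <- if (denom == 0) 0 else sum(apply(t_ij, 2L, max)) / denom
  structure(list(precision = precision, recall = recall,
                 f_score = f_score, sn = sn, ppv = ppv,
                 accuracy = sqrt(sn * ppv),
                 n_cp = as.integer(n_cp), n_cb = as.integer(n_cb),
                 n_predicted = m, n_benchmark = n,
                 match_pairs = match_pairs),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%d predicted vs %d benchmark complexes (Ncp=%d, Ncb=%d)\n",
              x$n_predicted, x$n_benchmark, x$n_cp, x$n_cb))
  v <- c(P = x$precision, R = x$recall, F = x$f_score,
         Sn = x$sn, PPV = x$ppv, Acc = x$accuracy)
  cat(paste(sprintf("%-4s %6.3f", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report)[c("precision", "recall", "f_score",
                                         "sn", "ppv", "accuracy", "n_cp",
                                         "n_cb", "n_predicted",
                                         "n_benchmark")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
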