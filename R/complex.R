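#' Detector configuration for core-attachment complex identification
#'
#' @param core_thresh Minimum edge weight (strictly exceeded) for an edge
#'   outside the selected clique-cores to become a 2-protein edge-core.
#' @param extend_thresh Minimum attachment score (strictly exceeded) for a
#'   neighbour protein to be attached to a core.
#' @param min_clique_size Smallest clique mined as a candidate core.
#' @param overlap_thresh Overlap ratio `|A∩B|/|B|` at or above which a
#'   lower-ranked candidate clique B is removed outright during greedy
#'   core selection; below it B is pruned of A's members and re-scored.
#' @return A `detector_config` list.
#' @export
detector_config <- function(core_thresh = 0.09, extend_thresh = 0.05,
                            min_clique_size = 3L, overlap_thresh = 0.5) {
  stopifnot(core_thresh >= 0, core_thresh <= 1,
            extend_thresh >= 0, extend_thresh <= 1,
            min_clique_size >= 2L,
            overlap_thresh > 0, overlap_thresh <= 1)
  structure(list(core_thresh = core_thresh, extend_thresh = extend_thresh,
                 min_clique_size = as.integer(min_clique_size),
                 overlap_thresh = overlap_thresh),
            class = "detector_config")
}

#' Enumerate maximal cliques of a DPPN
#'
#' All maximal cliques with at least `min_size` vertices of the DPPN's
#' (time-aggregated) edge set, via igraph's Bron-Kerbosch implementation.
#'
#' @param dppn A `dppn`.
#' @param min_size Minimum clique size (default 3).
#' @return List of sorted character vectors of member IDs, in a
#'   deterministic order (by size descending, then lexicographic).
#' @export
enumerate_maximal_cliques <- function(dppn, min_size = 3L) {
  if (length(dppn$vertices) < min_size || nrow(dppn$edges) == 0L)
    return(list())
  g <- igraph::graph_from_edgelist(dppn$edges, directed = FALSE)
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(x) sort(igraph::V(g)$name[x]))
  keys <- vapply(cl, paste, character(1L), collapse = "|")
  cl[order(-lengths(cl), keys)]
}

# memoized Eq-5 topology scorer bound to one DPPN
.topo_scorer <- function(dppn) {
  avg <- if (length(dppn$vertices)) average_degree(dppn) else 0
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  function(vi, vj) {
    key <- if (vi < vj) paste0(vi, "|", vj) else paste0(vj, "|", vi)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    ni <- dppn$adj[[vi]]
    nj <- dppn$adj[[vj]]
    val <- (length(intersect(ni, nj)) + 1) /
      (max(avg, length(ni)) + max(avg, length(nj)))
    memo[[key]] <- val
    val
  }
}

# common active-time set of a member set (vector of 1-based time points)
.common_active <- function(dppn, members) {
  sub <- dppn$prob[members, , drop = FALSE]
  unname(which(colSums(sub > 0) == length(members)))
}

# full active-correlated-clique record, or NULL when Ac is empty
.acc_record <- function(dppn, members, topo) {
  ac <- .common_active(dppn, members)
  if (length(ac) == 0L) return(NULL)
  sub <- dppn$prob[members, ac, drop = FALSE]
  prods <- apply(sub, 2L, prod)
  best <- which.max(prods)           # earliest time on ties
  pairs <- utils::combn(members, 2L)
  tsum <- sum(vapply(seq_len(ncol(pairs)),
                     function(i) topo(pairs[1L, i], pairs[2L, i]),
                     numeric(1L)))
  list(members = sort(members), ac = ac, tc = ac[best],
       prob = unname(prods[best]), score = unname(prods[best]) * tsum,
       origin = "clique-core")
}

#' Filter cliques to active correlated cliques and score them
#'
#' A maximal clique is an active correlated clique when its members share
#' at least one common active time point.  Each surviving clique receives
#' a clique probability (the maximum over shared time points of the
#' product of member levels; earliest time wins ties), an assigned time
#' point `tc`, and a clique score (probability times the sum of topology
#' scores over all clique edges).
#'
#' @param dppn A `dppn`.
#' @param cliques List of member-ID vectors (from
#'   [enumerate_maximal_cliques()]).
#' @return List of records with elements `members`, `ac`, `tc`, `prob`,
#'   `score`, `origin`.
#' @export
active_correlated_cliques <- function(dppn, cliques) {
  topo <- .topo_scorer(dppn)
  recs <- lapply(cliques, function(cl) .acc_record(dppn, cl, topo))
  recs[!vapply(recs, is.null, logical(1L))]
}

#' Score of an active correlated clique
#'
#' @param dppn A `dppn`.
#' @param members Character vector of clique member IDs (must induce a
#'   complete subgraph sharing a common active time point).
#' @return The clique score (probability at the best shared time point
#'   times the summed topology scores of the clique's edges).
#' @export
clique_score <- function(dppn, members) {
  rec <- .acc_record(dppn, members, .topo_scorer(dppn))
  if (is.null(rec))
    stop("clique has no common active time point")
  rec$score
}

# deterministic ranking: score desc, size desc, lexicographic member key
.rank_order <- function(recs) {
  keys <- vapply(recs, function(r) paste(r$members, collapse = "|"),
                 character(1L))
  order(-vapply(recs, `[[`, numeric(1L), "score"), -lengths(
    lapply(recs, `[[`, "members")), keys)
}

#' Select complex cores from scored cliques
#'
#' Phase A: greedy selection of mutually non-overlapping clique-cores.
#' The top-scoring candidate is moved to the core set; every remaining
#' candidate B overlapping it by `|A∩B|/|B| >= overlap_thresh` is removed,
#' while partially overlapping candidates are pruned of A's members,
#' re-scored, and kept if at least `min_clique_size` members remain.
#' Phase B: every DPPN edge not inside any selected clique-core whose
#' maximum weight over its active-time set strictly exceeds `core_thresh`
#' becomes a 2-member edge-core assigned to the argmax time (earliest on
#' ties).
#'
#' @param dppn A `dppn`.
#' @param accs Scored cliques from [active_correlated_cliques()].
#' @param config A [detector_config()].
#' @return Ordered list of core records (`members`, `tc`, `score`,
#'   `origin` = `"clique-core"` or `"edge-core"`).
#' @export
select_cores <- function(dppn, accs, config = detector_config()) {
  topo <- .topo_scorer(dppn)
  cand <- accs
  cores <- list()
  while (length(cand)) {
    cand <- cand[.rank_order(cand)]
    top <- cand[[1L]]
    cand <- cand[-1L]
    cores[[length(cores) + 1L]] <- top
    if (!length(cand)) break
    kept <- list()
    seen <- vapply(cores, function(r) paste(r$members, collapse = "|"),
                   character(1L))
    for (b in cand) {
      ov <- length(intersect(top$members, b$members)) / length(b$members)
      if (ov >= config$overlap_thresh) next
      if (ov > 0) {
        rest <- setdiff(b$members, top$members)
        if (length(rest) < config$min_clique_size) next
        b <- .acc_record(dppn, rest, topo)   # Ac only grows: non-NULL
      }
      key <- paste(b$members, collapse = "|")
      if (key %in% seen) next
      dupe <- vapply(kept, function(r)
        identical(r$members, b$members), logical(1L))
      if (any(dupe)) {
        i <- which(dupe)[1L]
        if (b$score > kept[[i]]$score) kept[[i]] <- b
      } else {
        kept[[length(kept) + 1L]] <- b
      }
    }
    cand <- kept
  }
  # phase B: high-weight edges outside every selected clique-core
  core_keys <- lapply(cores, `[[`, "members")
  for (i in seq_len(nrow(dppn$edges))) {
    a <- unname(dppn$edges[i, 1L]); b <- unname(dppn$edges[i, 2L])
    inside <- any(vapply(core_keys,
                         function(m) a %in% m && b %in% m, logical(1L)))
    if (inside) next
    fe <- dppn$fe[[i]]
    w <- dppn$prob[a, fe] * dppn$prob[b, fe] * topo(a, b)
    j <- which.max(w)                 # earliest time on ties
    if (w[j] > config$core_thresh)
      cores[[length(cores) + 1L]] <-
        list(members = sort(c(a, b)), ac = fe, tc = fe[j],
             prob = unname(dppn$prob[a, fe[j]] * dppn$prob[b, fe[j]]),
             score = unname(w[j]), origin = "edge-core")
  }
  cores
}

#' Attachment score of a candidate protein against a core
#'
#' Mean over core members of the time-`tc` edge weight between the member
#' and the candidate; absent edges contribute 0.
#'
#' @param dppn A `dppn`.
#' @param core_members Character vector of core member IDs.
#' @param tc The core's assigned time point.
#' @param candidate Protein ID not in the core.
#' @return Nonnegative scalar.
#' @export
attach_score <- function(dppn, core_members, tc, candidate) {
  if (candidate %in% core_members)
    stop("candidate is already a core member")
  pc <- dppn$prob[candidate, tc]
  if (pc == 0) return(0)
  topo <- .topo_scorer(dppn)
  nb <- intersect(core_members, dppn$adj[[candidate]])
  if (!length(nb)) return(0)
  w <- vapply(nb, function(m) {
    pm <- dppn$prob[m, tc]
    if (pm == 0) 0 else topo(m, candidate) * pm * pc
  }, numeric(1L))
  sum(w) / length(core_members)
}

#' Expand cores into predicted complexes
#'
#' Single-pass attachment: for each core, every DPPN neighbour of a core
#' member that is active at the core's time point and whose attachment
#' score strictly exceeds `extend_thresh` is added.  Attachments are
#' evaluated against the frozen core, and a protein may attach to several
#' cores.  Complexes with identical member sets are deduplicated keeping
#' the higher-scoring core.
#'
#' @param dppn A `dppn`.
#' @param cores Cores from [select_cores()].
#' @param config A [detector_config()].
#' @return List of predicted-complex records (`members`, `core_members`,
#'   `attachments`, `tc`, `score`, `origin`), sorted by descending score.
#' @export
expand_cores <- function(dppn, cores, config = detector_config()) {
  topo <- .topo_scorer(dppn)
  out <- lapply(cores, function(core) {
    nbrs <- setdiff(sort(unique(unlist(dppn$adj[core$members],
                                       use.names = FALSE))),
                    core$members)
    nbrs <- nbrs[dppn$prob[nbrs, core$tc] > 0]
    att <- character(0L)
    for (v in nbrs) {
      pc <- dppn$prob[v, core$tc]
      nb <- intersect(core$members, dppn$adj[[v]])
      s <- sum(vapply(nb, function(m) {
        pm <- dppn$prob[m, core$tc]
        if (pm == 0) 0 else topo(m, v) * pm * pc
      }, numeric(1L))) / length(core$members)
      if (s > config$extend_thresh) att <- c(att, v)
    }
    list(members = sort(c(core$members, att)),
         core_members = core$members, attachments = sort(att),
         tc = core$tc, score = core$score, origin = core$origin)
  })
  # deduplicate identical member sets, keeping the higher-scoring core
  if (length(out) > 1L) {
    out <- out[.rank_order(out)]
    keys <- vapply(out, function(r) paste(r$members, collapse = "|"),
                   character(1L))
    out <- out[!duplicated(keys)]
  }
  out
}

#' Identify protein complexes on a DPPN
#'
#' Deterministic composition of the two-phase pipeline: maximal-clique
#' enumeration, active-correlated-clique filtering and scoring, greedy
#' core selection plus high-weight edge-cores, and single-pass attachment
#' expansion.
#'
#' @param dppn A `dppn`.
#' @param config A [detector_config()].
#' @return List of predicted complexes sorted by descending core score;
#'   each has `members`, `core_members`, `attachments`, `tc`, `score`,
#'   `origin`.
#' @export
identify_complexes <- function(dppn, config = detector_config()) {
  if (length(dppn$vertices) == 0L) return(list())
  cliques <- enumerate_maximal_cliques(dppn, config$min_clique_size)
  accs <- active_correlated_cliques(dppn, cliques)
  cores <- select_cores(dppn, accs, config)
  expand_cores(dppn, cores, config)
}

#' Write predicted complexes as TSV and JSON
#'
#' TSV columns: `complex_id`, `tc`, `score`, then tab-separated member
#' IDs.  The JSON dump additionally splits members into core and
#' attachments.
#'
#' @param complexes Output of [identify_complexes()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Invisibly, the two paths written.
#' @export
write_complexes <- function(complexes, prefix) {
  tsv <- paste0(prefix, ".tsv")
  lines <- vapply(seq_along(complexes), function(i) {
    r <- complexes[[i]]
    paste(c(sprintf("C%04d", i), paste0("T", r$tc),
            sprintf("%.6g", r$score), r$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, tsv)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(lapply(seq_along(complexes), function(i) {
    r <- complexes[[i]]
    list(complex_id = sprintf("C%04d", i), tc = r$tc, score = r$score,
         origin = r$origin, core = r$core_members,
         attachments = r$attachments, members = r$members)
  }), js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
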