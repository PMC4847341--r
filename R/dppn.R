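#' Read a static PPI network from a two-column edge list
#'
#' Tab-separated file, two protein identifiers per line (extra columns are
#' ignored).  Identifiers are uppercased; self-loops are dropped and
#' duplicate pairs (in either orientation) collapsed, with counts reported
#' via `message()`.
#'
#' @param path Path to the edge-list TSV.
#' @return A `ppi_network`: list with `vertices` (character) and `edges`
#'   (two-column character matrix, `from < to` lexicographically).
#' @export
read_ppi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("PPI edge-list line ", bad[1L], " has fewer than 2 columns")
  a <- toupper(vapply(fields, `[[`, character(1L), 1L))
  b <- toupper(vapply(fields, `[[`, character(1L), 2L))
  self <- a == b
  if (any(self))
    message("read_ppi: dropped ", sum(self), " self-loop(s)")
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  key <- paste(a2, b2, sep = "\t")
  dup <- duplicated(key)
  if (any(dup))
    message("read_ppi: collapsed ", sum(dup), " duplicate edge(s)")
  edges <- cbind(from = a2[!dup], to = b2[!dup])
  vertices <- sort(unique(c(edges)))
  message("read_ppi: ", length(vertices), " proteins, ",
          nrow(edges), " interactions")
  structure(list(vertices = vertices, edges = edges),
            class = "ppi_network")
}

#' Construct a static PPI network from vertices and edges in memory
#'
#' @param edges Two-column character matrix or data frame of protein pairs.
#' @return A `ppi_network` (self-loops and duplicates removed silently).
#' @export
ppi_network <- function(edges) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  edges <- toupper(edges)
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  keep <- !duplicated(paste(a, b, sep = "\t"))
  edges <- cbind(from = a[keep], to = b[keep])
  structure(list(vertices = sort(unique(c(edges))), edges = edges),
            class = "ppi_network")
}

#' Build the dynamic probabilistic protein network
#'
#' Integrates a static PPI network with an activity table.  A vertex is
#' retained only if it has at least one active time point; an edge is
#' retained only if its active-time set -- the intersection of the
#' endpoints' active sets -- is nonempty.  Vertices carry per-time-point
#' probability levels; edges carry active-time sets.
#'
#' @param network A `ppi_network`.
#' @param activity An `activity_table` (rows indexed by protein ID).
#' @return A `dppn` object: list with `vertices`, `n_timepoints`, `prob`
#'   (vertex x time matrix of levels), `edges` (character matrix), `fe`
#'   (list of integer active-time sets per edge) and `adj` (named neighbour
#'   list on the pruned graph).
#' @export
build_dppn <- function(network, activity) {
  m <- unclass(activity)
  n_tp <- ncol(m)
  act <- rownames(m)[rowSums(m > 0) > 0L]
  keep_v <- intersect(network$vertices, act)
  dropped <- length(network$vertices) - length(keep_v)
  if (dropped > 0L)
    message("build_dppn: dropped ", dropped,
            " vertex(es) without activity data or with empty active sets")
  e <- network$edges
  e <- e[e[, 1L] %in% keep_v & e[, 2L] %in% keep_v, , drop = FALSE]
  if (length(keep_v)) {
    prob <- m[keep_v, , drop = FALSE]
  } else {
    prob <- matrix(0, 0L, n_tp)
  }
  fe <- vector("list", nrow(e))
  keep_e <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    s <- which(prob[e[i, 1L], ] > 0 & prob[e[i, 2L], ] > 0)
    fe[[i]] <- unname(s)
    keep_e[i] <- length(s) > 0L
  }
  if (any(!keep_e))
    message("build_dppn: dropped ", sum(!keep_e),
            " edge(s) with empty active-time sets")
  e <- e[keep_e, , drop = FALSE]
  fe <- fe[keep_e]
  # vertices that kept no edge stay in the DPPN (isolated but active)
  vertices <- sort(keep_v)
  prob <- prob[vertices, , drop = FALSE]
  if (nrow(e) == 0L && length(vertices) == 0L)
    message("build_dppn: resulting network is empty")
  adj <- .adjacency(vertices, e)
  structure(list(vertices = vertices, n_timepoints = n_tp, prob = prob,
                 edges = e, fe = fe, adj = adj),
            class = "dppn")
}

.adjacency <- function(vertices, edges) {
  adj <- lapply(stats::setNames(vector("list", length(vertices)), vertices),
                function(x) character(0L))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, sort)
}

#' @export
print.dppn <- function(x, ...) {
  cat("DPPN:", length(x$vertices), "vertices,", nrow(x$edges),
      "edges,", x$n_timepoints, "time points\n")
  invisible(x)
}

#' Average vertex degree of a DPPN
#'
#' @param dppn A `dppn`.
#' @return Mean degree over the (pruned) DPPN vertices.
#' @export
average_degree <- function(dppn) {
  if (length(dppn$vertices) == 0L)
    stop("average degree undefined on an empty DPPN")
  2 * nrow(dppn$edges) / length(dppn$vertices)
}

#' Topology score of a DPPN edge
#'
#' For edge (v_i, v_j) with neighbourhoods N_i, N_j on the pruned DPPN:
#' \deqn{(|N_i \cap N_j| + 1) /
#'       (\max\{Avg(G), |N_i|\} + \max\{Avg(G), |N_j|\})}
#' where Avg(G) is the DPPN's average degree.  Shared neighbours raise the
#' score; the max() terms damp the contribution of near-isolated vertices.
#'
#' @param dppn A `dppn`.
#' @param vi,vj Endpoint protein IDs.
#' @return Strictly positive scalar.
#' @export
topology_score <- function(dppn, vi, vj) {
  avg <- average_degree(dppn)
  ni <- dppn$adj[[vi]]
  nj <- dppn$adj[[vj]]
  common <- length(intersect(ni, nj))
  (common + 1) / (max(avg, length(ni)) + max(avg, length(nj)))
}

#' Time-indexed weight of a DPPN edge
#'
#' The topology score multiplied by both endpoints' active probability
#' levels at time `k`.  If `k` is not in the edge's active-time set the
#' weight is 0 (one endpoint's level is 0).
#'
#' @param dppn A `dppn`.
#' @param vi,vj Endpoint protein IDs.
#' @param k Time point (1-based integer).
#' @return Nonnegative scalar.
#' @export
edge_weight <- function(dppn, vi, vj, k) {
  pi_ <- unname(dppn$prob[vi, k])
  pj <- unname(dppn$prob[vj, k])
  if (pi_ == 0 || pj == 0) return(0)
  topology_score(dppn, vi, vj) * pi_ * pj
}

#' Serialize a DPPN to JSON
#'
#' Writes vertices (with active-time sets and per-time levels), edges
#' (with active-time sets) and the number of time points.  The file can be
#' read back with [read_dppn()] to an identical object.
#'
#' @param dppn A `dppn`.
#' @param path Output path.
#' @export
write_dppn <- function(dppn, path) {
  obj <- list(
    n_timepoints = dppn$n_timepoints,
    vertices = lapply(dppn$vertices, function(v) {
      a <- unname(which(dppn$prob[v, ] > 0))
      list(id = v, active = as.integer(a),
           levels = unname(dppn$prob[v, a]))
    }),
    edges = lapply(seq_len(nrow(dppn$edges)), function(i) {
      list(from = dppn$edges[i, 1L], to = dppn$edges[i, 2L],
           fe = as.integer(dppn$fe[[i]]))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a DPPN serialized with [write_dppn()]
#'
#' @param path Path to the JSON dump.
#' @return A `dppn` object.
#' @export
read_dppn <- function(path) {
  obj <- jsonlite::read_json(path)
  n_tp <- obj$n_timepoints
  ids <- vapply(obj$vertices, `[[`, character(1L), "id")
  prob <- matrix(0, length(ids), n_tp, dimnames = list(ids, NULL))
  for (v in obj$vertices) {
    a <- unlist(v$active)
    prob[v$id, a] <- unlist(v$levels)
  }
  colnames(prob) <- paste0("T", seq_len(n_tp))
  if (length(obj$edges)) {
    e <- cbind(from = vapply(obj$edges, `[[`, character(1L), "from"),
               to = vapply(obj$edges, `[[`, character(1L), "to"))
    fe <- lapply(obj$edges, function(x) as.integer(unlist(x$fe)))
  } else {
    e <- matrix(character(0L), 0L, 2L,
                dimnames = list(NULL, c("from", "to")))
    fe <- list()
  }
  vertices <- sort(ids)
  prob <- prob[vertices, , drop = FALSE]
  structure(list(vertices = vertices, n_timepoints = n_tp, prob = prob,
                 edges = e, fe = fe, adj = .adjacency(vertices, e)),
            class = "dppn")
}

#' Count active proteins per time point
#'
#' A protein counts as active at a time point when its probability level
#' there is at least 0.68 (the one-sigma tier).
#'
#' @param x A `dppn` or an `activity_table`.
#' @return Data frame with columns `time_point` (`T1..Tn`) and
#'   `n_active`.
#' @export
active_protein_distribution <- function(x) {
  m <- if (inherits(x, "dppn")) x$prob else unclass(x)
  counts <- colSums(m >= ACTIVITY_LEVELS[["P3"]])
  data.frame(time_point = paste0("T", seq_len(ncol(m))),
             n_active = as.integer(counts), row.names = NULL)
}
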