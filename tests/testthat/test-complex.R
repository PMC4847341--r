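test_that("maximal clique enumeration handles canonical graphs", {
  ids <- c("A", "B", "C", "D")
  k4 <- uniform_dppn(t(utils::combn(ids, 2)))
  expect_identical(clique_keys(enumerate_maximal_cliques(k4)), "A|B|C|D")

  # two triangles sharing one vertex
  bowtie <- uniform_dppn(rbind(c("A", "B"), c("A", "C"), c("B", "C"),
                               c("C", "D"), c("C", "E"), c("D", "E")))
  expect_identical(clique_keys(enumerate_maximal_cliques(bowtie)),
                   c("A|B|C", "C|D|E"))

  # triangle-free path graph
  p4 <- uniform_dppn(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  expect_identical(enumerate_maximal_cliques(p4), list())
})

test_that("clique enumeration agrees with exhaustive subset search", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    adj <- random_adjacency(n, runif(1, 0.3, 0.8))
    edges <- adjacency_to_edges(adj)
    if (nrow(edges) == 0) next
    dp <- uniform_dppn(edges)
    got <- clique_keys(enumerate_maximal_cliques(dp))
    # oracle works on the full adjacency (isolated vertices irrelevant)
    want <- clique_keys(brute_force_cliques(adj))
    expect_identical(got, want)
  }
})

test_that("active correlated cliques require a common active time", {
  # triangle sharing T2, all at 0.99
  lev <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), NULL))
  lev[, 2] <- 0.99
  dp <- make_dppn(rbind(c("A", "B"), c("A", "C"), c("B", "C")), lev)
  accs <- active_correlated_cliques(dp, enumerate_maximal_cliques(dp))
  expect_length(accs, 1)
  expect_equal(accs[[1]]$prob, 0.99^3)
  expect_identical(accs[[1]]$tc, 2L)
  # score = prob * sum of the three K3 topology scores (0.5 each)
  expect_equal(accs[[1]]$score, 0.99^3 * 1.5)
  expect_equal(clique_score(dp, c("A", "B", "C")), 0.970299 * 1.5)

  # pairwise-nonempty but jointly empty active sets -> excluded
  lev2 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), NULL))
  lev2["A", c(1, 2)] <- 0.99
  lev2["B", c(2, 3)] <- 0.99
  lev2["C", c(1, 3)] <- 0.99
  dp2 <- make_dppn(rbind(c("A", "B"), c("A", "C"), c("B", "C")), lev2)
  expect_identical(nrow(dp2$edges), 3L)     # every edge survives
  expect_length(active_correlated_cliques(
    dp2, enumerate_maximal_cliques(dp2)), 0)
  expect_error(clique_score(dp2, c("A", "B", "C")), "common active")
})

test_that("clique probability picks the best shared time point", {
  # members share {T1, T5}: 0.68*0.99*0.99 at T1 vs 0.99^3 at T5
  lev <- matrix(0, 3, 5, dimnames = list(c("A", "B", "C"), NULL))
  lev["A", c(1, 5)] <- c(0.68, 0.99)
  lev["B", c(1, 5)] <- 0.99
  lev["C", c(1, 5)] <- 0.99
  dp <- make_dppn(rbind(c("A", "B"), c("A", "C"), c("B", "C")), lev)
  acc <- active_correlated_cliques(dp, enumerate_maximal_cliques(dp))[[1]]
  expect_identical(acc$tc, 5L)
  expect_equal(acc$prob, 0.99^3)
  expect_identical(acc$ac, c(1L, 5L))
})

test_that("greedy core selection removes or prunes overlapping cliques", {
  # two disjoint triangles: both survive
  lev <- matrix(0.99, 6, 2,
                dimnames = list(c("A", "B", "C", "D", "E", "F"), NULL))
  dp <- make_dppn(rbind(c("A", "B"), c("A", "C"), c("B", "C"),
                        c("D", "E"), c("D", "F"), c("E", "F")), lev)
  accs <- active_correlated_cliques(dp, enumerate_maximal_cliques(dp))
  cores <- select_cores(dp, accs, detector_config(core_thresh = 1))
  expect_identical(clique_keys(lapply(cores, `[[`, "members")),
                   c("A|B|C", "D|E|F"))

  # two K4s sharing 3 of 4 vertices (overlap 3/4 >= 0.5): the
  # higher-scoring one survives alone
  ids <- c("A", "B", "C", "D", "E")
  edges <- rbind(t(utils::combn(c("A", "B", "C", "D"), 2)),
                 cbind("E", c("A", "B", "C")))
  lev2 <- matrix(0, 5, 2, dimnames = list(ids, NULL))
  lev2[c("A", "B", "C", "D"), 1] <- 0.99
  lev2["E", 1] <- 0.68
  lev2[, 2] <- 0                           # single shared time
  dp2 <- make_dppn(edges, lev2)
  accs2 <- active_correlated_cliques(dp2, enumerate_maximal_cliques(dp2))
  expect_length(accs2, 2)
  cores2 <- select_cores(dp2, accs2, detector_config(core_thresh = 1))
  expect_length(cores2, 1)
  expect_identical(cores2[[1]]$members, c("A", "B", "C", "D"))

  # partial overlap below overlap_thresh: pruned candidate survives when
  # enough members remain
  accs3 <- list(
    list(members = c("A", "B", "C", "D"), ac = 1L, tc = 1L,
         prob = 0.9, score = 10, origin = "clique-core"),
    list(members = c("D", "E", "F", "G", "H", "I", "J", "K", "L"),
         ac = 1L, tc = 1L, prob = 0.9, score = 5,
         origin = "clique-core"))
  # fake a DPPN where all listed proteins form one clique at T1 so the
  # pruned remainder can be re-scored
  ids3 <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L")
  lev3 <- matrix(0.99, 12, 1, dimnames = list(ids3, NULL))
  dp3 <- make_dppn(t(utils::combn(ids3, 2)), lev3)
  cores3 <- select_cores(dp3, accs3, detector_config(core_thresh = 1))
  keys <- clique_keys(lapply(cores3, `[[`, "members"))
  expect_true("A|B|C|D" %in% keys)
  expect_true("E|F|G|H|I|J|K|L" %in% keys)  # D removed, 8 remain
})

test_that("high-weight edges outside clique-cores become edge-cores", {
  # isolated edge A-B at 0.99/0.99: topology 0.5 on its own component,
  # but avg degree over the whole DPPN determines the exact weight
  lev <- matrix(0, 5, 2, dimnames = list(c("A", "B", "C", "D", "E"), NULL))
  lev[c("A", "B"), 1] <- 0.99
  lev[c("C", "D", "E"), 2] <- 0.68
  edges <- rbind(c("A", "B"), c("C", "D"), c("C", "E"), c("D", "E"))
  dp <- make_dppn(edges, lev)
  accs <- active_correlated_cliques(dp, enumerate_maximal_cliques(dp))
  w_ab <- edge_weight(dp, "A", "B", 1)
  expect_gt(w_ab, 0.09)
  cores <- select_cores(dp, accs, detector_config(core_thresh = 0.09))
  ec <- Filter(function(r) r$origin == "edge-core", cores)
  expect_length(ec, 1)
  expect_identical(ec[[1]]$members, c("A", "B"))
  expect_identical(ec[[1]]$tc, 1L)
  expect_equal(ec[[1]]$score, w_ab)

  # same edge with a prohibitive threshold: no edge-core
  cores_hi <- select_cores(dp, accs,
                           detector_config(core_thresh = round(w_ab, 6) +
                                             0.01))
  expect_length(Filter(function(r) r$origin == "edge-core", cores_hi), 0)

  # edges inside the selected triangle core never duplicate as edge-cores
  expect_false(any(vapply(cores, function(r)
    r$origin == "edge-core" &&
      all(r$members %in% c("C", "D", "E")), logical(1))))
})

test_that("attach_score averages time-Tc edge weights over the core", {
  # core {A, B} at T1; candidate X adjacent to both
  lev <- matrix(0, 3, 1, dimnames = list(c("A", "B", "X"), NULL))
  lev[, 1] <- c(0.99, 0.95, 0.68)
  dp <- make_dppn(rbind(c("A", "B"), c("A", "X"), c("B", "X")), lev)
  manual <- (edge_weight(dp, "A", "X", 1) + edge_weight(dp, "B", "X", 1)) / 2
  expect_equal(attach_score(dp, c("A", "B"), 1L, "X"), manual)

  # candidate adjacent to no core member scores 0
  lev2 <- matrix(0.99, 4, 1,
                 dimnames = list(c("A", "B", "X", "Y"), NULL))
  dp2 <- make_dppn(rbind(c("A", "B"), c("X", "Y")), lev2)
  expect_equal(attach_score(dp2, c("A", "B"), 1L, "X"), 0)

  # candidate inactive at Tc scores 0
  lev3 <- matrix(c(0.99, 0.99, 0, 0, 0, 0.68), 3, 2,
                 dimnames = list(c("A", "B", "X"), NULL))
  dp3 <- make_dppn(rbind(c("A", "B"), c("A", "X"), c("B", "X")), lev3)
  expect_equal(attach_score(dp3, c("A", "B"), 1L, "X"), 0)
  expect_error(attach_score(dp3, c("A", "B"), 1L, "A"), "already")
})

test_that("expansion adds qualified neighbours and respects thresholds", {
  # planted triangle core + a satellite S adjacent to all three members
  ids <- c("A", "B", "C", "S")
  lev <- matrix(0, 4, 1, dimnames = list(ids, NULL))
  lev[, 1] <- 0.99
  edges <- rbind(t(utils::combn(c("A", "B", "C"), 2)),
                 cbind("S", c("A", "B", "C")))
  dp <- make_dppn(edges, lev)
  accs <- active_correlated_cliques(dp, enumerate_maximal_cliques(dp))
  # the maximal clique here is the K4 itself; force a triangle-only core
  core <- list(members = c("A", "B", "C"), ac = 1L, tc = 1L,
               prob = 0.99^3, score = 1, origin = "clique-core")
  s_attach <- attach_score(dp, core$members, 1L, "S")
  expect_gt(s_attach, 0.05)
  cx <- expand_cores(dp, list(core), detector_config(extend_thresh = 0.05))
  expect_identical(cx[[1]]$members, c("A", "B", "C", "S"))
  expect_identical(cx[[1]]$attachments, "S")

  # extend_thresh = 1: nothing can attach (levels <= 0.99, topology < 1)
  cx1 <- expand_cores(dp, list(core), detector_config(extend_thresh = 1))
  expect_identical(cx1[[1]]$members, c("A", "B", "C"))

  # extend_thresh = 0: every active neighbour with a positive connection
  cx0 <- expand_cores(dp, list(core), detector_config(extend_thresh = 0))
  expect_identical(cx0[[1]]$members, c("A", "B", "C", "S"))
})

test_that("identify_complexes composes the phases deterministically", {
  expect_identical(identify_complexes(
    make_dppn(rbind(c("A", "B")), matrix(numeric(0), 0, 3))), list())

  # planted 8-clique sharing T2 in a sparse background
  set.seed(41)
  ids <- sprintf("P%02d", 1:20)
  members <- ids[1:8]
  edges <- t(utils::combn(members, 2))
  extra <- rbind(c("P09", "P10"), c("P10", "P11"), c("P12", "P13"),
                 c("P09", "P01"))
  lev <- matrix(0, 20, 4, dimnames = list(ids, NULL))
  lev[members, 2] <- 0.99
  lev[c("P09", "P10", "P11", "P12", "P13"), 4] <- 0.68
  dp <- make_dppn(rbind(edges, extra), lev)
  cx <- identify_complexes(dp)
  expect_identical(cx[[1]]$members, sort(members))
  expect_identical(cx[[1]]$tc, 2L)

  # overlapping planted complexes may both be reported: the attachment
  # phase permits overlapping outputs
  lev2 <- matrix(0.99, 7, 1,
                 dimnames = list(c("A", "B", "C", "D", "E", "F", "G"),
                                 NULL))
  tri1 <- t(utils::combn(c("A", "B", "C", "D"), 2))
  tri2 <- t(utils::combn(c("D", "E", "F", "G"), 2))
  dp2 <- make_dppn(rbind(tri1, tri2), lev2)
  # extend_thresh 0.1 blocks the weak cross-attachments (hand-computed
  # attach scores: 0.078 for E against {A,B,C,D}, 0.312 for D against
  # {E,F,G}) so the overlap structure stays visible
  cx2 <- identify_complexes(dp2, detector_config(core_thresh = 1,
                                                 extend_thresh = 0.1))
  mk <- clique_keys(lapply(cx2, `[[`, "members"))
  expect_identical(mk, c("A|B|C|D", "D|E|F|G"))
  shared <- intersect(cx2[[1]]$members, cx2[[2]]$members)
  expect_identical(shared, "D")
})

test_that("every attachment re-verifies its threshold independently", {
  set.seed(47)
  ids <- sprintf("P%02d", 1:25)
  lev <- matrix(sample(c(0, 0.68, 0.95, 0.99), 25 * 4, replace = TRUE,
                       prob = c(0.4, 0.2, 0.2, 0.2)),
                25, 4, dimnames = list(ids, NULL))
  adj <- random_adjacency(25, 0.2)
  dimnames(adj) <- list(ids, ids)
  dp <- make_dppn(adjacency_to_edges(adj), lev)
  cfg <- detector_config()
  cx <- identify_complexes(dp, cfg)
  for (r in cx) {
    for (v in r$attachments)
      expect_gt(attach_score(dp, r$core_members, r$tc, v),
                cfg$extend_thresh)
    expect_identical(r$members, sort(union(r$core_members,
                                           r$attachments)))
  }
})

test_that("the pipeline is byte-identical across repeated runs", {
  set.seed(53)
  ids <- sprintf("P%02d", 1:20)
  lev <- matrix(sample(c(0, 0.68, 0.95, 0.99), 20 * 5, replace = TRUE),
                20, 5, dimnames = list(ids, NULL))
  adj <- random_adjacency(20, 0.25)
  dimnames(adj) <- list(ids, ids)
  dp <- make_dppn(adjacency_to_edges(adj), lev)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_complexes(identify_complexes(dp), f1)
  write_complexes(identify_complexes(dp), f2)
  expect_identical(readLines(paste0(f1, ".tsv")),
                   readLines(paste0(f2, ".tsv")))
  expect_identical(readLines(paste0(f1, ".json")),
                   readLines(paste0(f2, ".json")))
})
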