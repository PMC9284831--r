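# Interaction tables, profiles, distances, clustering, annotation.

test_that("read_interactions filters by cutoff and collapses duplicates", {
  dir <- withr::local_tempdir()
  cp <- file.path(dir, "cp.tsv"); pp <- file.path(dir, "pp.tsv")
  writeLines(c("chemical\tprotein\tcombined_score",
               "CHEM1\tPROT1\t900", "CHEM1\tPROT2\t300",
               "CHEM2\tPROT1\t500", "CHEM2\tPROT1\t800"), cp)
  writeLines(c("protein1\tprotein2\tcombined_score",
               "PROT2\tPROT1\t600", "PROT1\tPROT2\t450"), pp)
  g <- read_interactions(cp, pp, quality_cutoff = 400L)
  expect_equal(nrow(g$chem_protein), 2L)               # 300 filtered, dup collapsed
  expect_equal(g$chem_protein$combined_score[
    g$chem_protein$chemical == "CHEM2"], 800L)
  expect_equal(nrow(g$protein_protein), 1L)            # undirected dup collapsed
  expect_equal(g$protein_protein$combined_score, 600L)
  expect_equal(g$protein_protein$protein1, "PROT1")    # normalized ordering
})

test_that("read_interactions rejects malformed tables", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tsv"); pp <- file.path(dir, "pp.tsv")
  writeLines(c("chem\tprot\tscore", "a\tb\t5"), bad)
  writeLines(c("protein1\tprotein2\tcombined_score", "a\tb\t5"), pp)
  expect_error(read_interactions(bad, pp), "must have columns")
  writeLines(c("chemical\tprotein\tcombined_score", "a\tb\thigh"), bad)
  expect_error(read_interactions(bad, pp), "non-integer")
})

test_that("profiles match the hand-computed propagation example", {
  cp <- data.frame(chemical = "CA", protein = c("P1", "P2"),
                   combined_score = c(800L, 600L))
  pp <- data.frame(protein1 = c("P1", "P2"), protein2 = c("P2", "P3"),
                   combined_score = c(500L, 1000L))
  g <- interaction_graph(cp, pp)
  prof <- build_profiles(g, propagation_weight = 0.5)[["CA"]]
  # direct: P1 0.8, P2 0.6; propagation: P2 += .5*.8*.5 = .2,
  # P1 += .5*.6*.5 = .15, P3 += .5*.6*1 = .3
  raw <- c(P1 = 0.95, P2 = 0.8, P3 = 0.3)
  expect_equal(prof[names(raw)], raw / sqrt(sum(raw^2)), tolerance = 1e-12)

  # propagation_weight 0: unit vector on the single bound protein
  g2 <- interaction_graph(data.frame(chemical = "CB", protein = "P9",
                                     combined_score = 1000L),
                          pp[0, ])
  expect_equal(unname(build_profiles(g2, 0)[["CB"]]), 1)
})

test_that("identical edge sets give identical profiles", {
  cp <- data.frame(chemical = rep(c("X", "Y"), each = 2),
                   protein = rep(c("P1", "P2"), 2),
                   combined_score = rep(c(900L, 400L), 2))
  g <- interaction_graph(cp, data.frame(protein1 = character(),
                                        protein2 = character(),
                                        combined_score = integer()))
  prof <- build_profiles(g, 0.5)
  expect_identical(unname(prof[["X"]]), unname(prof[["Y"]]))
})

test_that("distance matrix equals the brute-force pairwise loop", {
  prof <- build_profiles(fx_net$graph, 0.5)
  sub <- structure(prof[1:10], class = "chem_profiles")
  D <- compute_distance_matrix(sub)
  ids <- rownames(D)
  prots <- sort(unique(unlist(lapply(sub, names))))
  dense <- function(p) { v <- setNames(numeric(length(prots)), prots)
                         v[names(p)] <- p; v }
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    a <- dense(sub[[ids[i]]]); b <- dense(sub[[ids[j]]])
    expect_equal(D[i, j],
                 min(max(1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2)), 0), 1),
                 tolerance = 1e-10)
  }
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_error(compute_distance_matrix(structure(prof[1],
                                                 class = "chem_profiles")),
               "at least 2")
})

test_that("identical and disjoint profiles hit the distance extremes", {
  p <- structure(list(A = c(P1 = 1), B = c(P1 = 1), C = c(P2 = 1)),
                 class = "chem_profiles")
  D <- compute_distance_matrix(p)
  expect_equal(D["A", "B"], 0)
  expect_equal(D["A", "C"], 1)
})

test_that("threshold cuts produce the expected degenerate clusterings", {
  ids <- c("a", "b", "c", "d")
  D <- matrix(0.9, 4, 4, dimnames = list(ids, ids))
  D[1:2, 1:2] <- 0.001; D[3:4, 3:4] <- 0.001; diag(D) <- 0
  cl <- hierarchical_cluster(D, 0.005)
  expect_equal(length(cl$support), 2L)
  expect_equal(unname(cl$assignment[c("a", "b")]), c(1L, 1L))
  expect_equal(length(hierarchical_cluster(D, 0.95)$support), 1L)
  expect_equal(length(hierarchical_cluster(D, 0.0005)$support), 4L)
  expect_error(hierarchical_cluster(D, 0.5, "ward"), "unsupported linkage")
})

test_that("cluster ids are stable under input order", {
  prof <- build_profiles(fx_net$graph, 0.5)
  D <- compute_distance_matrix(prof)
  cl1 <- hierarchical_cluster(D, 0.5)
  perm <- sample(nrow(D))
  cl2 <- hierarchical_cluster(D[perm, perm], 0.5)
  expect_identical(cl1$assignment[sort(names(cl1$assignment))],
                   cl2$assignment[sort(names(cl2$assignment))])
})

test_that("support filter keeps strictly-greater clusters only", {
  assignment <- setNames(rep(1:3, c(150L, 99L, 101L)),
                         sprintf("c%03d", 1:350))
  cl <- structure(list(assignment = assignment,
                       support = table(assignment), threshold = 0.1),
                  class = "chem_clustering")
  f <- filter_by_support(cl, 100L)
  expect_setequal(as.integer(names(f$support)), c(1L, 3L))
  expect_length(f$discarded, 99L)
  # exactly-at-threshold cluster is discarded
  f2 <- filter_by_support(cl, 101L)
  expect_setequal(as.integer(names(f2$support)), 1L)
  # everything below: empty clustering, full discard list
  f3 <- filter_by_support(cl, 1000L)
  expect_length(f3$assignment, 0L)
  expect_length(f3$discarded, 350L)
})

test_that("annotation is the member-union and monotone in the cutoff", {
  prof <- build_profiles(fx_net$graph, 0.5)
  D <- compute_distance_matrix(prof)
  cl <- hierarchical_cluster(D, 0.5)
  q <- annotate_cluster(cl, fx_net$graph, 700L)
  l <- annotate_cluster(cl, fx_net$graph, 150L)
  cp <- fx_net$graph$chem_protein
  for (cid in names(q$proteins)) {
    members <- names(cl$assignment)[cl$assignment == as.integer(cid)]
    brute <- sort(unique(cp$protein[cp$chemical %in% members &
                                      cp$combined_score >= 700L]))
    expect_identical(q$proteins[[cid]], brute)
    expect_true(all(q$proteins[[cid]] %in% l$proteins[[cid]]))
  }
})

test_that("single-chemical annotation filters by score", {
  g <- interaction_graph(
    data.frame(chemical = "CX", protein = c("P1", "P2"),
               combined_score = c(900L, 300L)),
    data.frame(protein1 = character(), protein2 = character(),
               combined_score = integer()))
  cl <- structure(list(assignment = c(CX = 1L), support = table(1L)),
                  class = "chem_clustering")
  expect_identical(annotate_cluster(cl, g, 700L)$proteins[["1"]], "P1")
  expect_identical(annotate_cluster(cl, g, 150L)$proteins[["1"]],
                   c("P1", "P2"))
})

test_that("cluster distances come off the linkage tree", {
  ids <- c("a", "b", "c", "d")
  D <- matrix(0.8, 4, 4, dimnames = list(ids, ids))
  D[1:2, 1:2] <- 0.1; D[3:4, 3:4] <- 0.1; diag(D) <- 0
  cl <- hierarchical_cluster(D, 0.3)
  expect_equal(cluster_distance(cl, 1L, 1L), 0)
  expect_equal(cluster_distance(cl, 1L, 2L), 0.8)   # average-linkage merge height
  expect_equal(cluster_distance(cl, 1L, 2L), cluster_distance(cl, 2L, 1L))
  expect_error(cluster_distance(cl, 1L, 9L), "unknown cluster")
})

test_that("planted clusters are recovered across the threshold range", {
  prof <- build_profiles(fx_net$graph, 0.5)
  D <- compute_distance_matrix(prof)
  n_cl <- vapply(c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5),
                 function(th) length(hierarchical_cluster(D, th)$support),
                 numeric(1))
  expect_true(all(diff(n_cl) <= 0))       # monotone in threshold
  cl <- filter_by_support(hierarchical_cluster(D, 0.5), 5L)
  truth <- fx_net$truth$chemical[names(cl$assignment)]
  expect_gte(adjusted_rand_index(cl$assignment, truth), 0.9)
})
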