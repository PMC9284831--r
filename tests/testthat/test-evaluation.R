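# Splits, F1, randomization tests, subset selection, prediction report.

test_that("F1 matches hand-computed oracles", {
  expect_equal(f1_scores(c("a", "b"), c("a", "b"))$macro, 1)
  expect_equal(f1_scores(c("a", "b"), c("a", "b"))$micro, 1)
  # degenerate one-class predictor on balanced 2-class set of 10
  truth <- rep(c("a", "b"), each = 5)
  pred <- rep("a", 10)
  fs <- f1_scores(truth, pred)
  expect_equal(fs$macro, 1 / 3)
  expect_equal(unname(fs$per_class["a"]), 2 / 3)
  expect_equal(unname(fs$per_class["b"]), 0)
  expect_equal(f1_scores(c("a", "b"), c("b", "a"))$macro, 0)
  expect_error(f1_scores(c("a"), c("a", "b")), "length")
})

test_that("randomization test: exact enumeration and edge cases", {
  expect_equal(randomization_test(1:10 / 10, 1:10 / 10), 1)
  a <- seq(0.5, 0.95, by = 0.05); b <- a - 0.1
  expect_equal(randomization_test(a, b), 2 / 1024)
  # symmetric in direction
  expect_equal(randomization_test(b, a), 2 / 1024)
  expect_error(randomization_test(1:3, 1:4), "length")
  # Monte-Carlo branch is deterministic per seed and in (0, 1]
  set.seed(1); x <- rnorm(20); y <- rnorm(20)
  p1 <- randomization_test(x, y, n_permutations = 500L, seed = 3L)
  p2 <- randomization_test(x, y, n_permutations = 500L, seed = 3L)
  expect_identical(p1, p2)
  expect_gt(p1, 0); expect_lte(p1, 1)
})

test_that("CV splits partition the data with balanced folds", {
  ids <- sprintf("s%03d", 1:100)
  labels <- rep(c("x", "y"), each = 50)
  sp <- make_splits(ids, labels, holdout_fraction = 0.1, k_folds = 10L,
                    seed = 2L)
  expect_length(sp$holdout, 10L)
  expect_equal(sort(lengths(sp$folds)), rep(9L, 10))
  all_ids <- c(sp$holdout, unlist(sp$folds))
  expect_setequal(all_ids, ids)
  expect_false(anyDuplicated(all_ids) > 0)
  # stratification: holdout has 5 of each class (+-1)
  expect_lte(abs(sum(labels[match(sp$holdout, ids)] == "x") - 5), 1)
  # determinism
  expect_identical(sp, make_splits(ids, labels, 0.1, 10L, seed = 2L))
})

test_that("small classes fall back with a warning under stratification", {
  ids <- sprintf("s%02d", 1:30)
  labels <- c(rep("big", 27), rep("tiny", 3))
  expect_warning(make_splits(ids, labels, 0.1, 10L, seed = 1L),
                 "fewer members than folds")
})

test_that("80/10/10 split respects class proportions", {
  ids <- sprintf("s%03d", 1:100)
  labels <- rep(c("x", "y"), c(60, 40))
  sp <- make_tvt(ids, labels, seed = 4L)
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_length(sp$test, 10L)
  tx <- sum(labels[match(sp$test, ids)] == "x")
  expect_lte(abs(tx - 6), 1)
  expect_lte(abs(length(sp$train) - 80), 1)
})

test_that("cluster subset selection keeps near pairs and spreads", {
  ids <- sprintf("m%02d", 1:8)
  D <- matrix(0.9, 8, 8, dimnames = list(ids, ids))
  D[1:2, 1:2] <- 0.05; D[3:4, 3:4] <- 0.05       # two tight pairs
  D[5:8, 5:8] <- pmax(D[5:8, 5:8], 0.9)
  diag(D) <- 0
  cl <- hierarchical_cluster(D, 0.2)              # pairs merge, rest singletons
  sub <- select_cluster_subset(cl, 4L, seed = 1L)
  near_pair <- cl$assignment[c("m01", "m02")]
  expect_true(all(near_pair %in% sub))            # nearest pair fully included
  expect_length(sub, 4L)
  expect_identical(sub, select_cluster_subset(cl, 4L, seed = 1L))
  expect_identical(select_cluster_subset(cl, length(cl$support), seed = 1L),
                   sort(unique(cl$assignment)))
  expect_error(select_cluster_subset(cl, 99L), "fewer clusters")
})

test_that("architecture comparison reports folds, p-values and failures", {
  df <- fx_lib
  sp <- make_splits(df$id, df$cluster, holdout_fraction = 0.1, k_folds = 3L,
                    seed = 5L)
  configs <- list(
    dnn = desk_config("dnn", epochs = 12L, seed = 1L),
    dnn_same = desk_config("dnn", epochs = 12L, seed = 1L))
  rep <- evaluate_architectures(df, configs, sp, seed = 7L)
  expect_equal(dim(rep$fold_f1), c(3L, 2L))
  expect_true(all(!is.na(rep$fold_f1)))
  # identical configs -> identical scores -> p = 1
  expect_equal(unname(rep$p_values["dnn", "dnn_same"]), 1)
  expect_true(all(rep$summary$mean_macro_f1 >= 0 &
                  rep$summary$mean_macro_f1 <= 1))
})

test_that("strong model beats label-shuffled model with small p", {
  df <- fx_lib
  set.seed(42)
  df_shuf <- df
  df_shuf$cluster <- sample(df$cluster)
  # 6 folds: the exhaustive sign-flip lattice (2/64) can dip below 0.05
  sp <- make_splits(df$id, df$cluster, 0.1, 6L, seed = 6L)
  k <- length(sp$folds)
  f_good <- f_bad <- numeric(k)
  for (fi in seq_len(k)) {
    te_ids <- sp$folds[[fi]]
    tr_ids <- setdiff(unlist(sp$folds), te_ids)
    cfg <- desk_config("dnn", epochs = 12L, seed = fi)
    fit <- function(d) {
      enc <- encode_dataset(d$smiles[d$id %in% tr_ids],
                            d$cluster[d$id %in% tr_ids], "fingerprint")
      m <- train_classifier(enc, cfg)
      predict(m, encode_like(enc, df$smiles[df$id %in% te_ids]))
    }
    truth <- df$cluster[df$id %in% te_ids]
    f_good[fi] <- f1_scores(truth, fit(df))$macro
    f_bad[fi] <- f1_scores(truth, fit(df_shuf))$macro
  }
  expect_lt(randomization_test(f_good, f_bad), 0.05)
})

test_that("leakage guard: split by source id keeps variants together", {
  aug <- classwise_augment(fx_tiny, 1, seed = 2L)
  sp <- make_splits(fx_tiny$id, fx_tiny$cluster, 0.2, 4L, seed = 3L)
  test_sources <- sp$holdout
  train_rows <- aug[aug$source_id %in% setdiff(fx_tiny$id, test_sources), ]
  expect_length(intersect(train_rows$source_id, test_sources), 0L)
  # and augmented variants of held-out compounds are excluded from training
  expect_false(any(aug$source_id[aug$id %in% train_rows$id] %in% test_sources))
})

test_that("prediction report ranks clusters and annotates at two cutoffs", {
  prof <- build_profiles(fx_net$graph, 0.5)
  D <- compute_distance_matrix(prof)
  cl <- hierarchical_cluster(D, 0.5)
  lab <- data.frame(id = names(cl$assignment),
                    cluster = unname(cl$assignment))
  df <- merge(fx_lib[c("id", "smiles")], lab, by = "id")
  enc <- encode_dataset(df$smiles, df$cluster, "fingerprint")
  m <- train_classifier(enc, desk_config("dnn", epochs = 15L, seed = 3L))
  q <- annotate_cluster(cl, fx_net$graph, 700L)
  l <- annotate_cluster(cl, fx_net$graph, 400L)
  compounds <- c(known = df$smiles[1], ring = "c1ccccc1CO", bad = "C1CC")
  rep <- predict_and_annotate(m, compounds, cl, q, l, top_k = 3L)
  expect_false(rep$predictions$bad$ok)
  top <- rep$predictions$known$top
  expect_equal(nrow(top), 3L)
  expect_true(all(diff(top$probability) <= 0))
  expect_lte(sum(top$probability), 1 + 1e-9)
  # Q annotation always a subset of L annotation for every reported cluster
  for (i in seq_len(nrow(top)))
    expect_true(all(top$proteins_q[[i]] %in% top$proteins_l[[i]]))
  # same-cluster compounds at distance zero; matrix symmetric, zero diagonal
  ok <- rownames(rep$distance)
  expect_true(isSymmetric(rep$distance))
  expect_true(all(diag(rep$distance) == 0))
})
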