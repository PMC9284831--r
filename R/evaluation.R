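# Study-design orchestration: cluster-subset selection, splits and
# cross-validation, F1 scoring, fold-wise randomization tests for
# architecture comparison, and the prediction + annotation report.

#' Macro, micro and per-class F1 scores
#'
#' Per-class F1 is `2PR/(P+R)` (0 when `P + R = 0`); macro F1 is the
#' unweighted mean over classes present in the true labels; micro F1 pools
#' counts over classes.
#'
#' @param truth,pred equal-length label vectors.
#' @return list with `macro`, `micro`, `per_class`.
#' @export
f1_scores <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(unique(truth))
  if (length(classes) < 1L) stop("need at least one class")
  per <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  tp_all <- sum(truth == pred)
  # micro: pooled precision == pooled recall == accuracy in single-label tasks
  micro <- tp_all / length(truth)
  list(macro = mean(per), micro = micro, per_class = per)
}

#' Paired sign-flip randomization test on fold-wise scores
#'
#' Two-sided test of the mean difference between two models' per-fold scores.
#' When the number of folds is at most `exhaustive_below`, all `2^n` sign
#' assignments are enumerated exactly; otherwise `n_permutations` Monte-Carlo
#' flips with add-one smoothing are used.
#'
#' @param scores_a,scores_b equal-length per-fold scores (same folds).
#' @param n_permutations Monte-Carlo sample size.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @param exhaustive_below exhaustive enumeration bound (default 12).
#' @return p-value in (0, 1].
#' @export
randomization_test <- function(scores_a, scores_b, n_permutations = 10000L,
                               seed = 1L, exhaustive_below = 12L) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors differ in length")
  d <- scores_a - scores_b
  n <- length(d)
  obs <- abs(mean(d))
  if (all(d == 0)) return(1)
  if (n <= exhaustive_below) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_means <- abs(as.vector(signs %*% d) / n)
    return(sum(null_means >= obs - 1e-12) / 2^n)
  }
  rng <- .local_rng(seed)
  hits <- 0L
  for (i in seq_len(n_permutations)) {
    s <- ifelse(rng$runif(n) < 0.5, -1, 1)
    if (abs(mean(s * d)) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_permutations + 1)
}

#' Holdout + k-fold cross-validation splits
#'
#' Holds out `holdout_fraction` of the data for final testing and partitions
#' the rest into `k_folds` folds (sizes differing by at most 1).  With
#' `stratified = TRUE`, class proportions are preserved within +-1 sample per
#' class; classes with fewer members than folds fall back to unstratified
#' assignment with a warning.
#'
#' @param ids sample identifiers (split unit -- pass source compound ids so
#'   augmented variants can never cross a boundary).
#' @param labels class labels aligned with `ids`.
#' @param holdout_fraction fraction held out (default 0.1).
#' @param k_folds number of CV folds (default 10).
#' @param seed RNG seed.
#' @param stratified stratify by class (default TRUE).
#' @return a `split_spec`: list with `holdout` (ids), `folds` (list of id
#'   vectors), `seed`, `stratified`.
#' @export
make_splits <- function(ids, labels, holdout_fraction = 0.1, k_folds = 10L,
                        seed = 1L, stratified = TRUE) {
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids))
  if (length(ids) < k_folds) stop("dataset smaller than k_folds")
  rng <- .local_rng(seed)
  labels <- as.character(labels)
  assign_strat <- function(ids, labels, n_groups, frac = NULL) {
    # returns group index per id; frac (scalar) carves one holdout group
    out <- integer(length(ids))
    names(out) <- ids
    for (cl in sort(unique(labels))) {
      members <- ids[labels == cl]
      members <- members[rng$sample(length(members))]
      if (!is.null(frac)) {
        nh <- round(length(members) * frac)
        out[members] <- c(rep(1L, nh), rep(2L, length(members) - nh))
      } else {
        out[members] <- rep(seq_len(n_groups),
                            length.out = length(members))
      }
    }
    out
  }
  if (stratified) {
    small <- names(which(table(labels) < k_folds))
    if (length(small) > 0L)
      warning("class(es) with fewer members than folds: ",
              paste(small, collapse = ", "),
              "; fold assignment is round-robin for them")
    grp <- assign_strat(ids, labels, 2L, frac = holdout_fraction)
  } else {
    perm <- ids[rng$sample(length(ids))]
    nh <- round(length(ids) * holdout_fraction)
    grp <- stats::setNames(rep(2L, length(ids)), ids)
    grp[perm[seq_len(nh)]] <- 1L
  }
  holdout <- names(grp)[grp == 1L]
  rest <- names(grp)[grp == 2L]
  rest_lab <- labels[match(rest, ids)]
  fold_id <- if (stratified)
    assign_strat(rest, rest_lab, k_folds)
  else {
    perm <- rest[rng$sample(length(rest))]
    stats::setNames(rep(seq_len(k_folds), length.out = length(perm)),
                    perm)[rest]
  }
  # rebalance so fold sizes differ by <= 1 (stratified rounding can drift)
  fold_id <- .rebalance_folds(fold_id, k_folds, rng)
  folds <- split(names(fold_id), fold_id)
  structure(list(holdout = holdout, folds = unname(folds), seed = seed,
                 stratified = stratified), class = "split_spec")
}

.rebalance_folds <- function(fold_id, k, rng) {
  repeat {
    sizes <- tabulate(fold_id, nbins = k)
    if (max(sizes) - min(sizes) <= 1L) return(fold_id)
    big <- which.max(sizes); small <- which.min(sizes)
    movable <- names(fold_id)[fold_id == big]
    fold_id[movable[rng$sample(length(movable), 1L)]] <- small
  }
}

#' Train/validation/test split (80/10/10 by default)
#'
#' @param ids,labels as in [make_splits()].
#' @param fractions length-3 vector summing to 1.
#' @param seed RNG seed.
#' @param stratified stratify by class.
#' @return a `split_spec` with `train`, `validation`, `test` id vectors.
#' @export
make_tvt <- function(ids, labels, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                     stratified = TRUE) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  rng <- .local_rng(seed)
  labels <- as.character(labels)
  grp <- stats::setNames(integer(length(ids)), ids)
  pools <- if (stratified) split(ids, labels) else list(all = ids)
  for (members in pools) {
    members <- members[rng$sample(length(members))]
    n <- length(members)
    n1 <- round(n * fractions[1]); n2 <- round(n * fractions[2])
    grp[members] <- c(rep(1L, n1), rep(2L, n2), rep(3L, n - n1 - n2))
  }
  structure(list(train = names(grp)[grp == 1L],
                 validation = names(grp)[grp == 2L],
                 test = names(grp)[grp == 3L],
                 seed = seed, stratified = stratified),
            class = "split_spec")
}

#' Select a study subset of clusters with near pairs and spread
#'
#' Half the subset comes from nearest-neighbor cluster pairs in cophenetic
#' distance (both members of the closest pairs), the other half from a
#' max-min spread sample over the remaining clusters, so the subset contains
#' both closely related and distant clusters.
#'
#' @param clustering a `chem_clustering` (its linkage provides distances).
#' @param n_clusters subset size.
#' @param seed RNG seed (max-min start cluster).
#' @return integer vector of cluster ids.
#' @export
select_cluster_subset <- function(clustering, n_clusters, seed = 1L) {
  cids <- sort(unique(clustering$assignment))
  if (length(cids) < n_clusters) stop("fewer clusters than requested")
  if (length(cids) == n_clusters) return(cids)
  D <- outer(cids, cids, Vectorize(function(a, b)
    cluster_distance(clustering, a, b)))
  dimnames(D) <- list(cids, cids)
  rng <- .local_rng(seed)
  chosen <- integer()
  # nearest-neighbor pairs first
  Dp <- D; diag(Dp) <- Inf
  n_pairs <- floor(n_clusters / 2 / 2) * 2L  # even count from pairs, half of n
  n_pair_target <- floor(n_clusters / 2)
  while (length(chosen) < n_pair_target - 1L) {
    ij <- which(Dp == min(Dp), arr.ind = TRUE)[1, ]
    pair <- cids[ij]
    chosen <- union(chosen, pair)
    Dp[ij[1], ] <- Inf; Dp[, ij[1]] <- Inf
    Dp[ij[2], ] <- Inf; Dp[, ij[2]] <- Inf
  }
  # max-min spread for the rest
  remaining <- setdiff(cids, chosen)
  if (length(chosen) == 0L)
    chosen <- remaining[rng$sample(length(remaining), 1L)]
  while (length(chosen) < n_clusters) {
    remaining <- setdiff(cids, chosen)
    dmin <- vapply(remaining, function(c0)
      min(D[as.character(c0), as.character(chosen)]), numeric(1))
    chosen <- c(chosen, remaining[which.max(dmin)])
  }
  sort(chosen[seq_len(n_clusters)])
}

#' Cross-validated architecture comparison
#'
#' Trains every architecture configuration on each CV fold (training on the
#' other folds, scoring F1 on the fold), then reports per-fold macro/micro
#' F1, means and standard deviations, and all pairwise sign-flip
#' randomization-test p-values.
#'
#' @param dataset data.frame with `id`, `smiles`, `cluster` columns.
#' @param configs named list of `model_config`s (names label the report).
#'   `lm_finetune` entries are fine-tuned from `lm` (required then).
#' @param splits a `split_spec` from [make_splits()].
#' @param lm optional pretrained bundle for `lm_finetune` configs: a list
#'   with `lm` (a `language_model`), `vocab`, `max_len`, and optionally
#'   `merges`, so every fold encodes with the pretraining vocabulary.
#' @param augment_k class-wise augmentation applied to each training split
#'   (token-sequence models only; 0 disables).
#' @param seed base seed.
#' @return an `evaluation_report`: list with `fold_f1` (matrix folds x
#'   models), `summary` (mean/sd), `p_values` (matrix), `failed` folds.
#' @export
evaluate_architectures <- function(dataset, configs, splits, lm = NULL,
                                   augment_k = 0, seed = 1L) {
  stopifnot(inherits(splits, "split_spec"), !is.null(splits$folds))
  k <- length(splits$folds)
  models <- names(configs)
  fold_f1 <- matrix(NA_real_, k, length(models),
                    dimnames = list(NULL, models))
  fold_micro <- fold_f1
  for (fi in seq_len(k)) {
    test_ids <- splits$folds[[fi]]
    train_ids <- setdiff(unlist(splits$folds), test_ids)
    tr <- dataset[dataset$id %in% train_ids, ]
    te <- dataset[dataset$id %in% test_ids, ]
    for (mi in seq_along(configs)) {
      cfg <- configs[[mi]]
      f1 <- tryCatch(
        .fit_score_once(tr, te, cfg, lm, augment_k,
                        seed + fi),
        error = function(e) {
          warning("fold ", fi, " model '", models[mi], "' failed: ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(f1)) {
        fold_f1[fi, mi] <- f1$macro
        fold_micro[fi, mi] <- f1$micro
      }
    }
  }
  pv <- matrix(NA_real_, length(models), length(models),
               dimnames = list(models, models))
  for (a in seq_along(models)) for (b in seq_along(models)) {
    ok <- stats::complete.cases(fold_f1[, c(a, b)])
    if (a != b && sum(ok) >= 2L)
      pv[a, b] <- randomization_test(fold_f1[ok, a], fold_f1[ok, b],
                                     seed = seed)
  }
  structure(list(
    fold_f1 = fold_f1, fold_micro = fold_micro,
    summary = data.frame(model = models,
                         mean_macro_f1 = colMeans(fold_f1, na.rm = TRUE),
                         sd_macro_f1 = apply(fold_f1, 2, stats::sd,
                                             na.rm = TRUE)),
    p_values = pv,
    failed = which(rowSums(is.na(fold_f1)) > 0L)
  ), class = "evaluation_report")
}

# train one config on tr, score macro/micro F1 on te
.fit_score_once <- function(tr, te, cfg, lm, augment_k, seed) {
  cfg$seed <- seed
  scheme <- switch(cfg$architecture,
                   dnn = "fingerprint", cnn = "matrix",
                   rnn_seq2seq = cfg$tokenizer, lm_finetune = cfg$tokenizer)
  tr_use <- tr
  if (augment_k > 0 && scheme %in% c("atomwise", "spe"))
    tr_use <- classwise_augment(tr, augment_k, seed = seed)
  if (scheme %in% c("atomwise", "spe")) {
    enc_tr <- if (!is.null(lm) && cfg$architecture == "lm_finetune")
      encode_dataset(tr_use$smiles, tr_use$cluster, scheme,
                     vocab = lm$vocab, max_len = lm$max_len,
                     merges = lm$merges)
    else encode_dataset(tr_use$smiles, tr_use$cluster, scheme)
    enc_te_x <- encode_like(enc_tr, te$smiles)
  } else {
    enc_tr <- encode_dataset(tr_use$smiles, tr_use$cluster, scheme)
    enc_te_x <- encode_like(enc_tr, te$smiles)
  }
  model <- if (cfg$architecture == "lm_finetune") {
    if (is.null(lm)) stop("lm_finetune config requires a language model")
    finetune_lm_classifier(lm$lm, enc_tr, cfg)
  } else train_classifier(enc_tr, cfg)
  pred <- predict.trained_classifier(model, enc_te_x)
  f1_scores(te$cluster, pred)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Predict clusters for compounds and annotate with protein sets
#'
#' For each compound: the top-k predicted clusters with softmax probabilities
#' (descending), each cluster's protein annotation at the high (Q) and low
#' (L) cutoff; plus the pairwise cophenetic distance matrix between the
#' compounds' top-1 clusters.  Unparseable compounds get an error entry and
#' the batch continues.
#'
#' @param model a `trained_classifier` whose classes are cluster ids.
#' @param compounds named character vector of SMILES (names label the rows).
#' @param clustering the `chem_clustering` carrying the linkage.
#' @param annotation_q,annotation_l `cluster_annotation`s at the Qcutoff and
#'   Lcutoff.
#' @param top_k number of clusters to report per compound.
#' @return list with `predictions` (per-compound list) and `distance`
#'   (matrix of cophenetic distances between predicted top-1 clusters).
#' @export
predict_and_annotate <- function(model, compounds, clustering,
                                 annotation_q, annotation_l, top_k = 3L) {
  if (is.null(names(compounds)))
    names(compounds) <- paste0("compound", seq_along(compounds))
  preds <- lapply(names(compounds), function(nm) {
    smi <- compounds[[nm]]
    tryCatch({
      probs <- predict_proba(model, smi)[1, ]
      ord <- order(probs, decreasing = TRUE)[seq_len(min(top_k,
                                                         length(probs)))]
      top <- data.frame(cluster = model$classes[ord],
                        probability = unname(probs[ord]),
                        stringsAsFactors = FALSE)
      top$proteins_q <- lapply(top$cluster, function(cl)
        annotation_q$proteins[[as.character(cl)]])
      top$proteins_l <- lapply(top$cluster, function(cl)
        annotation_l$proteins[[as.character(cl)]])
      list(ok = TRUE, top = top)
    }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  })
  names(preds) <- names(compounds)
  ok <- names(preds)[vapply(preds, `[[`, logical(1), "ok")]
  D <- matrix(NA_real_, length(ok), length(ok), dimnames = list(ok, ok))
  for (a in ok) for (b in ok) {
    ca <- preds[[a]]$top$cluster[1]; cb <- preds[[b]]$top$cluster[1]
    D[a, b] <- if (identical(ca, cb)) 0 else
      cluster_distance(clustering, as.integer(ca), as.integer(cb))
  }
  list(predictions = preds, distance = D)
}
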