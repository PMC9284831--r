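# Model conformance: the same train/predict contract across all four
# architectures, at desk-scale configurations.

enc_fp <- encode_dataset(fx_tiny$smiles, fx_tiny$cluster, "fingerprint")
enc_fm <- encode_dataset(fx_tiny$smiles, fx_tiny$cluster, "matrix")
enc_tk <- encode_dataset(fx_tiny$smiles, fx_tiny$cluster, "atomwise")

mem_configs <- list(
  dnn = desk_config("dnn", epochs = 25L, batch_size = 32L, dropout = 0,
                    seed = 2L),
  cnn = desk_config("cnn", epochs = 25L, batch_size = 32L, dropout = 0,
                    seed = 2L, lr = 3e-3),
  rnn_seq2seq = desk_config("rnn_seq2seq", epochs = 25L, batch_size = 32L,
                            dropout = 0, seed = 2L))

enc_for <- function(arch) switch(arch, dnn = enc_fp, cnn = enc_fm, enc_tk)

lm_small <- local({
  cfg <- desk_config("lm_finetune", epochs = 4L, seed = 3L)
  cfg$vocab_n <- vocab_size(enc_tk$vocab)
  pretrain_lm(enc_tk$x, cfg, enc_tk$vocab)
})

fit_arch <- function(arch, cfg = NULL) {
  if (arch == "lm_finetune") {
    cfg <- cfg %||% desk_config("lm_finetune", epochs = 10L, batch_size = 32L,
                                dropout = 0, seed = 2L)
    finetune_lm_classifier(lm_small, enc_tk, cfg)
  } else {
    train_classifier(enc_for(arch), cfg %||% mem_configs[[arch]])
  }
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("every architecture meets the shared contract", {
  for (arch in c("dnn", "cnn", "rnn_seq2seq", "lm_finetune")) {
    m <- fit_arch(arch)
    enc <- if (arch %in% c("rnn_seq2seq", "lm_finetune")) enc_tk else enc_for(arch)
    probs <- predict_proba(m, enc$x)
    expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)),
                 tolerance = 1e-6, info = arch)
    expect_true(all(probs >= 0), info = arch)
    expect_identical(colnames(probs), m$classes, info = arch)
    # argmax consistency
    expect_identical(predict(m, enc$x),
                     m$classes[max.col(probs, ties.method = "first")],
                     info = arch)
    # determinism: same seed, same data -> identical predictions
    m2 <- fit_arch(arch)
    expect_identical(predict_proba(m2, enc$x), probs, info = arch)
    # serialization round-trip preserves predictions exactly
    dir <- withr::local_tempdir()
    model_save(m, dir)
    expect_identical(predict_proba(model_load(dir), enc$x), probs,
                     info = arch)
    # loss decreases after the early epochs on the memorization fixture
    lg <- m$log
    expect_true(all(diff(lg[-(1:2)]) <= 1e-4), info = arch)
  }
})

test_that("dnn memorizes a separable 2-class fingerprint fixture", {
  m <- fit_arch("dnn")
  expect_equal(mean(predict(m, enc_fp$x) == as.character(enc_fp$y)), 1)
  probs <- predict_proba(m, enc_fp$x)
  expect_true(all(probs[cbind(seq_len(nrow(probs)),
                              match(as.character(enc_fp$y), m$classes))] >
                  apply(probs, 1, function(r) max(r[-which.max(r)]))))
})

test_that("encoding/architecture mismatches are configuration errors", {
  expect_error(train_classifier(enc_fp, desk_config("cnn")), "does not match")
  expect_error(train_classifier(enc_tk, desk_config("dnn")), "does not match")
  one_class <- encode_dataset(fx_tiny$smiles[1:5], rep("A", 5), "fingerprint")
  expect_error(train_classifier(one_class, desk_config("dnn")),
               "at least 2 classes")
  expect_error(model_config("dnn", channels = c(3L)), "not valid")
  expect_error(model_config("dnn", dropout = 1), "dropout")
})

test_that("predict_proba validates input dimensions", {
  m <- fit_arch("dnn")
  expect_error(predict_proba(m, enc_fp$x[, 1:100]), "model expects")
})

test_that("language model learns and vocabulary hash is enforced", {
  # degenerate corpus: one repeated sequence -> perplexity near 1
  seqs <- lapply(1:20, function(i) tokenize_atomwise("CCOCC"))
  v <- build_vocab(seqs)
  ids <- t(vapply(seqs, encode_tokens, integer(10L), vocab = v, max_len = 10L))
  cfg <- desk_config("lm_finetune", epochs = 60L, seed = 1L, weight_drop = 0,
                     lr = 1e-2)
  cfg$vocab_n <- vocab_size(v)
  lm <- pretrain_lm(ids, cfg, v)
  expect_lt(lm_perplexity(lm, ids), 1.1)
  # learning sanity on the fixture corpus
  expect_lt(lm_small$log[length(lm_small$log)], lm_small$log[1])
  # vocab mismatch blocks fine-tuning
  other <- encode_dataset(fx_tiny$smiles, fx_tiny$cluster, "atomwise",
                          vocab = v, max_len = 10L)
  expect_error(finetune_lm_classifier(lm_small, other,
                                      desk_config("lm_finetune")),
               "vocabulary mismatch")
})

test_that("random-token corpus perplexity stays near vocabulary size", {
  set.seed(7)
  V <- 6L   # 4 specials + 2 content tokens would be too few; use raw ids
  ids <- cbind(2L, matrix(sample(4:9, 20 * 8, replace = TRUE), 20), 3L)
  v <- build_vocab(lapply(1:6, function(i) letters[1:6]))
  cfg <- desk_config("lm_finetune", epochs = 3L, seed = 1L, weight_drop = 0)
  cfg$vocab_n <- 10L
  lm <- pretrain_lm(ids, cfg, v)
  ppl <- lm_perplexity(lm, ids)
  # 6 equiprobable content tokens: perplexity cannot dip much below 6
  expect_gt(ppl, 4.5)
})

test_that("frozen-body fine-tuning changes only the head in epoch 1", {
  cfg <- desk_config("lm_finetune", epochs = 1L, seed = 2L, dropout = 0)
  m <- finetune_lm_classifier(lm_small, enc_tk, cfg)
  for (k in c("E", "W1", "U1", "b1", "W2", "U2", "b2", "W3", "U3", "b3"))
    expect_identical(m$params[[k]], lm_small$params[[k]])
  expect_false(is.null(m$params$Wh))
})

test_that("pretraining transfer helps at reduced training size", {
  # paired over 5 seeds (different half-size training subsets): fine-tuning
  # from the pretrained body should match or beat a random-init body on
  # held-out macro F1 in the majority of pairs, and on the mean difference
  df <- fx_lib
  enc_all <- encode_dataset(df$smiles, df$cluster, "atomwise")
  cfgp <- desk_config("lm_finetune", epochs = 30L, seed = 31L)
  cfgp$vocab_n <- vocab_size(enc_all$vocab)
  lm_all <- pretrain_lm(enc_all$x, cfgp, enc_all$vocab)
  wins <- 0L
  diffs <- numeric(5L)
  for (s in 1:5) {
    set.seed(s)
    idx <- unlist(lapply(split(seq_len(nrow(df)), df$cluster),
                         function(ix) sample(ix, 6L)))
    tr <- df[idx, ]; te <- df[-idx, ]
    enc_tr <- encode_dataset(tr$smiles, tr$cluster, "atomwise",
                             vocab = enc_all$vocab, max_len = enc_all$max_len)
    cfg <- desk_config("lm_finetune", epochs = 10L, seed = s)
    m_pre <- finetune_lm_classifier(lm_all, enc_tr, cfg)
    lm_rand <- structure(list(
      params = chemclust:::.with_seed(1000 + s,
        chemclust:::.seq_params_init(cfgp$vocab_n, cfgp$emb_dim,
                                     cfgp$hidden, cfgp$n_layers)),
      config = cfgp, vocab_hash = vocab_hash(enc_all$vocab),
      log = NA_real_), class = "language_model")
    m_rnd <- finetune_lm_classifier(lm_rand, enc_tr, cfg)
    te_x <- encode_like(enc_tr, te$smiles)
    f_pre <- f1_scores(te$cluster, predict(m_pre, te_x))$macro
    f_rnd <- f1_scores(te$cluster, predict(m_rnd, te_x))$macro
    diffs[s] <- f_pre - f_rnd
    if (f_pre >= f_rnd) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
  expect_gte(mean(diffs), 0)
})
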