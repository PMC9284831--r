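# Fingerprints, feature matrices, tokenizers, vocabulary.

test_that("fingerprints have the configured shape and molecule invariance", {
  fp <- morgan_fingerprint(ASPIRIN)
  expect_length(fp, 1024L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_equal(attr(fp, "radius"), 2L)
  vars <- enumerate_smiles(ASPIRIN, max_variants = 12L, seed = 1L)
  fps <- fingerprint_matrix(vars)
  expect_true(all(apply(fps, 2, function(col) length(unique(col)) == 1L)))
  expect_false(identical(morgan_fingerprint("C"), morgan_fingerprint("CC")))
  expect_length(morgan_fingerprint("CCO", radius = 3L, n_bits = 256L), 256L)
})

test_that("feature matrices are 42 x max_len with correct padding", {
  fm <- feature_matrix(canonicalize_smiles("C"), max_len = 10L)
  expect_equal(dim(fm), c(42L, 10L))
  expect_equal(sum(colSums(abs(fm)) > 0), 1L)
  expect_equal(attr(fm, "valid_len"), 1L)
  expect_error(feature_matrix("CCCCCCCCCC", max_len = 5L), "exceeds max_len")
})

test_that("non-atom characters hit only the symbol block", {
  fm <- feature_matrix("CC(=O)O", max_len = 10L)
  for (col in c(3L, 4L, 6L)) {            # "(", "=", ")"
    expect_true(all(fm[1:21, col] == 0))
    expect_equal(sum(fm[22:42, col]), 1)
  }
  # atom columns carry element one-hot in the atom block
  expect_equal(fm[1, 1], 1)               # C slot
  expect_true(all(fm[22:42, 1] == 0))
})

test_that("feature dimension is 42 for many random variants", {
  dims <- vapply(fx_variants[seq_len(300)], function(s)
    nrow(feature_matrix(canonicalize_smiles(s),
                        max_len = 120L)), numeric(1))
  expect_true(all(dims == 42))
})

test_that("atom-wise tokenization matches the reference split", {
  expect_identical(
    tokenize_atomwise(ASPIRIN),
    c("C", "C", "(", "=", "O", ")", "O", "c", "1", "c", "c", "c", "c", "c",
      "1", "C", "(", "=", "O", ")", "O"))
  expect_identical(tokenize_atomwise("C[Cl-]"), c("C", "[Cl-]"))
  expect_identical(tokenize_atomwise("CCl"), c("C", "Cl"))
  expect_identical(tokenize_atomwise("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
  expect_error(tokenize_atomwise("C[NH"), "unmatched")
})

test_that("tokenizers are lossless over the random fixture library", {
  merges <- learn_spe(fx_lib$smiles, max_merges = 30L)
  for (s in fx_variants[seq(1, length(fx_variants), by = 7)]) {
    expect_identical(paste(tokenize_atomwise(s), collapse = ""), s)
    expect_identical(paste(tokenize_spe(s, merges), collapse = ""), s)
  }
})

test_that("pair-encoding learning is deterministic with lexicographic ties", {
  m <- learn_spe(rep("CCO", 10L), max_merges = 1L)
  expect_equal(nrow(m), 1L)
  expect_equal(unlist(m[1, 1:2], use.names = FALSE), c("C", "C"))
  expect_equal(m$frequency[1], 10L)
  m0 <- learn_spe(c("CCO", "OCC"), max_merges = 0L)
  expect_equal(nrow(m0), 0L)
  expect_identical(tokenize_spe("CCO", m0), tokenize_atomwise("CCO"))
  m5 <- learn_spe(fx_lib$smiles, max_merges = 5L)
  expect_lte(nrow(m5), 5L)
  expect_true(all(diff(m5$frequency) <= 0))
})

test_that("spe merges apply leftmost-first and compress on average", {
  m <- structure(data.frame(token_a = "C", token_b = "C",
                            frequency = 2L, stringsAsFactors = FALSE),
                 class = c("spe_merges", "data.frame"))
  expect_identical(tokenize_spe("CCC", m), c("CC", "C"))
  merges <- learn_spe(fx_lib$smiles, max_merges = 40L)
  aw <- mean(vapply(fx_lib$smiles, function(s)
    length(tokenize_atomwise(s)), numeric(1)))
  sp <- mean(vapply(fx_lib$smiles, function(s)
    length(tokenize_spe(s, merges)), numeric(1)))
  expect_lte(sp, aw)
})

test_that("vocabulary ids and encoding round-trip", {
  seqs <- lapply(fx_lib$smiles[1:30], tokenize_atomwise)
  v <- build_vocab(seqs)
  expect_identical(v$id2token[1:4], c("<pad>", "<unk>", "<bos>", "<eos>"))
  expect_identical(unname(v$token2id[v$id2token]),
                   seq_along(v$id2token) - 1L)
  ids <- encode_tokens(seqs[[1]], v, max_len = 40L)
  expect_length(ids, 40L)
  expect_false(any(ids == 1L))            # no UNK on training tokens
  expect_identical(decode_tokens(ids, v), seqs[[1]])
  expect_equal(encode_tokens("Zz9", v, 5L)[2], 1L)  # unseen -> UNK
  # truncation keeps BOS/EOS framing
  long <- encode_tokens(rep("C", 50L), v, 10L)
  expect_length(long, 10L)
  expect_equal(long[1], v$token2id[["<bos>"]])
  expect_equal(long[10], v$token2id[["<eos>"]])
})
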