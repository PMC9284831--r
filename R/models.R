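# Unified train/predict contract over the four classifier families:
#   dnn          fingerprint bit vectors  -> fully connected net
#   cnn          42 x L feature matrices  -> 1-D convolutional net
#   rnn_seq2seq  token-id sequences       -> 3-layer LSTM encoder ("perceiver")
#   lm_finetune  token-id sequences       -> pretrained LSTM + concat pooling
#
# Paper-scale widths are the documented defaults; desk_config() shrinks them
# for CPU-scale runs.  Scale is configuration, not code.

ARCHITECTURES <- c("dnn", "cnn", "rnn_seq2seq", "lm_finetune")

#' Model configuration
#'
#' @param architecture one of `"dnn"`, `"cnn"`, `"rnn_seq2seq"`,
#'   `"lm_finetune"`.
#' @param ... overrides of the architecture's fields.  Common fields:
#'   `dropout`, `lr`, `batch_size`, `epochs`, `seed`.  `dnn`: `hidden`
#'   (vector of layer widths).  `cnn`: `channels`, `kernels`.  Sequence
#'   models: `emb_dim`, `hidden`, `n_layers`, `tokenizer`; `lm_finetune`
#'   additionally `weight_drop`, `patience`, `lr_decay_factor`,
#'   `gradual_unfreeze`.
#' @return a validated `model_config` list.
#' @export
model_config <- function(architecture = ARCHITECTURES, ...) {
  architecture <- match.arg(architecture)
  base <- list(architecture = architecture, dropout = 0.2, lr = 1e-3,
               batch_size = 32L, epochs = 20L, seed = 1L)
  arch <- switch(architecture,
    dnn = list(hidden = c(4096L, 4096L, 1024L), dropout = 0.4),
    cnn = list(channels = c(64L, 64L, 64L), kernels = c(11L, 11L, 11L),
               dropout = 0.25),
    rnn_seq2seq = list(emb_dim = 128L, hidden = 256L, n_layers = 3L,
                       dropout = 0.3, tokenizer = "atomwise"),
    lm_finetune = list(emb_dim = 128L, hidden = 256L, n_layers = 3L,
                       dropout = 0.3, tokenizer = "atomwise",
                       weight_drop = 0.5, patience = 2L,
                       lr_decay_factor = 2.6, gradual_unfreeze = TRUE))
  cfg <- utils::modifyList(base, arch)
  dots <- list(...)
  allowed <- c(names(cfg), "vocab_n")
  bad <- setdiff(names(dots), allowed)
  if (length(bad) > 0L)
    stop("field(s) not valid for architecture '", architecture, "': ",
         paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, dots)
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0,1)")
  if (cfg$epochs < 1L) stop("epochs must be >= 1")
  structure(cfg, class = "model_config")
}

#' Desk-scale preset configurations for CPU testing
#'
#' @param architecture architecture name.
#' @param ... further overrides.
#' @return a `model_config`.
#' @export
desk_config <- function(architecture = ARCHITECTURES, ...) {
  architecture <- match.arg(architecture)
  preset <- switch(architecture,
    dnn = list(hidden = c(64L, 64L, 32L), epochs = 30L, batch_size = 16L),
    cnn = list(channels = c(16L, 16L, 16L), kernels = c(5L, 5L, 5L),
               epochs = 20L, batch_size = 16L),
    rnn_seq2seq = list(emb_dim = 16L, hidden = 32L, n_layers = 3L,
                       epochs = 20L, batch_size = 16L, lr = 3e-3),
    lm_finetune = list(emb_dim = 16L, hidden = 32L, n_layers = 3L,
                       epochs = 12L, batch_size = 16L, lr = 3e-3,
                       weight_drop = 0.3))
  do.call(model_config, utils::modifyList(c(list(architecture = architecture),
                                            preset), list(...)))
}

#' Encode a labeled molecule set for a model family
#'
#' @param smiles character vector of SMILES.
#' @param labels cluster labels (coerced to factor); may be `NULL` for
#'   unlabeled corpora.
#' @param scheme `"fingerprint"`, `"matrix"`, `"atomwise"` or `"spe"`.
#' @param radius,n_bits fingerprint parameters.
#' @param max_len length cutoff (characters for `"matrix"`, tokens incl.
#'   BOS/EOS for token schemes); default fits the longest input.
#' @param vocab,merges reuse a vocabulary / merge table built on training
#'   data (pass these when encoding validation or test molecules).
#' @param spe_merges number of merges to learn when `scheme = "spe"` and no
#'   `merges` given.
#' @return an `encoded_dataset`: list with `scheme`, `x`, `y`, and the
#'   encoder state needed to encode new compounds the same way.
#' @export
encode_dataset <- function(smiles, labels = NULL,
                           scheme = c("fingerprint", "matrix", "atomwise",
                                      "spe"),
                           radius = 2L, n_bits = 1024L, max_len = NULL,
                           vocab = NULL, merges = NULL, spe_merges = 50L) {
  scheme <- match.arg(scheme)
  y <- if (is.null(labels)) NULL else factor(labels)
  if (scheme == "fingerprint") {
    x <- fingerprint_matrix(smiles, radius = radius, n_bits = n_bits)
    return(structure(list(scheme = scheme, x = x, y = y, radius = radius,
                          n_bits = n_bits), class = "encoded_dataset"))
  }
  if (scheme == "matrix") {
    can <- vapply(smiles, canonicalize_smiles, character(1), USE.NAMES = FALSE)
    if (is.null(max_len)) max_len <- max(nchar(can))
    x <- feature_array(can, max_len = max_len)
    return(structure(list(scheme = scheme, x = x, y = y, max_len = max_len),
                     class = "encoded_dataset"))
  }
  toks <- if (scheme == "atomwise") {
    lapply(smiles, tokenize_atomwise)
  } else {
    if (is.null(merges)) merges <- learn_spe(smiles, max_merges = spe_merges)
    lapply(smiles, tokenize_spe, merges = merges)
  }
  if (is.null(vocab)) vocab <- build_vocab(toks)
  if (is.null(max_len)) max_len <- max(lengths(toks)) + 2L
  x <- t(vapply(toks, encode_tokens, integer(max_len), vocab = vocab,
                max_len = max_len))
  structure(list(scheme = scheme, x = x, y = y, vocab = vocab,
                 merges = merges, max_len = max_len),
            class = "encoded_dataset")
}

#' Re-encode new compounds with a dataset's (or model's) encoder state
#'
#' @param enc an `encoded_dataset` or `trained_classifier`.
#' @param smiles character vector of SMILES.
#' @return the encoded `x` block (matrix or array) matching the scheme.
#' @export
encode_like <- function(enc, smiles) {
  if (inherits(enc, "trained_classifier")) enc <- enc$encoder
  switch(enc$scheme,
    fingerprint = fingerprint_matrix(smiles, radius = enc$radius,
                                     n_bits = enc$n_bits),
    matrix = feature_array(vapply(smiles, canonicalize_smiles, character(1),
                                  USE.NAMES = FALSE), max_len = enc$max_len),
    {
      toks <- if (enc$scheme == "atomwise") lapply(smiles, tokenize_atomwise)
              else lapply(smiles, tokenize_spe, merges = enc$merges)
      t(vapply(toks, encode_tokens, integer(enc$max_len), vocab = enc$vocab,
               max_len = enc$max_len))
    })
}

.check_compat <- function(encoded, config) {
  ok <- switch(config$architecture,
    dnn = encoded$scheme == "fingerprint",
    cnn = encoded$scheme == "matrix",
    rnn_seq2seq = ,
    lm_finetune = encoded$scheme %in% c("atomwise", "spe"))
  if (!ok)
    stop("encoding scheme '", encoded$scheme,
         "' does not match architecture '", config$architecture, "'")
}

.encoder_state <- function(encoded) {
  encoded[setdiff(names(encoded), c("x", "y"))]
}

#' Train a classifier on an encoded dataset
#'
#' @param encoded an `encoded_dataset` with labels (`y`) present and >= 2
#'   classes.
#' @param config a `model_config` whose architecture matches the encoding
#'   (fingerprint -> dnn, matrix -> cnn, tokens -> rnn_seq2seq).  For
#'   `lm_finetune` use [finetune_lm_classifier()].
#' @return a `trained_classifier`: architecture, fitted parameters, class
#'   ordering (fixed at fit time), per-epoch loss log, and the encoder state
#'   for scoring new compounds.
#' @export
train_classifier <- function(encoded, config) {
  .check_compat(encoded, config)
  if (is.null(encoded$y)) stop("encoded dataset has no labels")
  if (length(levels(encoded$y)) < 2L) stop("need at least 2 classes")
  if (config$architecture == "lm_finetune")
    stop("train lm_finetune via finetune_lm_classifier() (needs a pretrained ",
         "language model; pass one built with pretrain_lm)")
  fit <- switch(config$architecture,
    dnn = .train_dnn(encoded$x, encoded$y, config),
    cnn = .train_cnn(encoded$x, encoded$y, config),
    rnn_seq2seq = {
      cfg <- config
      cfg$vocab_n <- vocab_size(encoded$vocab)
      .train_rnn(encoded$x, encoded$y, cfg)
    })
  cfg <- config
  if (config$architecture == "rnn_seq2seq")
    cfg$vocab_n <- vocab_size(encoded$vocab)
  structure(list(architecture = config$architecture, params = fit$params,
                 config = cfg, classes = levels(encoded$y), log = fit$log,
                 encoder = .encoder_state(encoded)),
            class = "trained_classifier")
}

#' Fine-tune a pretrained language model into a classifier
#'
#' Transfers the embedding and LSTM body, adds a concat-pooling linear head,
#' and trains with gradual unfreezing and discriminative learning rates.
#'
#' @param lm a `language_model` from [pretrain_lm()].
#' @param encoded token-encoded dataset; its vocabulary hash must match the
#'   language model's (guards against silent UNK flooding).
#' @param config a `model_config` with architecture `"lm_finetune"`; network
#'   shape fields are taken from the language model.
#' @return a `trained_classifier`.
#' @export
finetune_lm_classifier <- function(lm, encoded, config) {
  .check_compat(encoded, config)
  if (length(levels(encoded$y)) < 2L) stop("need at least 2 classes")
  if (vocab_hash(encoded$vocab) != lm$vocab_hash)
    stop("vocabulary mismatch between language model and dataset")
  cfg <- config
  for (k in c("emb_dim", "hidden", "n_layers", "vocab_n"))
    cfg[[k]] <- lm$config[[k]]
  fit <- .train_lm_classifier(encoded$x, encoded$y, cfg, lm$params,
                              cfg$n_layers)
  structure(list(architecture = "lm_finetune", params = fit$params,
                 config = cfg, classes = levels(encoded$y), log = fit$log,
                 encoder = .encoder_state(encoded)),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat("<trained_classifier> ", x$architecture, ", ", length(x$classes),
      " classes, final loss ", round(x$log[length(x$log)], 4), "\n", sep = "")
  invisible(x)
}

#' Per-class probabilities for encoded samples
#'
#' @param model a `trained_classifier`.
#' @param x encoded samples matching the model's scheme (use [encode_like()]
#'   for raw SMILES), or a character vector of SMILES.
#' @return matrix of probabilities, one row per sample; columns follow
#'   `model$classes`; each row sums to 1.
#' @export
predict_proba <- function(model, x) {
  if (is.character(x)) x <- encode_like(model, x)
  .check_dims(model, x)
  probs <- switch(model$architecture,
    dnn = .predict_dnn(model, x),
    cnn = .predict_cnn(model, x),
    rnn_seq2seq = .predict_rnn(model, x),
    lm_finetune = .predict_lmclf(model, x))
  colnames(probs) <- model$classes
  probs
}

.check_dims <- function(model, x) {
  sc <- model$encoder$scheme
  if (sc == "fingerprint" && ncol(x) != model$encoder$n_bits)
    stop("input has ", ncol(x), " columns; model expects ",
         model$encoder$n_bits)
  if (sc == "matrix" && (length(dim(x)) != 3L || dim(x)[2] != FEATURE_DIM ||
                         dim(x)[3] != model$encoder$max_len))
    stop("feature array dimensions do not match the model")
  if (sc %in% c("atomwise", "spe") && ncol(x) != model$encoder$max_len)
    stop("token id matrix has wrong max_len for this model")
  invisible(TRUE)
}

#' Predicted class labels (argmax of probabilities)
#'
#' @param object a `trained_classifier`.
#' @param x encoded samples or SMILES.
#' @param ... unused.
#' @return character vector of class labels.
#' @export
predict.trained_classifier <- function(object, x, ...) {
  probs <- predict_proba(object, x)
  object$classes[max.col(probs, ties.method = "first")]
}

#' Save / load a trained classifier
#'
#' Writes a directory with the weights blob, `config.json` and
#' `classes.json`; loading restores a model with identical predictions.
#'
#' @param model a `trained_classifier`.
#' @param dir artifact directory.
#' @return `model_save` the directory (invisibly); `model_load` the model.
#' @export
model_save <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  saveRDS(model$encoder, file.path(dir, "encoder.rds"))
  cfg <- unclass(model$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(classes = model$classes,
                            architecture = model$architecture,
                            log = model$log),
                       file.path(dir, "classes.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname model_save
#' @export
model_load <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  for (k in c("hidden", "channels", "kernels"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.integer(cfg[[k]])
  meta <- jsonlite::read_json(file.path(dir, "classes.json"),
                              simplifyVector = TRUE)
  structure(list(architecture = meta$architecture,
                 params = readRDS(file.path(dir, "weights.rds")),
                 config = structure(as.list(cfg), class = "model_config"),
                 classes = meta$classes, log = meta$log,
                 encoder = readRDS(file.path(dir, "encoder.rds"))),
            class = "trained_classifier")
}
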