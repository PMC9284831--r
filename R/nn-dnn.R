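# Fully connected classifier over fingerprint bit vectors.
#
# Architecture: input -> [dense -> ReLU -> dropout] per hidden layer ->
# dense -> softmax.  The published configuration uses hidden sizes
# 4096/4096/1024 with dropout 0.4; desk-scale presets shrink the widths,
# not the code.

.mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  params <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", i)]] <- .glorot(sizes[i], sizes[i + 1L])
    params[[paste0("b", i)]] <- rep(0, sizes[i + 1L])
  }
  params
}

.mlp_forward <- function(params, X, dropout = 0, training = FALSE) {
  nl <- length(params) / 2L
  h <- X
  cache <- list(h0 = X)
  for (i in seq_len(nl - 1L)) {
    z <- sweep(h %*% params[[paste0("W", i)]], 2, params[[paste0("b", i)]], "+")
    h <- .relu(z)
    if (training && dropout > 0) {
      mask <- .dropout_mask(dim(h), dropout)
      h <- h * mask
      cache[[paste0("mask", i)]] <- mask
    }
    cache[[paste0("z", i)]] <- z
    cache[[paste0("h", i)]] <- h
  }
  logits <- sweep(h %*% params[[paste0("W", nl)]], 2,
                  params[[paste0("b", nl)]], "+")
  cache$logits <- logits
  cache$probs <- .softmax(logits)
  cache
}

.mlp_backward <- function(params, cache, y) {
  nl <- length(params) / 2L
  grads <- list()
  d <- .ce_grad(cache$probs, y)              # n x C
  for (i in rev(seq_len(nl))) {
    hin <- cache[[paste0("h", i - 1L)]]
    if (i == 1L) hin <- cache$h0
    grads[[paste0("W", i)]] <- t(hin) %*% d
    grads[[paste0("b", i)]] <- colSums(d)
    if (i > 1L) {
      d <- d %*% t(params[[paste0("W", i)]])
      mask <- cache[[paste0("mask", i - 1L)]]
      if (!is.null(mask)) d <- d * mask
      d <- d * (cache[[paste0("z", i - 1L)]] > 0)
    }
  }
  grads
}

.train_dnn <- function(X, y, config) {
  .with_seed(config$seed, {
    params <- .mlp_init(ncol(X), config$hidden, length(levels(y)))
    opt <- .adam(params, lr = config$lr)
    yi <- as.integer(y)
    log <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      for (idx in .minibatches(nrow(X), config$batch_size)) {
        cache <- .mlp_forward(params, X[idx, , drop = FALSE],
                              dropout = config$dropout, training = TRUE)
        grads <- .mlp_backward(params, cache, yi[idx])
        params <- opt$step(params, grads)
      }
      probs <- .mlp_forward(params, X)$probs
      log[ep] <- .ce_loss(probs, yi)
    }
    list(params = params, log = log)
  })
}

.predict_dnn <- function(model, X) {
  .mlp_forward(model$params, X)$probs
}
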