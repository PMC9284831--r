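# 1-D convolutional classifier over per-character feature matrices.
#
# Three same-padded conv layers (ReLU) over the character axis, global max
# pooling per channel, then a fully connected softmax head.  Inputs are
# (n, 42, L) arrays from feature_array().

.conv_init <- function(in_ch, out_ch, k) {
  list(W = .glorot(k * in_ch, out_ch), b = rep(0, out_ch))
}

# X3: (n, in_ch, L); W: (k*in_ch, out_ch).  Returns (n, out_ch, L).
.conv_forward <- function(X3, W, b, k) {
  n <- dim(X3)[1]; in_ch <- dim(X3)[2]; L <- dim(X3)[3]
  pad <- (k - 1L) %/% 2L
  Xp <- array(0, dim = c(n, in_ch, L + 2L * pad))
  Xp[, , pad + seq_len(L)] <- X3
  Xcol <- matrix(0, n * L, k * in_ch)
  for (j in seq_len(k)) for (c in seq_len(in_ch))
    Xcol[, (j - 1L) * in_ch + c] <- as.vector(Xp[, c, (j - 1L) + seq_len(L)])
  Z <- sweep(Xcol %*% W, 2, b, "+")          # (n*L, out_ch)
  out_ch <- ncol(W)
  Z3 <- array(Z, dim = c(n, L, out_ch))
  Z3 <- aperm(Z3, c(1, 3, 2))                # (n, out_ch, L)
  list(out = Z3, Xcol = Xcol, dims = c(n = n, in_ch = in_ch, L = L,
                                       k = k, pad = pad))
}

# dZ3: (n, out_ch, L) gradient.  Returns grads and dX3.
.conv_backward <- function(dZ3, W, cache) {
  d <- cache$dims
  n <- d["n"]; in_ch <- d["in_ch"]; L <- d["L"]; k <- d["k"]; pad <- d["pad"]
  dZ <- matrix(aperm(dZ3, c(1, 3, 2)), n * L, dim(dZ3)[2])
  dW <- t(cache$Xcol) %*% dZ
  db <- colSums(dZ)
  dXcol <- dZ %*% t(W)                       # (n*L, k*in_ch)
  dXp <- array(0, dim = c(n, in_ch, L + 2L * pad))
  for (j in seq_len(k)) for (c in seq_len(in_ch)) {
    sl <- (j - 1L) + seq_len(L)
    dXp[, c, sl] <- dXp[, c, sl] +
      array(dXcol[, (j - 1L) * in_ch + c], dim = c(n, L))
  }
  list(dW = dW, db = db, dX = dXp[, , pad + seq_len(L), drop = FALSE])
}

.cnn_init <- function(in_ch, channels, kernels, n_out) {
  params <- list()
  prev <- in_ch
  for (i in seq_along(channels)) {
    cv <- .conv_init(prev, channels[i], kernels[i])
    params[[paste0("Wc", i)]] <- cv$W
    params[[paste0("bc", i)]] <- cv$b
    prev <- channels[i]
  }
  params$Wf <- .glorot(prev, n_out)
  params$bf <- rep(0, n_out)
  params
}

.cnn_forward <- function(params, X3, kernels, dropout = 0, training = FALSE) {
  cache <- list(conv = list())
  h <- X3
  for (i in seq_along(kernels)) {
    cv <- .conv_forward(h, params[[paste0("Wc", i)]],
                        params[[paste0("bc", i)]], kernels[i])
    z <- cv$out
    h <- .relu(z)
    cache$conv[[i]] <- list(cv = cv, z = z)
  }
  # global max pool over length
  n <- dim(h)[1]; ch <- dim(h)[2]; L <- dim(h)[3]
  hm <- matrix(h, n * ch, L)
  arg <- max.col(hm, ties.method = "first")
  pooled <- matrix(hm[cbind(seq_len(n * ch), arg)], n, ch)
  cache$arg <- arg; cache$pool_dims <- c(n, ch, L); cache$h_last <- h
  p <- pooled
  if (training && dropout > 0) {
    mask <- .dropout_mask(dim(p), dropout)
    p <- p * mask
    cache$mask <- mask
  }
  cache$pooled <- p
  logits <- sweep(p %*% params$Wf, 2, params$bf, "+")
  cache$probs <- .softmax(logits)
  cache
}

.cnn_backward <- function(params, cache, y, kernels) {
  grads <- list()
  d <- .ce_grad(cache$probs, y)
  grads$Wf <- t(cache$pooled) %*% d
  grads$bf <- colSums(d)
  dp <- d %*% t(params$Wf)
  if (!is.null(cache$mask)) dp <- dp * cache$mask
  pd <- cache$pool_dims
  dH <- matrix(0, pd[1] * pd[2], pd[3])
  dH[cbind(seq_len(pd[1] * pd[2]), cache$arg)] <- as.vector(dp)
  dH <- array(dH, dim = pd)
  for (i in rev(seq_along(kernels))) {
    dZ <- dH * (cache$conv[[i]]$z > 0)
    bk <- .conv_backward(dZ, params[[paste0("Wc", i)]], cache$conv[[i]]$cv)
    grads[[paste0("Wc", i)]] <- bk$dW
    grads[[paste0("bc", i)]] <- bk$db
    dH <- bk$dX
  }
  grads
}

.train_cnn <- function(X3, y, config) {
  .with_seed(config$seed, {
    params <- .cnn_init(dim(X3)[2], config$channels, config$kernels,
                        length(levels(y)))
    opt <- .adam(params, lr = config$lr)
    yi <- as.integer(y)
    n <- dim(X3)[1]
    log <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      for (idx in .minibatches(n, config$batch_size)) {
        cache <- .cnn_forward(params, X3[idx, , , drop = FALSE],
                              config$kernels, config$dropout, training = TRUE)
        grads <- .cnn_backward(params, cache, yi[idx], config$kernels)
        params <- opt$step(params, grads)
      }
      # epoch loss in eval mode, batched to bound memory
      tot <- 0
      for (idx in .minibatches(n, 64L, shuffle = FALSE)) {
        pr <- .cnn_forward(params, X3[idx, , , drop = FALSE],
                           config$kernels)$probs
        tot <- tot + .ce_loss(pr, yi[idx]) * length(idx)
      }
      log[ep] <- tot / n
    }
    list(params = params, log = log)
  })
}

.predict_cnn <- function(model, X3) {
  out <- NULL
  n <- dim(X3)[1]
  for (idx in .minibatches(n, 64L, shuffle = FALSE)) {
    pr <- .cnn_forward(model$params, X3[idx, , , drop = FALSE],
                       model$config$kernels)$probs
    out <- rbind(out, pr)
  }
  out[order(unlist(.minibatches(n, 64L, shuffle = FALSE))), , drop = FALSE]
}
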