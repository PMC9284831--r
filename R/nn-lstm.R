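# LSTM machinery shared by the sequence classifier ("perceiver" route) and
# the language-model route.  Hand-derived backpropagation through time with
# pad masking: hidden and cell states freeze across padding positions.
#
# Gate order in the fused weight matrices is i, f, g, o.

.lstm_init <- function(in_dim, hidden) {
  list(W = .glorot(in_dim, 4L * hidden),
       U = .glorot(hidden, 4L * hidden),
       b = c(rep(0, hidden), rep(1, hidden), rep(0, 2L * hidden)))  # forget bias 1
}

.sigm <- function(x) 1 / (1 + exp(-x))

# X: (n, T, in_dim); M: (n, T) 1/0 mask; Umask: optional DropConnect mask on U
# Returns H: (n, T, hidden) and caches for backward.
.lstm_forward <- function(X, M, W, U, b, Umask = NULL) {
  n <- dim(X)[1]; TT <- dim(X)[2]; H <- ncol(U) / 4L
  Ueff <- if (is.null(Umask)) U else U * Umask
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  Hout <- array(0, dim = c(n, TT, H))
  cache <- vector("list", TT)
  for (t in seq_len(TT)) {
    xt <- matrix(X[, t, ], n)
    z <- xt %*% W + h %*% Ueff
    z <- sweep(z, 2, b, "+")
    i <- .sigm(z[, seq_len(H), drop = FALSE])
    f <- .sigm(z[, H + seq_len(H), drop = FALSE])
    g <- tanh(z[, 2L * H + seq_len(H), drop = FALSE])
    o <- .sigm(z[, 3L * H + seq_len(H), drop = FALSE])
    cnew <- f * cc + i * g
    hnew <- o * tanh(cnew)
    m <- M[, t]
    cache[[t]] <- list(xt = xt, hprev = h, cprev = cc, i = i, f = f, g = g,
                       o = o, cnew = cnew, m = m)
    cc <- cnew * m + cc * (1 - m)
    h <- hnew * m + h * (1 - m)
    Hout[, t, ] <- h
  }
  list(H = Hout, cache = cache, Ueff = Ueff)
}

# dH: (n, T, hidden) external gradient on the layer output.
.lstm_backward <- function(dH, X, W, U, b, fw, Umask = NULL) {
  n <- dim(X)[1]; TT <- dim(X)[2]; H <- ncol(U) / 4L
  Ueff <- fw$Ueff
  dW <- W * 0; dU <- U * 0; db <- b * 0
  dX <- array(0, dim = dim(X))
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(TT))) {
    ca <- fw$cache[[t]]
    m <- ca$m
    dh_total <- matrix(dH[, t, ], n) + dh_next
    # output h_t = m*hnew + (1-m)*h_{t-1}; same for c
    dhnew <- dh_total * m
    dh_prev_skip <- dh_total * (1 - m)
    tc <- tanh(ca$cnew)
    do <- dhnew * tc * ca$o * (1 - ca$o)
    dcnew <- dhnew * ca$o * (1 - tc^2) + dc_next * m
    dc_prev_skip <- dc_next * (1 - m)
    di <- dcnew * ca$g * ca$i * (1 - ca$i)
    df <- dcnew * ca$cprev * ca$f * (1 - ca$f)
    dg <- dcnew * ca$i * (1 - ca$g^2)
    dc_prev <- dcnew * ca$f + dc_prev_skip
    dz <- cbind(di, df, dg, do)
    dW <- dW + t(ca$xt) %*% dz
    dU <- dU + t(ca$hprev) %*% dz
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(W)
    dh_prev <- dz %*% t(Ueff) + dh_prev_skip
    dh_next <- dh_prev
    dc_next <- dc_prev
  }
  if (!is.null(Umask)) dU <- dU * Umask
  list(dW = dW, dU = dU, db = db, dX = dX)
}

# --- stacked network helpers -------------------------------------------------

.seq_params_init <- function(vocab_n, emb_dim, hidden, n_layers) {
  params <- list(E = .glorot(vocab_n, emb_dim))
  prev <- emb_dim
  for (l in seq_len(n_layers)) {
    lp <- .lstm_init(prev, hidden)
    params[[paste0("W", l)]] <- lp$W
    params[[paste0("U", l)]] <- lp$U
    params[[paste0("b", l)]] <- lp$b
    prev <- hidden
  }
  params
}

# ids: (n, T) 0-based; returns embedded (n, T, emb), mask (n, T)
.embed <- function(params, ids) {
  n <- nrow(ids); TT <- ncol(ids)
  emb <- ncol(params$E)
  X <- array(0, dim = c(n, TT, emb))
  flat <- as.vector(ids) + 1L
  Xm <- params$E[flat, , drop = FALSE]        # (n*T, emb)
  X <- array(Xm, dim = c(n, TT, emb))
  M <- matrix(as.numeric(ids != 0L), n, TT)   # PAD id is 0
  list(X = X, M = M)
}

.embed_backward <- function(params, ids, dX) {
  n <- nrow(ids); TT <- ncol(ids)
  dE <- params$E * 0
  flat <- as.vector(ids) + 1L
  dXm <- matrix(dX, n * TT, ncol(params$E))
  # accumulate by destination row
  agg <- rowsum(dXm, flat)
  dE[as.integer(rownames(agg)), ] <- dE[as.integer(rownames(agg)), ] + agg
  dE[1, ] <- 0   # PAD embedding stays fixed
  dE
}

.stack_forward <- function(params, ids, n_layers, Umasks = NULL) {
  eb <- .embed(params, ids)
  h <- eb$X
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fw <- .lstm_forward(h, eb$M, params[[paste0("W", l)]],
                        params[[paste0("U", l)]], params[[paste0("b", l)]],
                        Umask = if (is.null(Umasks)) NULL else Umasks[[l]])
    layers[[l]] <- list(input = h, fw = fw)
    h <- fw$H
  }
  list(H = h, M = eb$M, layers = layers)
}

.stack_backward <- function(params, ids, st, dH, n_layers, Umasks = NULL,
                            frozen = integer()) {
  grads <- list()
  d <- dH
  for (l in rev(seq_len(n_layers))) {
    bk <- .lstm_backward(d, st$layers[[l]]$input, params[[paste0("W", l)]],
                         params[[paste0("U", l)]], params[[paste0("b", l)]],
                         st$layers[[l]]$fw,
                         Umask = if (is.null(Umasks)) NULL else Umasks[[l]])
    if (!(l %in% frozen)) {
      grads[[paste0("W", l)]] <- bk$dW
      grads[[paste0("U", l)]] <- bk$dU
      grads[[paste0("b", l)]] <- bk$db
    }
    d <- bk$dX
    if (l == 1L && !(0L %in% frozen))
      grads$E <- .embed_backward(params, ids, d)
  }
  grads
}

# index of last non-pad position per row (>= 1)
.last_pos <- function(M) {
  apply(M, 1, function(m) max(which(m > 0), 1L))
}

# concat pooling over time: [h_last, max_t h, mean_t h] -> (n, 3H)
.concat_pool <- function(H, M) {
  n <- dim(H)[1]; TT <- dim(H)[2]; hd <- dim(H)[3]
  last <- .last_pos(M)
  hl <- matrix(0, n, hd)
  hmax <- matrix(-Inf, n, hd); argmax <- matrix(1L, n, hd)
  hsum <- matrix(0, n, hd)
  for (t in seq_len(TT)) {
    ht <- matrix(H[, t, ], n)
    m <- M[, t]
    upd <- (ht > hmax) & (m > 0)
    argmax[upd] <- t
    hmax[upd] <- ht[upd]
    hsum <- hsum + ht * m
  }
  cnt <- pmax(rowSums(M), 1)
  hl <- t(vapply(seq_len(n), function(i) H[i, last[i], ], numeric(hd)))
  list(pooled = cbind(hl, hmax, hsum / cnt), last = last, argmax = argmax,
       cnt = cnt)
}

.concat_pool_backward <- function(dP, H, M, pool) {
  n <- dim(H)[1]; TT <- dim(H)[2]; hd <- dim(H)[3]
  dH <- array(0, dim = dim(H))
  dlast <- dP[, seq_len(hd), drop = FALSE]
  dmax <- dP[, hd + seq_len(hd), drop = FALSE]
  dmean <- dP[, 2L * hd + seq_len(hd), drop = FALSE]
  for (i in seq_len(n)) {
    dH[i, pool$last[i], ] <- dH[i, pool$last[i], ] + dlast[i, ]
    for (j in seq_len(hd)) {
      tm <- pool$argmax[i, j]
      dH[i, tm, j] <- dH[i, tm, j] + dmax[i, j]
    }
  }
  for (t in seq_len(TT))
    dH[, t, ] <- dH[, t, ] + dmean * (M[, t] / pool$cnt)
  dH
}

# --- sequence classifier (3-layer LSTM encoder + linear head) ---------------

.train_rnn <- function(ids, y, config) {
  .with_seed(config$seed, {
    n_layers <- config$n_layers
    params <- .seq_params_init(config$vocab_n, config$emb_dim,
                               config$hidden, n_layers)
    params$Wh <- .glorot(config$hidden, length(levels(y)))
    params$bh <- rep(0, length(levels(y)))
    opt <- .adam(params, lr = config$lr)
    yi <- as.integer(y)
    log <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      for (idx in .minibatches(nrow(ids), config$batch_size)) {
        sub <- ids[idx, , drop = FALSE]
        st <- .stack_forward(params, sub, n_layers)
        last <- .last_pos(st$M)
        nb <- length(idx)
        hl <- t(vapply(seq_len(nb), function(i) st$H[i, last[i], ],
                       numeric(config$hidden)))
        if (config$dropout > 0) {
          mask <- .dropout_mask(dim(hl), config$dropout)
          hl_d <- hl * mask
        } else { mask <- NULL; hl_d <- hl }
        probs <- .softmax(sweep(hl_d %*% params$Wh, 2, params$bh, "+"))
        d <- .ce_grad(probs, yi[idx])
        grads <- list(Wh = t(hl_d) %*% d, bh = colSums(d))
        dhl <- d %*% t(params$Wh)
        if (!is.null(mask)) dhl <- dhl * mask
        dH <- array(0, dim = dim(st$H))
        for (i in seq_len(nb)) dH[i, last[i], ] <- dhl[i, ]
        grads <- c(grads, .stack_backward(params, sub, st, dH, n_layers))
        params <- opt$step(params, grads)
      }
      log[ep] <- .rnn_loss(params, ids, yi, config)
    }
    list(params = params, log = log)
  })
}

.rnn_logits <- function(params, ids, config) {
  st <- .stack_forward(params, ids, config$n_layers)
  last <- .last_pos(st$M)
  hl <- t(vapply(seq_len(nrow(ids)), function(i) st$H[i, last[i], ],
                 numeric(config$hidden)))
  sweep(hl %*% params$Wh, 2, params$bh, "+")
}

.rnn_loss <- function(params, ids, yi, config) {
  tot <- 0
  for (idx in .minibatches(nrow(ids), 64L, shuffle = FALSE)) {
    pr <- .softmax(.rnn_logits(params, ids[idx, , drop = FALSE], config))
    tot <- tot + .ce_loss(pr, yi[idx]) * length(idx)
  }
  tot / nrow(ids)
}

.predict_rnn <- function(model, ids) {
  out <- NULL
  for (idx in .minibatches(nrow(ids), 64L, shuffle = FALSE))
    out <- rbind(out, .softmax(.rnn_logits(model$params,
                                           ids[idx, , drop = FALSE],
                                           model$config)))
  out
}
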