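# Language-model route: next-token pretraining of the embedding + 3-layer
# LSTM body (with DropConnect on the recurrent matrices and an
# averaged-weights switchover triggered by validation patience), then
# classifier fine-tuning with concat pooling and gradual unfreezing.

#' Pretrain a SMILES language model
#'
#' Next-token prediction over encoded token-id sequences.  Recurrent weight
#' matrices get DropConnect (`weight_drop`); when the held-out loss fails to
#' improve for `patience` epochs, parameter averaging starts and the returned
#' weights are the running average from that point (an averaged-SGD-style
#' switchover).
#'
#' @param corpus integer matrix (n x T) of 0-based token ids (0 = pad), e.g.
#'   rows from [encode_tokens()].
#' @param config a `model_config` with architecture `"lm_finetune"` (the
#'   pretraining fields: `emb_dim`, `hidden`, `n_layers`, `weight_drop`,
#'   `patience`, `lr`, `batch_size`, `epochs`, `seed`).
#' @param vocab the `token_vocab` the corpus was encoded with.
#' @return a `language_model`: list with `params`, `config`, `vocab_hash`,
#'   `log` (per-epoch held-out loss).
#' @export
pretrain_lm <- function(corpus, config, vocab) {
  if (is.null(dim(corpus)) || nrow(corpus) == 0L) stop("empty corpus")
  .with_seed(config$seed, {
    n <- nrow(corpus)
    n_layers <- config$n_layers
    params <- .seq_params_init(config$vocab_n, config$emb_dim,
                               config$hidden, n_layers)
    params$D <- .glorot(config$hidden, config$vocab_n)
    params$dB <- rep(0, config$vocab_n)
    opt <- .adam(params, lr = config$lr)
    hold <- sort(sample.int(n, max(1L, floor(n * 0.1))))
    tr <- setdiff(seq_len(n), hold)
    if (length(tr) == 0L) tr <- hold
    log <- numeric(config$epochs)
    best <- Inf; stall <- 0L; averaging <- FALSE
    avg <- NULL; avg_n <- 0L
    for (ep in seq_len(config$epochs)) {
      for (idx in .minibatches(length(tr), config$batch_size))
        {
        sub <- corpus[tr[idx], , drop = FALSE]
        Umasks <- lapply(seq_len(n_layers), function(l)
          if (config$weight_drop > 0)
            .dropout_mask(dim(params[[paste0("U", l)]]), config$weight_drop)
          else NULL)
        res <- .lm_forward_loss(params, sub, n_layers, Umasks)
        if (is.null(res)) next
        params <- opt$step(params, res$grads)
        if (averaging) {
          avg_n <- avg_n + 1L
          for (k in names(params))
            avg[[k]] <- avg[[k]] + (params[[k]] - avg[[k]]) / avg_n
        }
      }
      log[ep] <- .lm_eval_loss(params, corpus[hold, , drop = FALSE], n_layers)
      if (log[ep] < best - 1e-6) { best <- log[ep]; stall <- 0L }
      else stall <- stall + 1L
      if (!averaging && stall >= config$patience) {
        averaging <- TRUE; avg <- params; avg_n <- 1L
      }
    }
    if (averaging) params <- avg
    structure(list(params = params, config = config,
                   vocab_hash = vocab_hash(vocab), log = log),
              class = "language_model")
  })
}

#' @export
print.language_model <- function(x, ...) {
  cat("<language_model> ", x$config$n_layers, "x", x$config$hidden,
      " LSTM, vocab ", x$config$vocab_n, ", final held-out loss ",
      round(x$log[length(x$log)], 4), "\n", sep = "")
  invisible(x)
}

# forward + loss + grads for one LM batch; returns NULL if batch has no
# predictable positions
.lm_forward_loss <- function(params, sub, n_layers, Umasks = NULL) {
  TT <- ncol(sub)
  inp <- sub[, -TT, drop = FALSE]
  targ <- sub[, -1L, drop = FALSE]
  st <- .stack_forward(params, inp, n_layers, Umasks)
  n <- nrow(inp); Tm <- ncol(inp); H <- dim(st$H)[3]
  mask <- targ != 0L & inp != 0L
  nt <- sum(mask)
  if (nt == 0L) return(NULL)
  Hm <- matrix(st$H, n * Tm, H)          # rows: (i,t) column-major over t
  sel <- which(as.vector(mask))
  logits <- sweep(Hm[sel, , drop = FALSE] %*% params$D, 2, params$dB, "+")
  probs <- .softmax(logits)
  yt <- as.vector(targ)[sel] + 1L        # 1-based class ids
  loss <- .ce_loss(probs, yt)
  d <- .ce_grad(probs, yt)
  grads <- list(D = t(Hm[sel, , drop = FALSE]) %*% d, dB = colSums(d))
  dHm <- matrix(0, n * Tm, H)
  dHm[sel, ] <- d %*% t(params$D)
  dH <- array(dHm, dim = dim(st$H))
  grads <- c(grads, .stack_backward(params, inp, st, dH, n_layers,
                                    Umasks = Umasks))
  grads$loss <- NULL
  list(loss = loss, grads = grads)
}

.lm_eval_loss <- function(params, corpus, n_layers) {
  tot <- 0; cnt <- 0
  for (idx in .minibatches(nrow(corpus), 64L, shuffle = FALSE)) {
    sub <- corpus[idx, , drop = FALSE]
    TT <- ncol(sub)
    inp <- sub[, -TT, drop = FALSE]; targ <- sub[, -1L, drop = FALSE]
    st <- .stack_forward(params, inp, n_layers)
    n <- nrow(inp); Tm <- ncol(inp); H <- dim(st$H)[3]
    mask <- targ != 0L & inp != 0L
    if (sum(mask) == 0L) next
    Hm <- matrix(st$H, n * Tm, H)
    sel <- which(as.vector(mask))
    probs <- .softmax(sweep(Hm[sel, , drop = FALSE] %*% params$D, 2,
                            params$dB, "+"))
    yt <- as.vector(targ)[sel] + 1L
    tot <- tot + .ce_loss(probs, yt) * length(sel)
    cnt <- cnt + length(sel)
  }
  if (cnt == 0L) NA_real_ else tot / cnt
}

#' Held-out per-token perplexity of a language model
#'
#' @param lm a `language_model`.
#' @param corpus integer id matrix.
#' @return `exp(mean cross-entropy)` over predictable positions.
#' @export
lm_perplexity <- function(lm, corpus) {
  exp(.lm_eval_loss(lm$params, corpus, lm$config$n_layers))
}

# --- fine-tuning -------------------------------------------------------------

# epoch -> set of frozen parameter groups (0 = embedding, l = LSTM layer l);
# one group unfreezes per epoch, top down.
.unfreeze_schedule <- function(epoch, n_layers) {
  open <- min(epoch - 1L, n_layers + 1L)   # groups unfrozen below the head
  if (open >= n_layers + 1L) return(integer())
  c(0L, seq_len(n_layers))[seq_len(n_layers + 1L - open)]
}

.train_lm_classifier <- function(ids, y, config, init_params, n_layers) {
  .with_seed(config$seed, {
    params <- init_params
    hd <- config$hidden
    params$Wh <- .glorot(3L * hd, length(levels(y)))
    params$bh <- rep(0, length(levels(y)))
    params$D <- NULL; params$dB <- NULL
    opt <- .adam(params, lr = config$lr)
    # discriminative learning rates: deeper groups get lr / 2.6^depth
    decay <- config$lr_decay_factor
    scale <- list(Wh = 1, bh = 1)
    for (l in seq_len(n_layers)) {
      s <- 1 / decay^(n_layers - l + 1L)
      scale[[paste0("W", l)]] <- s
      scale[[paste0("U", l)]] <- s
      scale[[paste0("b", l)]] <- s
    }
    scale$E <- 1 / decay^(n_layers + 1L)
    yi <- as.integer(y)
    log <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      frozen <- if (config$gradual_unfreeze)
        .unfreeze_schedule(ep, n_layers) else integer()
      for (idx in .minibatches(nrow(ids), config$batch_size)) {
        sub <- ids[idx, , drop = FALSE]
        st <- .stack_forward(params, sub, n_layers)
        pool <- .concat_pool(st$H, st$M)
        p <- pool$pooled
        if (config$dropout > 0) {
          mask <- .dropout_mask(dim(p), config$dropout)
          p <- p * mask
        } else mask <- NULL
        probs <- .softmax(sweep(p %*% params$Wh, 2, params$bh, "+"))
        d <- .ce_grad(probs, yi[idx])
        grads <- list(Wh = t(p) %*% d, bh = colSums(d))
        dp <- d %*% t(params$Wh)
        if (!is.null(mask)) dp <- dp * mask
        if (length(frozen) < n_layers + 1L) {
          dH <- .concat_pool_backward(dp, st$H, st$M, pool)
          grads <- c(grads, .stack_backward(params, sub, st, dH, n_layers,
                                            frozen = frozen))
        }
        params <- opt$step(params, grads, lr_scale = scale)
      }
      log[ep] <- .lmclf_loss(params, ids, yi, config, n_layers)
    }
    list(params = params, log = log)
  })
}

.lmclf_logits <- function(params, ids, config, n_layers) {
  st <- .stack_forward(params, ids, n_layers)
  pool <- .concat_pool(st$H, st$M)
  sweep(pool$pooled %*% params$Wh, 2, params$bh, "+")
}

.lmclf_loss <- function(params, ids, yi, config, n_layers) {
  tot <- 0
  for (idx in .minibatches(nrow(ids), 64L, shuffle = FALSE)) {
    pr <- .softmax(.lmclf_logits(params, ids[idx, , drop = FALSE],
                                 config, n_layers))
    tot <- tot + .ce_loss(pr, yi[idx]) * length(idx)
  }
  tot / nrow(ids)
}

.predict_lmclf <- function(model, ids) {
  out <- NULL
  for (idx in .minibatches(nrow(ids), 64L, shuffle = FALSE))
    out <- rbind(out, .softmax(.lmclf_logits(model$params,
                                             ids[idx, , drop = FALSE],
                                             model$config,
                                             model$config$n_layers)))
  out
}
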