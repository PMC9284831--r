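# Minimal neural-network core: initialization, activations, Adam, and the
# categorical cross-entropy head shared by all four architectures.
#
# Everything is plain R matrix code with hand-derived gradients.  Networks are
# parameter lists (named matrices/vectors); optimizers are closures keeping
# per-parameter moment estimates.  Training is deterministic for a fixed seed
# because all randomness (init, shuffling, dropout) flows through one RNG
# stream and R's BLAS use here is single-threaded elementwise/matrix ops.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  force(expr)
}

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

.relu <- function(x) x * (x > 0)

# rows of logits -> probabilities; numerically stable
.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and gradient wrt logits; y is 1-based class index vector
.ce_loss <- function(probs, y) {
  n <- nrow(probs)
  -mean(log(pmax(probs[cbind(seq_len(n), y)], 1e-12)))
}

.ce_grad <- function(probs, y) {
  n <- nrow(probs)
  g <- probs
  g[cbind(seq_len(n), y)] <- g[cbind(seq_len(n), y)] - 1
  g / n
}

# Adam optimizer over a flat named list of arrays
.adam <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  v <- m
  t <- 0L
  list(
    step = function(params, grads, lr_scale = NULL) {
      t <<- t + 1L
      for (k in names(grads)) {
        if (is.null(grads[[k]])) next
        g <- grads[[k]]
        m[[k]] <<- beta1 * m[[k]] + (1 - beta1) * g
        v[[k]] <<- beta2 * v[[k]] + (1 - beta2) * g^2
        mh <- m[[k]] / (1 - beta1^t)
        vh <- v[[k]] / (1 - beta2^t)
        rate <- if (is.null(lr_scale) || is.null(lr_scale[[k]])) lr
                else lr * lr_scale[[k]]
        params[[k]] <- params[[k]] - rate * mh / (sqrt(vh) + eps)
      }
      params
    })
}

.dropout_mask <- function(dim, rate) {
  if (rate <= 0) return(NULL)
  array(stats::rbinom(prod(dim), 1L, 1 - rate) / (1 - rate), dim = dim)
}

.minibatches <- function(n, batch_size, shuffle = TRUE) {
  idx <- if (shuffle) sample.int(n) else seq_len(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# accumulate named gradient lists
.acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (k in names(b)) a[[k]] <- a[[k]] + b[[k]]
  a
}
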