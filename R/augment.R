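# Enumeration-based augmentation and class balancing.
#
# Because fingerprints and canonical feature matrices are order-invariant,
# augmentation only helps token-sequence models; the class-wise scheme grows
# under-represented clusters toward k x (largest class size) by adding
# enumerated SMILES variants of their members.

#' Class-wise SMILES augmentation
#'
#' Grows each class toward a target of `k` times the largest class size by
#' adding enumerated SMILES variants of its members round-robin, never
#' duplicating a string already present in the class.  `k = 0` returns the
#' input unchanged (plus provenance columns).  Classes whose members lack
#' enough distinct variants stop early with a warning.
#'
#' @param dataset data.frame with columns `id`, `smiles`, `cluster`.
#' @param k non-negative augmentation multiplier.
#' @param seed integer seed; variant draw order is deterministic per seed.
#' @param limit per-molecule cap on exhaustive enumeration.
#' @return data.frame with columns `id`, `smiles`, `cluster`, `is_augmented`,
#'   `source_id`.  Original rows are all retained, in order, first.
#' @export
classwise_augment <- function(dataset, k, seed = 1L, limit = 2000L) {
  stopifnot(all(c("id", "smiles", "cluster") %in% names(dataset)))
  if (length(k) != 1L || is.na(k) || k < 0) stop("k must be a count >= 0")
  out <- data.frame(id = as.character(dataset$id),
                    smiles = as.character(dataset$smiles),
                    cluster = as.character(dataset$cluster),
                    is_augmented = FALSE,
                    source_id = as.character(dataset$id),
                    stringsAsFactors = FALSE)
  if (k == 0 || nrow(out) == 0L) return(out)
  sizes <- table(out$cluster)
  target <- ceiling(k * max(sizes))
  rng <- .local_rng(seed)
  added <- list()
  for (cl in names(sizes)) {
    members <- out[out$cluster == cl, ]
    present <- members$smiles
    need <- target - nrow(members)
    if (need <= 0L) next
    # variant pools, shuffled deterministically, originals excluded
    pools <- lapply(seq_len(nrow(members)), function(i) {
      v <- suppressWarnings(
        enumerate_smiles(members$smiles[i], max_variants = Inf, limit = limit))
      v <- setdiff(v, present)
      if (length(v) > 1L) v[rng$sample(length(v))] else v
    })
    ptr <- rep(1L, length(pools))
    got <- 0L
    taken <- character(0)
    rows <- vector("list", need)
    repeat {
      progressed <- FALSE
      for (i in seq_along(pools)) {
        if (got >= need) break
        while (ptr[i] <= length(pools[[i]]) &&
               pools[[i]][ptr[i]] %in% taken) ptr[i] <- ptr[i] + 1L
        if (ptr[i] > length(pools[[i]])) next
        s <- pools[[i]][ptr[i]]; ptr[i] <- ptr[i] + 1L
        got <- got + 1L; progressed <- TRUE
        taken <- c(taken, s)
        rows[[got]] <- data.frame(
          id = paste0(members$id[i], "_aug", got),
          smiles = s, cluster = cl, is_augmented = TRUE,
          source_id = members$id[i], stringsAsFactors = FALSE)
      }
      if (got >= need || !progressed) break
    }
    if (got < need)
      warning("class '", cl, "': only ", got, " of ", need,
              " augmentation variants available (shortfall)")
    if (got > 0L) added[[cl]] <- do.call(rbind, rows[seq_len(got)])
  }
  if (length(added) > 0L) out <- rbind(out, do.call(rbind, unname(added)))
  rownames(out) <- NULL
  out
}

# Seed-scoped RNG helper: evaluates draws under a private RNG state so package
# functions never disturb the caller's .Random.seed.
.local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    force(expr)
  }
  list(
    sample = function(n, size = n, replace = FALSE)
      with_state(sample.int(n, size, replace = replace)),
    runif = function(n, min = 0, max = 1) with_state(runif(n, min, max)),
    rbinom = function(n, size, prob) with_state(rbinom(n, size, prob)),
    int = function(n, k) with_state(sample.int(k, n, replace = TRUE))
  )
}
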