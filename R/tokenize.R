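# SMILES tokenization: atom-wise and learned pair encoding (SMILES-PE).

ATOMWISE_REGEX <- "\\[[^]]+\\]|Br|Cl|%[0-9]{2}|."

#' Atom-wise tokenization of a SMILES string
#'
#' Splits into bracket atoms (`[...]` as single tokens), two-letter elements
#' (`Cl`, `Br`), `%NN` ring closures, and otherwise single characters.
#' Concatenating the tokens reproduces the input exactly.
#'
#' @param smiles a SMILES string.
#' @return character vector of tokens.
#' @examples
#' tokenize_atomwise("CC(=O)Oc1ccccc1C(=O)O")
#' @export
tokenize_atomwise <- function(smiles) {
  if (grepl("\\[", smiles) &&
      lengths(regmatches(smiles, gregexpr("\\[", smiles))) !=
      lengths(regmatches(smiles, gregexpr("\\]", smiles))))
    stop("unmatched '[' in SMILES '", smiles, "'")
  toks <- regmatches(smiles, gregexpr(ATOMWISE_REGEX, smiles, perl = TRUE))[[1]]
  if (paste(toks, collapse = "") != smiles)
    stop("tokenization failed to cover input '", smiles, "'")
  if (any(toks == "["))
    stop("unmatched '[' in SMILES '", smiles, "'")
  toks
}

#' Learn a pair-encoding merge table from a SMILES corpus
#'
#' Starts from atom-wise token sequences and iteratively merges the most
#' frequent adjacent token pair (ties broken lexicographically on the pair)
#' until `max_merges` rules are learned or no pair reaches `min_frequency`.
#'
#' @param corpus character vector of SMILES strings.
#' @param min_frequency minimum pair count for a merge to be learned.
#' @param max_merges maximum number of merge rules.
#' @return a `spe_merges` object: data.frame with columns `token_a`,
#'   `token_b`, `frequency`, in learned (descending-frequency) order.
#' @export
learn_spe <- function(corpus, min_frequency = 2L, max_merges = 100L) {
  if (length(corpus) == 0L) stop("empty corpus")
  seqs <- lapply(corpus, tokenize_atomwise)
  rules <- data.frame(token_a = character(), token_b = character(),
                      frequency = integer(), stringsAsFactors = FALSE)
  if (max_merges < 1L)
    return(structure(rules, class = c("spe_merges", "data.frame")))
  for (m in seq_len(max_merges)) {
    counts <- new.env(parent = emptyenv())
    for (s in seqs) {
      if (length(s) < 2L) next
      pairs <- paste(s[-length(s)], s[-1], sep = "\x01")
      for (p in pairs)
        assign(p, (if (is.null(counts[[p]])) 0L else counts[[p]]) + 1L,
               envir = counts)
    }
    keys <- ls(counts)
    if (length(keys) == 0L) break
    freqs <- vapply(keys, function(k) counts[[k]], integer(1))
    top <- max(freqs)
    if (top < min_frequency) break
    best <- sort(keys[freqs == top])[1]   # lexicographic tie-break
    ab <- strsplit(best, "\x01", fixed = TRUE)[[1]]
    rules <- rbind(rules, data.frame(token_a = ab[1], token_b = ab[2],
                                     frequency = top, stringsAsFactors = FALSE))
    seqs <- lapply(seqs, .apply_merge, a = ab[1], b = ab[2])
  }
  structure(rules, class = c("spe_merges", "data.frame"))
}

# leftmost-first, non-overlapping merge of adjacent pair (a, b), to fixpoint
.apply_merge <- function(tokens, a, b) {
  repeat {
    n <- length(tokens)
    if (n < 2L) return(tokens)
    hit <- which(tokens[-n] == a & tokens[-1] == b)
    if (length(hit) == 0L) return(tokens)
    i <- hit[1]
    tokens <- c(if (i > 1L) tokens[1:(i - 1L)], paste0(a, b),
                if (i + 1L < n) tokens[(i + 2L):n])
  }
}

#' Tokenize a SMILES string with a learned merge table
#'
#' Atom-wise tokens are greedily merged by rule order (leftmost-first within a
#' rule).  With an empty merge table the output equals atom-wise tokenization.
#'
#' @param smiles a SMILES string.
#' @param merges a `spe_merges` object from [learn_spe()].
#' @return character vector of tokens; concatenation reproduces the input.
#' @export
tokenize_spe <- function(smiles, merges) {
  toks <- tokenize_atomwise(smiles)
  if (nrow(merges) == 0L) return(toks)
  for (k in seq_len(nrow(merges)))
    toks <- .apply_merge(toks, merges$token_a[k], merges$token_b[k])
  toks
}

# --- vocabulary --------------------------------------------------------------

SPECIAL_TOKENS <- c("<pad>", "<unk>", "<bos>", "<eos>")

#' Build a token vocabulary from token sequences
#'
#' Reserved ids: `<pad>`=0, `<unk>`=1, `<bos>`=2, `<eos>`=3; observed tokens
#' follow, sorted by descending frequency then lexicographically.
#'
#' @param sequences list of character token vectors.
#' @return a `token_vocab` object: list with `token2id` (named integer vector,
#'   0-based ids) and `id2token`.
#' @export
build_vocab <- function(sequences) {
  if (length(sequences) == 0L) stop("no sequences")
  tab <- table(unlist(sequences))
  toks <- names(tab)[order(-as.integer(tab), names(tab))]
  toks <- setdiff(toks, SPECIAL_TOKENS)
  all <- c(SPECIAL_TOKENS, toks)
  ids <- seq_along(all) - 1L
  names(ids) <- all
  structure(list(token2id = ids, id2token = all), class = "token_vocab")
}

#' @export
print.token_vocab <- function(x, ...) {
  cat("<token_vocab> ", length(x$id2token), " tokens (4 reserved)\n", sep = "")
  invisible(x)
}

#' Number of tokens in a vocabulary (reserved tokens included)
#' @param vocab a `token_vocab`.
#' @return integer count.
#' @export
vocab_size <- function(vocab) length(vocab$id2token)

#' Stable content hash of a vocabulary
#'
#' Used to guard language-model / dataset pairing at fine-tune time.
#' @param vocab a `token_vocab`.
#' @return integer hash.
#' @export
vocab_hash <- function(vocab) {
  sum(vapply(seq_along(vocab$id2token), function(i)
    i * .hash_ints(utf8ToInt(vocab$id2token[i])), numeric(1))) %% 2147483648
}

#' Encode a token sequence as integer ids
#'
#' Wraps the sequence in `<bos>`/`<eos>`, maps unseen tokens to `<unk>`,
#' truncates the token body to fit `max_len`, and pads with `<pad>` (id 0).
#'
#' @param tokens character vector of tokens.
#' @param vocab a `token_vocab`.
#' @param max_len output length.
#' @return integer vector of length `max_len` (0-based ids).
#' @export
encode_tokens <- function(tokens, vocab, max_len) {
  body <- unname(vocab$token2id[tokens])
  body[is.na(body)] <- vocab$token2id[["<unk>"]]
  if (length(body) > max_len - 2L) body <- body[seq_len(max_len - 2L)]
  ids <- c(vocab$token2id[["<bos>"]], body, vocab$token2id[["<eos>"]])
  c(ids, rep(vocab$token2id[["<pad>"]], max_len - length(ids)))
}

#' Decode an id sequence back to tokens (specials stripped)
#'
#' @param ids integer vector of 0-based token ids.
#' @param vocab a `token_vocab`.
#' @return character vector of tokens.
#' @export
decode_tokens <- function(ids, vocab) {
  toks <- vocab$id2token[ids + 1L]
  toks[!(toks %in% SPECIAL_TOKENS)]
}
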