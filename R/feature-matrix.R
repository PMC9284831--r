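# Per-character feature matrices for convolutional models.
#
# Each character of a canonical SMILES becomes one 42-entry column.  The first
# character of each atom token carries the atom block (element one-hot plus
# scaled topology descriptors); every other character carries a one-hot in the
# symbol block.  Columns beyond the string length are zero padding.  The
# 21 + 21 partition lives behind the constants below so an alternative layout
# summing to 42 is a drop-in.

FEATURE_DIM <- 42L
ATOM_BLOCK_ELEMS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
                      "Si", "Se", "other")                      # 13 slots
# remaining atom block rows: degree, aromatic, ring, charge, H count, 2 reserved
SYMBOL_ALPHABET <- c("(", ")", "[", "]", "=", "#", "-", "+", ".", "/", "\\",
                     "@", "%", ":", "l", "r", "H", "digit", "other")  # 19 slots
ATOM_BLOCK_LEN <- length(ATOM_BLOCK_ELEMS) + 6L + 2L                  # 21
SYMBOL_BLOCK_LEN <- FEATURE_DIM - ATOM_BLOCK_LEN                      # 21

#' Encode a canonical SMILES as a 42 x max_len feature matrix
#'
#' @param smiles a canonical SMILES string (canonicalize first; the encoding is
#'   defined on the canonical form so that it is unique per molecule).
#' @param max_len maximum string length; longer inputs raise an error so the
#'   caller can raise the cutoff deliberately.
#' @return numeric matrix of dimension `42 x max_len` with attribute
#'   `valid_len` (the number of non-padding columns).
#' @examples
#' fm <- feature_matrix(canonicalize_smiles("CCO"), max_len = 10)
#' dim(fm)  # 42 10
#' @export
feature_matrix <- function(smiles, max_len = 100L) {
  if (nchar(smiles) > max_len)
    stop("SMILES length ", nchar(smiles), " exceeds max_len ", max_len,
         "; raise the sequence length cutoff to accommodate it")
  mol <- smiles_parse(smiles)
  toks <- tokenize_atomwise(smiles)
  hc <- mol_hcount(mol)
  deg <- .mol_degree(mol)
  inring <- .mol_in_ring(mol)

  out <- matrix(0, nrow = FEATURE_DIM, ncol = max_len)
  atom_idx <- 0L
  col <- 0L
  atom_token <- function(tk) {
    grepl("^\\[", tk) || tk %in% c(ORGANIC_SUBSET, tolower(ORGANIC_SUBSET),
                                   "b", "c", "n", "o", "p", "s")
  }
  for (tk in toks) {
    chars <- strsplit(tk, "", fixed = TRUE)[[1]]
    is_atom <- atom_token(tk)
    if (is_atom) atom_idx <- atom_idx + 1L
    for (ci in seq_along(chars)) {
      col <- col + 1L
      if (is_atom && ci == 1L) {
        i <- atom_idx
        slot <- match(mol$atoms$element[i], ATOM_BLOCK_ELEMS,
                      nomatch = length(ATOM_BLOCK_ELEMS))
        out[slot, col] <- 1
        base <- length(ATOM_BLOCK_ELEMS)
        out[base + 1L, col] <- deg[i] / 4
        out[base + 2L, col] <- as.numeric(mol$atoms$aromatic[i])
        out[base + 3L, col] <- as.numeric(inring[i])
        out[base + 4L, col] <- mol$atoms$charge[i] / 4
        out[base + 5L, col] <- hc[i] / 4
        # base + 6 (chirality) and the 2 reserved rows stay zero
      } else {
        ch <- chars[ci]
        key <- if (grepl("[0-9]", ch)) "digit"
               else if (ch %in% SYMBOL_ALPHABET) ch
               else "other"
        out[ATOM_BLOCK_LEN + match(key, SYMBOL_ALPHABET), col] <- 1
      }
    }
  }
  structure(out, valid_len = col)
}

#' Feature-matrix-encode a set of molecules into an array
#'
#' @param smiles character vector of canonical SMILES.
#' @param max_len shared length cutoff; defaults to the longest input.
#' @return numeric array of dimension `(n, 42, max_len)`.
#' @export
feature_array <- function(smiles, max_len = NULL) {
  if (is.null(max_len)) max_len <- max(nchar(smiles))
  arr <- array(0, dim = c(length(smiles), FEATURE_DIM, max_len))
  for (i in seq_along(smiles)) arr[i, , ] <- feature_matrix(smiles[i], max_len)
  arr
}
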