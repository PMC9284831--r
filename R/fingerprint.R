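# Morgan-style circular fingerprints (ECFP-like).
#
# Atom environments are hashed iteratively: round 0 hashes per-atom invariants
# (element, degree, H count, charge, aromaticity, ring membership); round r
# hashes the previous identifier together with the sorted (bond type, neighbor
# identifier) pairs.  Every identifier from every round sets one bit of the
# output vector.  All hashing is order-independent, so any SMILES ordering of
# the same molecule yields the same bit vector -- the invariance that makes
# enumeration-based augmentation useless for this representation.

# 32-bit FNV-1a over an integer vector, kept in [0, 2^31)
.hash_ints <- function(xs) {
  h <- 2166136261
  for (x in xs) {
    x <- as.numeric(x) %% 4294967296
    # fold in 4 bytes
    for (shift in c(1, 256, 65536, 16777216)) {
      byte <- floor(x / shift) %% 256
      h <- bitwXor(as.integer(h %% 2147483648), as.integer(byte))
      h <- (h * 16777619) %% 4294967296
    }
  }
  floor(h %% 2147483648)
}

.bond_type_code <- c("-" = 1L, "=" = 2L, "#" = 3L, "ar" = 4L)

#' Morgan circular fingerprint of a molecule
#'
#' @param smiles a SMILES string or `chem_mol`.
#' @param radius neighborhood radius (number of hashing rounds); default 2.
#' @param n_bits length of the bit vector; default 1024.
#' @return integer vector of 0/1 of length `n_bits` with attributes `radius`
#'   and `n_bits`.
#' @examples
#' fp <- morgan_fingerprint("CC(=O)Oc1ccccc1C(=O)O")
#' length(fp)  # 1024
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 1024L) {
  mol <- if (inherits(smiles, "chem_mol")) smiles else smiles_parse(smiles)
  n <- nrow(mol$atoms)
  adj <- .mol_adjacency(mol)
  hc <- mol_hcount(mol)
  deg <- .mol_degree(mol)
  inring <- .mol_in_ring(mol)
  elem_code <- match(mol$atoms$element,
                     c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B"),
                     nomatch = 99L)
  ids <- vapply(seq_len(n), function(i) .hash_ints(c(
    elem_code[i], deg[i], hc[i], mol$atoms$charge[i] + 10L,
    as.integer(mol$atoms$aromatic[i]), as.integer(inring[i]))), numeric(1))
  all_ids <- ids
  if (radius >= 1L) for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(i) {
      nb <- vapply(adj[[i]], function(b) {
        j <- .bond_other(mol, b, i)
        .bond_type_code[[mol$bonds$type[b]]] * 2^31 + ids[j]
      }, numeric(1))
      nb <- sort(nb)
      .hash_ints(c(r, ids[i], as.vector(rbind(floor(nb / 2^31), nb %% 2^31))))
    }, numeric(1))
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  bits <- integer(n_bits)
  bits[(all_ids %% n_bits) + 1L] <- 1L
  structure(bits, radius = radius, n_bits = n_bits)
}

#' Fingerprint-encode a set of molecules
#'
#' @param smiles character vector of SMILES.
#' @param radius,n_bits see [morgan_fingerprint()].
#' @return numeric matrix, one row per molecule, `n_bits` columns.
#' @export
fingerprint_matrix <- function(smiles, radius = 2L, n_bits = 1024L) {
  out <- matrix(0L, nrow = length(smiles), ncol = n_bits)
  for (i in seq_along(smiles))
    out[i, ] <- morgan_fingerprint(smiles[i], radius = radius, n_bits = n_bits)
  rownames(out) <- names(smiles)
  out
}
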