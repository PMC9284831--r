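# SMILES parsing and molecular graph construction.
#
# A `chem_mol` is a light molecular graph: a data.frame of atoms (element,
# aromatic flag, formal charge, explicit H count from bracket atoms, isotope)
# and a data.frame of bonds (atom indices a1 < a2 for lookup convenience is NOT
# enforced -- order is traversal order; type is one of "-", "=", "#", "ar").
# Stereo bond marks (/ and \) and atom chirality tags are parsed and dropped:
# biological-distance clustering and the classifiers here operate on the
# constitutional graph.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s", "se", "as")

DEFAULT_VALENCE <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
                     F = 1L, Cl = 1L, Br = 1L, I = 1L)

BOND_ORDER <- c("-" = 1, "=" = 2, "#" = 3, "ar" = 1.5)

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms (isotope, charge, explicit H,
#' chirality -- chirality is dropped), branches, ring closures (`1`-`9` and
#' `%NN`), and the bond symbols `-`, `=`, `#`, `:`, `/`, `\`.  Aromaticity is
#' normalized after parsing: Kekule-form rings that satisfy the Hueckel rule
#' are rewritten with aromatic atoms and bonds, so `C1=CC=CC=C1` and
#' `c1ccccc1` produce identical graphs.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `chem_mol` with elements `atoms` (data.frame)
#'   and `bonds` (data.frame).
#' @examples
#' mol <- smiles_parse("CC(=O)Oc1ccccc1C(=O)O")
#' nrow(mol$atoms)  # 13 heavy atoms of aspirin
#' @export
smiles_parse <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stop("smiles must be a single character string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty SMILES")

  el <- character(); arom <- logical(); chg <- integer()
  hexp <- integer(); iso <- integer()
  b1 <- integer(); b2 <- integer(); btype <- character()

  add_atom <- function(element, aromatic, charge = 0L, h = NA_integer_,
                       isotope = NA_integer_) {
    el[[length(el) + 1L]] <<- element
    arom[[length(arom) + 1L]] <<- aromatic
    chg[[length(chg) + 1L]] <<- charge
    hexp[[length(hexp) + 1L]] <<- h
    iso[[length(iso) + 1L]] <<- isotope
    length(el)
  }
  add_bond <- function(a, b, type) {
    if (a == b) stop("self-loop bond in SMILES")
    b1[[length(b1) + 1L]] <<- a
    b2[[length(b2) + 1L]] <<- b
    btype[[length(btype) + 1L]] <<- type
  }

  prev <- 0L                 # previous atom index (0 = none)
  stack <- integer()         # branch stack
  pending_bond <- NA_character_
  ring <- list()             # digit -> list(atom, bond)
  i <- 1L

  bond_chars <- c("-", "=", "#", ":", "/", "\\")

  close_ring <- function(digit, atom) {
    key <- as.character(digit)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = atom, bond = pending_bond)
    } else {
      open <- ring[[key]]
      bt <- pending_bond
      if (is.na(bt)) bt <- open$bond
      if (!is.na(open$bond) && !is.na(pending_bond) &&
          open$bond != pending_bond)
        stop("conflicting ring-closure bond symbols for digit ", key)
      if (is.na(bt)) bt <- "-"
      if (bt %in% c(":", "/", "\\")) bt <- if (bt == ":") "ar" else "-"
      add_bond(open$atom, atom, bt)
      ring[[key]] <<- NULL
    }
    pending_bond <<- NA_character_
  }

  link_atom <- function(idx) {
    if (prev > 0L) {
      bt <- pending_bond
      if (is.na(bt)) bt <- "-"   # may be promoted to aromatic later
      if (bt == ":") bt <- "ar"
      if (bt %in% c("/", "\\")) bt <- "-"
      add_bond(prev, idx, bt)
    }
    pending_bond <<- NA_character_
    prev <<- idx
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (prev == 0L) stop("branch before any atom at position ", i)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unmatched ')' at position ", i)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% bond_chars) {
      pending_bond <- ch; i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L; pending_bond <- NA_character_; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (prev == 0L) stop("ring closure before any atom")
      close_ring(ch, prev); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %NN ring closure")
      dig <- paste0(chars[i + 1L], chars[i + 2L])
      if (!grepl("^[0-9]{2}$", dig)) stop("malformed %NN ring closure")
      close_ring(dig, prev); i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unmatched '[' in SMILES")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parse_bracket_atom(body)
      idx <- add_atom(at$element, at$aromatic, at$charge, at$h, at$isotope)
      link_atom(idx)
      i <- j + 1L
    } else {
      # organic-subset atom, possibly two characters (Cl, Br)
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        idx <- add_atom(two, FALSE); link_atom(idx); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        idx <- add_atom(ch, FALSE); link_atom(idx); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        idx <- add_atom(toupper(ch), TRUE); link_atom(idx); i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' at position ", i,
             " in SMILES '", smiles, "'")
      }
    }
  }
  if (length(stack) > 0L) stop("unclosed '(' in SMILES '", smiles, "'")
  if (length(ring) > 0L)
    stop("unclosed ring bond(s) ", paste(names(ring), collapse = ","),
         " in SMILES '", smiles, "'")
  if (length(el) == 0L) stop("no atoms in SMILES")

  mol <- structure(list(
    atoms = data.frame(element = el, aromatic = arom, charge = chg,
                       hexp = hexp, isotope = iso,
                       stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b1, a2 = b2, type = btype,
                       stringsAsFactors = FALSE)
  ), class = "chem_mol")
  mol <- .normalize_aromaticity(mol)
  .validate_mol(mol)
  mol
}

.parse_bracket_atom <- function(body) {
  m <- regmatches(body,
    regexec("^([0-9]*)([A-Za-z][a-z]?)(@{0,2}|@TH[12])?(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?(:[0-9]+)?$",
            body))[[1]]
  if (length(m) == 0L || m[1] != body)
    stop("cannot parse bracket atom [", body, "]")
  iso <- if (nzchar(m[2])) as.integer(m[2]) else NA_integer_
  sym <- m[3]
  aromatic <- sym %in% AROMATIC_ELEMS
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  } else sym
  h <- if (nzchar(m[5])) {
    if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
  } else 0L   # bracket atom with no H spec has zero hydrogens
  chg <- 0L
  if (nzchar(m[6])) {
    cs <- m[6]
    if (grepl("^[+-][0-9]+$", cs)) {
      chg <- as.integer(cs)
    } else {
      chg <- nchar(cs) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
    }
  }
  list(element = element, aromatic = aromatic, charge = chg,
       h = h, isotope = iso)
}

.validate_mol <- function(mol) {
  bad <- !(mol$atoms$element %in% names(DEFAULT_VALENCE)) &
    is.na(mol$atoms$hexp)
  if (any(bad))
    stop("element(s) outside supported set without explicit H count: ",
         paste(unique(mol$atoms$element[bad]), collapse = ","))
  invisible(mol)
}

# --- adjacency helpers -------------------------------------------------------

.mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  if (nrow(mol$bonds) == 0L) return(lapply(adj, function(x) integer()))
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], k)
    adj[[b]] <- c(adj[[b]], k)
  }
  lapply(adj, function(x) if (is.null(x)) integer() else x)
}

.bond_other <- function(mol, bond, atom) {
  a <- mol$bonds$a1[bond]
  if (a == atom) mol$bonds$a2[bond] else a
}

# --- aromaticity -------------------------------------------------------------

# Smallest ring through each bond (bounded at 7-membered); returns a list of
# integer atom cycles.  Adequate for the fused/simple 5- and 6-rings this
# package generates and consumes; macrocyclic aromaticity is out of scope.
.mol_rings <- function(mol, max_size = 7L) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(list())
  adj <- .mol_adjacency(mol)
  n <- nrow(mol$atoms)
  rings <- list()
  seen <- character()
  for (k in seq_len(nb)) {
    src <- mol$bonds$a1[k]; dst <- mol$bonds$a2[k]
    # BFS from src to dst avoiding bond k
    parent <- rep(NA_integer_, n); dist <- rep(NA_integer_, n)
    dist[src] <- 0L; queue <- src
    while (length(queue) > 0L && is.na(dist[dst])) {
      cur <- queue[1]; queue <- queue[-1]
      if (dist[cur] >= max_size - 1L) next
      for (bk in adj[[cur]]) {
        if (bk == k) next
        nxt <- .bond_other(mol, bk, cur)
        if (is.na(dist[nxt])) {
          dist[nxt] <- dist[cur] + 1L; parent[nxt] <- cur
          queue <- c(queue, nxt)
        }
      }
    }
    if (is.na(dist[dst])) next
    path <- dst
    while (path[length(path)] != src) path <- c(path, parent[path[length(path)]])
    if (length(path) > max_size) next
    key <- paste(sort(path), collapse = ",")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- path }
  }
  rings
}

# Promote Hueckel-aromatic Kekule rings to aromatic form and mark ring bonds
# between aromatic atoms as aromatic.  Operates in place on the graph.
.normalize_aromaticity <- function(mol) {
  rings <- .mol_rings(mol)
  if (length(rings) == 0L) return(mol)
  adj <- .mol_adjacency(mol)

  bond_between <- function(a, b) {
    for (k in adj[[a]]) if (.bond_other(mol, k, a) == b) return(k)
    NA_integer_
  }

  for (ring in rings) {
    sz <- length(ring)
    if (sz < 5L || sz > 6L) next
    ringbonds <- vapply(seq_len(sz), function(i)
      bond_between(ring[i], ring[i %% sz + 1L]), integer(1))
    if (anyNA(ringbonds)) next
    types <- mol$bonds$type[ringbonds]
    if (all(types == "ar") ||
        (all(mol$atoms$aromatic[ring]))) {
      mol$bonds$type[ringbonds] <- "ar"
      next
    }
    if (any(mol$atoms$aromatic[ring])) next  # mixed notation: leave as-is
    # Kekule candidate: count pi electrons
    pi_e <- 0L; ok <- TRUE
    for (a in ring) {
      elem <- mol$atoms$element[a]
      abonds <- adj[[a]]
      dbl_in_ring <- any(mol$bonds$type[intersect(abonds, ringbonds)] == "=")
      dbl_exo <- any(mol$bonds$type[setdiff(abonds, ringbonds)] %in% c("=", "#"))
      if (elem == "C") {
        if (dbl_in_ring) pi_e <- pi_e + 1L
        else { ok <- FALSE; break }   # exocyclic-double or sp3 carbon
      } else if (elem %in% c("N", "P")) {
        if (dbl_in_ring) pi_e <- pi_e + 1L else pi_e <- pi_e + 2L
      } else if (elem %in% c("O", "S")) {
        if (dbl_in_ring || dbl_exo) { ok <- FALSE; break }
        pi_e <- pi_e + 2L
      } else { ok <- FALSE; break }
    }
    if (!ok) next
    if (pi_e %% 4L != 2L) next
    mol$atoms$aromatic[ring] <- TRUE
    mol$bonds$type[ringbonds] <- "ar"
  }
  mol
}

# --- hydrogen counts and valence --------------------------------------------

#' Implicit hydrogen counts for every atom
#'
#' Bracket atoms carry their explicit count; organic-subset atoms get the
#' standard default-valence fill.  Aromatic atoms contribute one extra unit of
#' used valence for their pi system.
#'
#' @param mol a `chem_mol`.
#' @return integer vector, one entry per atom.
#' @export
mol_hcount <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- .mol_adjacency(mol)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(mol$atoms$hexp[i])) { out[i] <- mol$atoms$hexp[i]; next }
    types <- mol$bonds$type[adj[[i]]]
    n_ar <- sum(types == "ar")
    used <- sum(BOND_ORDER[types[types != "ar"]]) + n_ar +
      (if (n_ar > 0L || mol$atoms$aromatic[i]) 1L else 0L)
    dv <- DEFAULT_VALENCE[[mol$atoms$element[i]]]
    # second-row S/P hypervalence: bump to next standard valence if exceeded
    if (mol$atoms$element[i] == "S" && used > 2) dv <- if (used > 4) 6L else 4L
    if (mol$atoms$element[i] == "P" && used > 3) dv <- 5L
    out[i] <- max(0L, as.integer(round(dv - used + mol$atoms$charge[i] *
                                         (if (mol$atoms$element[i] %in% c("N", "O", "S", "P")) 1L else -1L))))
  }
  out
}

.mol_degree <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- integer(n)
  if (nrow(mol$bonds) > 0L) {
    t1 <- tabulate(mol$bonds$a1, nbins = n)
    t2 <- tabulate(mol$bonds$a2, nbins = n)
    deg <- t1 + t2
  }
  deg
}

.mol_in_ring <- function(mol) {
  rings <- .mol_rings(mol, max_size = 12L)
  inring <- logical(nrow(mol$atoms))
  for (r in rings) inring[r] <- TRUE
  inring
}

#' @export
print.chem_mol <- function(x, ...) {
  cat("<chem_mol> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds: ",
      smiles_write(x), "\n", sep = "")
  invisible(x)
}
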