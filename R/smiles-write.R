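# SMILES generation: canonical writing and traversal enumeration.
#
# The writer machinery renders a depth-first traversal of the molecular graph.
# Ring-closure digits are placed immediately after the atom token (before any
# branch parentheses), never reused, and carry their bond symbol only for
# double/triple closure bonds.  Single bonds are implicit except between two
# aromatic atoms that do not share an aromatic bond (biphenyl-type links).
# One traversal = one root atom + one neighbor ordering decided at visit time;
# the exhaustive enumerator explores every such traversal, which is also the
# degree of freedom the enumeration-based augmentation exploits.

# atom token for output; `mol_hc` is mol_hcount(mol) precomputed
.atom_token <- function(mol, i, mol_hc) {
  el <- mol$atoms$element[i]
  arom <- mol$atoms$aromatic[i]
  sym <- if (arom) tolower(el) else el
  bare_ok <- el %in% ORGANIC_SUBSET && mol$atoms$charge[i] == 0L &&
    is.na(mol$atoms$isotope[i])
  if (bare_ok && !is.na(mol$atoms$hexp[i])) {
    # bracket-specified H must match what the bare form would imply
    bare <- mol
    bare$atoms$hexp[i] <- NA_integer_
    bare_ok <- mol_hcount(bare)[i] == mol_hc[i]
  }
  if (bare_ok) return(sym)
  h <- mol_hc[i]
  hstr <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  chg <- mol$atoms$charge[i]
  cstr <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
          else sprintf("%+d", chg)
  istr <- if (is.na(mol$atoms$isotope[i])) "" else as.character(mol$atoms$isotope[i])
  paste0("[", istr, sym, hstr, cstr, "]")
}

.bond_symbol <- function(mol, k) {
  ty <- mol$bonds$type[k]
  if (ty == "=") return("=")
  if (ty == "#") return("#")
  if (ty == "ar") return("")
  # explicit single between two aromatic atoms (non-aromatic bond)
  if (mol$atoms$aromatic[mol$bonds$a1[k]] && mol$atoms$aromatic[mol$bonds$a2[k]])
    return("-")
  ""
}

.digit_token <- function(d) if (d <= 9L) as.character(d) else sprintf("%%%02d", d)

# Deterministic single-traversal writer.  `order_fn(bonds, state)` returns the
# bonds sorted into visiting order; closures are resolved before choices in
# ascending bond-index order.
.write_traversal <- function(mol, root, order_fn) {
  adj <- .mol_adjacency(mol)
  hc <- mol_hcount(mol)
  st <- list(
    em = list(),                       # emission items: int atom id or literal chr
    tok = vapply(seq_len(nrow(mol$atoms)), function(i)
      .atom_token(mol, i, hc), character(1)),
    visited = logical(nrow(mol$atoms)),
    used = logical(max(1L, nrow(mol$bonds))),
    nextdig = 1L
  )

  close_ring <- function(st, b, atom) {
    d <- st$nextdig; st$nextdig <- st$nextdig + 1L
    other <- .bond_other(mol, b, atom)
    sym <- mol$bonds$type[b]
    bsym <- if (sym %in% c("=", "#")) sym else ""
    st$tok[other] <- paste0(st$tok[other], bsym, .digit_token(d))
    st$tok[atom] <- paste0(st$tok[atom], bsym, .digit_token(d))
    st$used[b] <- TRUE
    st
  }

  visit <- function(atom, frombond, st) {
    st$visited[atom] <- TRUE
    st$em[[length(st$em) + 1L]] <- atom
    remaining <- setdiff(adj[[atom]], frombond)
    frags <- list()
    repeat {
      # resolve closures / consumed bonds before each choice
      drop <- logical(length(remaining))
      for (j in seq_along(remaining)) {
        b <- remaining[j]
        if (st$used[b]) { drop[j] <- TRUE; next }
        v <- .bond_other(mol, b, atom)
        if (st$visited[v]) { st <- close_ring(st, b, atom); drop[j] <- TRUE }
      }
      remaining <- remaining[!drop]
      if (length(remaining) == 0L) break
      remaining <- order_fn(remaining, atom, st)
      b <- remaining[1]; remaining <- remaining[-1]
      v <- .bond_other(mol, b, atom)
      st$used[b] <- TRUE
      stopifnot(!st$visited[v])
      start <- length(st$em) + 1L
      bs <- .bond_symbol(mol, b)
      if (nzchar(bs)) st$em[[length(st$em) + 1L]] <- bs
      st <- visit(v, b, st)
      frags[[length(frags) + 1L]] <- c(start, length(st$em))
    }
    # parenthesize all fragments but the last, back to front
    if (length(frags) >= 2L) {
      for (j in rev(seq_len(length(frags) - 1L))) {
        rg <- frags[[j]]
        st$em <- append(st$em, list(")"), after = rg[2])
        st$em <- append(st$em, list("("), after = rg[1] - 1L)
      }
    }
    st
  }

  st <- visit(root, NA_integer_, st)
  paste(vapply(st$em, function(it)
    if (is.character(it)) it else st$tok[[it]], character(1)), collapse = "")
}

#' Canonical atom ranks by iterative neighborhood refinement
#'
#' Morgan-style refinement of atom invariants (element, aromaticity, charge,
#' degree, hydrogen count, ring membership) followed by deterministic
#' tie-breaking.  Atoms left tied after refinement are treated as symmetry
#' equivalent.
#'
#' @param mol a `chem_mol`.
#' @return integer vector of distinct-unless-equivalent ranks (1-based).
#' @keywords internal
.canonical_ranks <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- .mol_adjacency(mol)
  hc <- mol_hcount(mol)
  inring <- .mol_in_ring(mol)
  key <- paste(mol$atoms$element, mol$atoms$aromatic, mol$atoms$charge,
               .mol_degree(mol), hc, inring,
               ifelse(is.na(mol$atoms$isotope), 0L, mol$atoms$isotope))
  rank <- match(key, sort(unique(key)))

  refine <- function(rank) {
    repeat {
      key <- vapply(seq_len(n), function(i) {
        nb <- vapply(adj[[i]], function(b) {
          sprintf("%s%04d", mol$bonds$type[b], rank[.bond_other(mol, b, i)])
        }, character(1))
        paste0(sprintf("%04d|", rank[i]), paste(sort(nb), collapse = ","))
      }, character(1))
      new <- match(key, sort(unique(key)))
      if (length(unique(new)) == length(unique(rank)) && all(new == rank)) break
      if (length(unique(new)) == length(unique(rank))) { rank <- new; break }
      rank <- new
    }
    rank
  }
  rank <- refine(rank)
  # tie-break: split the lowest tied class on its first member, re-refine
  repeat {
    tab <- table(rank)
    tied <- as.integer(names(tab)[tab > 1L])
    if (length(tied) == 0L) break
    cls <- min(tied)
    pick <- which(rank == cls)[1]
    rank <- rank * 2L
    rank[pick] <- rank[pick] - 1L
    rank <- match(rank, sort(unique(rank)))
    rank <- refine(rank)
  }
  rank
}

#' Canonicalize a SMILES string
#'
#' Parses the input, normalizes aromaticity, computes canonical atom ranks and
#' writes the unique representative string.  All equivalent orderings of the
#' same molecule map to one output, and the function is idempotent.
#'
#' @param smiles a single SMILES string.
#' @return a single canonical SMILES string.
#' @examples
#' canonicalize_smiles("C1=CC=CC=C1") == canonicalize_smiles("c1ccccc1")
#' @export
canonicalize_smiles <- function(smiles) {
  mol <- if (inherits(smiles, "chem_mol")) smiles else smiles_parse(smiles)
  rank <- .canonical_ranks(mol)
  root <- which.min(rank)
  .write_traversal(mol, root, function(bonds, atom, st) {
    bonds[order(rank[vapply(bonds, function(b)
      .bond_other(mol, b, atom), integer(1))], bonds)]
  })
}

#' Write a SMILES string for a molecular graph
#'
#' @param mol a `chem_mol`.
#' @param root optional root atom index; default is the canonical root.
#' @param random if `TRUE`, neighbor order is randomized (uses the current
#'   RNG state) -- one draw from the traversal-enumeration space.
#' @return a SMILES string.
#' @export
smiles_write <- function(mol, root = NULL, random = FALSE) {
  rank <- .canonical_ranks(mol)
  if (is.null(root)) root <- which.min(rank)
  if (random) {
    .write_traversal(mol, root, function(bonds, atom, st)
      if (length(bonds) > 1L) sample(bonds) else bonds)
  } else {
    .write_traversal(mol, root, function(bonds, atom, st) {
      bonds[order(rank[vapply(bonds, function(b)
        .bond_other(mol, b, atom), integer(1))], bonds)]
    })
  }
}

# Exhaustive traversal enumeration.  Returns all distinct strings over every
# root and every at-visit-time neighbor ordering; `limit` bounds the number of
# raw traversals explored (safety for large molecules).
.enumerate_exhaustive <- function(mol, limit = 10000L) {
  adj <- .mol_adjacency(mol)
  hc <- mol_hcount(mol)
  tok0 <- vapply(seq_len(nrow(mol$atoms)), function(i)
    .atom_token(mol, i, hc), character(1))
  out <- new.env(parent = emptyenv())
  count <- 0L
  overflow <- FALSE

  close_ring <- function(st, b, atom) {
    d <- st$nextdig; st$nextdig <- st$nextdig + 1L
    other <- .bond_other(mol, b, atom)
    bsym <- if (mol$bonds$type[b] %in% c("=", "#")) mol$bonds$type[b] else ""
    st$tok[other] <- paste0(st$tok[other], bsym, .digit_token(d))
    st$tok[atom] <- paste0(st$tok[atom], bsym, .digit_token(d))
    st$used[b] <- TRUE
    st
  }

  # returns a list of completed states for the subtree rooted at `atom`
  visit <- function(atom, frombond, st) {
    st$visited[atom] <- TRUE
    st$em[[length(st$em) + 1L]] <- atom
    seq_step(atom, setdiff(adj[[atom]], frombond), st, list())
  }

  finalize_atom <- function(st, frags) {
    if (length(frags) >= 2L) {
      for (j in rev(seq_len(length(frags) - 1L))) {
        rg <- frags[[j]]
        st$em <- append(st$em, list(")"), after = rg[2])
        st$em <- append(st$em, list("("), after = rg[1] - 1L)
      }
    }
    list(st)
  }

  seq_step <- function(atom, remaining, st, frags) {
    if (overflow) return(list())
    drop <- logical(length(remaining))
    for (j in seq_along(remaining)) {
      b <- remaining[j]
      if (st$used[b]) { drop[j] <- TRUE; next }
      if (st$visited[.bond_other(mol, b, atom)]) {
        st <- close_ring(st, b, atom); drop[j] <- TRUE
      }
    }
    remaining <- remaining[!drop]
    if (length(remaining) == 0L) return(finalize_atom(st, frags))
    res <- list()
    for (b in remaining) {
      st2 <- st
      st2$used[b] <- TRUE
      start <- length(st2$em) + 1L
      bs <- .bond_symbol(mol, b)
      if (nzchar(bs)) st2$em[[length(st2$em) + 1L]] <- bs
      subs <- visit(.bond_other(mol, b, atom), b, st2)
      for (st3 in subs) {
        res <- c(res, seq_step(atom, setdiff(remaining, b), st3,
                               c(frags, list(c(start, length(st3$em))))))
        if (overflow) return(res)
      }
    }
    res
  }

  n <- nrow(mol$atoms)
  for (root in seq_len(n)) {
    st0 <- list(em = list(), tok = tok0, visited = logical(n),
                used = logical(max(1L, nrow(mol$bonds))), nextdig = 1L)
    states <- visit(root, NA_integer_, st0)
    for (st in states) {
      count <- count + 1L
      if (count > limit) { overflow <- TRUE; break }
      s <- paste(vapply(st$em, function(it)
        if (is.character(it)) it else st$tok[[it]], character(1)), collapse = "")
      assign(s, TRUE, envir = out)
    }
    if (overflow) break
  }
  list(smiles = ls(out), overflow = overflow)
}

# Ring-closure depth rule: matching ring-closure digits must sit at the same
# parenthesis depth, i.e. a parenthesized branch never closes a ring opened
# outside it.  This is the convention of mainstream SMILES writers, and the
# enumeration space it induces is what gives the reference variant counts
# (144 for aspirin).
.ring_depth_ok <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  open <- list()
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      while (i <= n && chars[i] != "]") i <- i + 1L
    } else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == "%" || grepl("[0-9]", ch)) {
      if (ch == "%") { d <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 2L }
      else d <- ch
      if (is.null(open[[d]])) open[[d]] <- depth
      else {
        if (open[[d]] != depth) return(FALSE)
        open[[d]] <- NULL
      }
    }
    i <- i + 1L
  }
  TRUE
}

#' Enumerate equivalent SMILES representations of a molecule
#'
#' Generates the distinct grammar-valid SMILES strings reachable by varying
#' the root atom and the branch traversal order, deduplicated as strings.
#' With `max_variants = Inf` the set is exhaustive (subject to `limit`, a
#' safety cap on raw traversals -- if exceeded, the function falls back to
#' random sampling and warns).  With finite `max_variants`, random distinct
#' draws are returned, deterministic per `seed`.  Every output canonicalizes
#' to `canonicalize_smiles(smiles)`.
#'
#' @param smiles a SMILES string (or `chem_mol`).
#' @param max_variants maximum number of variants, `Inf` for exhaustive.
#' @param seed integer seed for sampled mode.
#' @param limit safety cap on raw traversals in exhaustive mode.
#' @return character vector of distinct SMILES strings (sorted in exhaustive
#'   mode; draw order in sampled mode).
#' @examples
#' length(enumerate_smiles("CC(=O)Oc1ccccc1C(=O)O"))  # 144 for aspirin
#' @export
enumerate_smiles <- function(smiles, max_variants = Inf, seed = 1L,
                             limit = 10000L) {
  mol <- if (inherits(smiles, "chem_mol")) smiles else smiles_parse(smiles)
  if (is.infinite(max_variants)) {
    res <- .enumerate_exhaustive(mol, limit = limit)
    if (!res$overflow)
      return(sort(res$smiles[vapply(res$smiles, .ring_depth_ok, logical(1))]))
    warning("traversal count exceeds limit (", limit,
            "); falling back to sampled enumeration")
    max_variants <- limit
  }
  if (max_variants < 1) stop("max_variants must be >= 1")
  rank <- .canonical_ranks(mol)
  n <- nrow(mol$atoms)
  found <- character()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  attempts <- 0L
  max_attempts <- 50L * max_variants + 200L
  while (length(found) < max_variants && attempts < max_attempts) {
    attempts <- attempts + 1L
    root <- sample.int(n, 1L)
    s <- .write_traversal(mol, root, function(bonds, atom, st)
      if (length(bonds) > 1L) sample(bonds) else bonds)
    if (.ring_depth_ok(s) && !(s %in% found)) found <- c(found, s)
  }
  found
}
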