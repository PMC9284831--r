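# Synthetic fixtures: planted-partition interaction networks and
# motif-structured SMILES libraries.
#
# The generators state a world in which every downstream stage is testable
# offline: proteins fall into communities (planted-partition protein-protein
# edges), each chemical cluster attaches to one community with high scores
# (true edges score 700-1000, noise edges 150-400, mirroring the 0-1000
# STITCH confidence convention), and each cluster's molecules share a
# substructure motif plus random small decorations.

#' Specification for a synthetic interaction-network fixture
#'
#' @param n_proteins total number of proteins.
#' @param n_communities number of planted protein communities.
#' @param n_clusters number of chemical clusters (`<= n_communities`).
#' @param chemicals_per_cluster integer vector of length `n_clusters`
#'   (imbalance allowed).
#' @param intra_community_edge_prob,inter_community_edge_prob planted-partition
#'   edge probabilities (`intra > inter`).
#' @param chem_attach_count proteins each chemical binds within its community.
#' @param noise_attach_count low-score off-community attachments per chemical.
#' @param score_range_high,score_range_low integer score bounds for true and
#'   noise edges.
#' @param motif_per_cluster character vector of SMILES fragments, one per
#'   cluster.
#' @param seed integer seed.
#' @return a validated `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 60L, n_communities = 4L,
                         n_clusters = 4L,
                         chemicals_per_cluster = rep(30L, 4L),
                         intra_community_edge_prob = 0.3,
                         inter_community_edge_prob = 0.01,
                         chem_attach_count = 5L,
                         noise_attach_count = 1L,
                         score_range_high = c(700L, 1000L),
                         score_range_low = c(150L, 400L),
                         motif_per_cluster = DEFAULT_MOTIFS[seq_len(n_clusters)],
                         seed = 1L) {
  spec <- list(n_proteins = as.integer(n_proteins),
               n_communities = as.integer(n_communities),
               n_clusters = as.integer(n_clusters),
               chemicals_per_cluster = as.integer(chemicals_per_cluster),
               intra_community_edge_prob = intra_community_edge_prob,
               inter_community_edge_prob = inter_community_edge_prob,
               chem_attach_count = as.integer(chem_attach_count),
               noise_attach_count = as.integer(noise_attach_count),
               score_range_high = as.integer(score_range_high),
               score_range_low = as.integer(score_range_low),
               motif_per_cluster = motif_per_cluster,
               seed = as.integer(seed))
  if (spec$n_proteins < 1L || spec$n_communities < 1L || spec$n_clusters < 1L)
    stop("counts must be positive")
  if (any(spec$chemicals_per_cluster < 1L))
    stop("chemicals_per_cluster entries must be positive")
  if (length(spec$chemicals_per_cluster) != spec$n_clusters)
    stop("chemicals_per_cluster must have one entry per cluster")
  if (length(spec$motif_per_cluster) != spec$n_clusters)
    stop("motif_per_cluster must have one motif per cluster")
  if (spec$n_clusters > spec$n_communities)
    stop("n_clusters must not exceed n_communities")
  for (p in c(spec$intra_community_edge_prob, spec$inter_community_edge_prob))
    if (is.na(p) || p < 0 || p > 1) stop("edge probabilities must be in [0,1]")
  if (spec$intra_community_edge_prob <= spec$inter_community_edge_prob)
    stop("intra_community_edge_prob must exceed inter_community_edge_prob")
  if (spec$chem_attach_count < 1L) stop("chem_attach_count must be positive")
  if (any(c(spec$score_range_high, spec$score_range_low) < 0L) ||
      any(c(spec$score_range_high, spec$score_range_low) > 1000L))
    stop("score ranges must lie in [0, 1000]")
  structure(spec, class = "fixture_spec")
}

#' Default cluster motifs: small, mutually distinguishable scaffolds
#' @export
DEFAULT_MOTIFS <- c("c1ccccc1",      # benzene
                    "C1CCCCC1",      # cyclohexane
                    "c1ccncc1",      # pyridine
                    "CC(=O)OC",      # ester chain
                    "C1CCOC1",       # tetrahydrofuran
                    "N#CCC#N")       # dinitrile chain

#' Generate a planted interaction network with ground truth
#'
#' Protein-protein edges follow a planted-partition model; each chemical of
#' cluster k binds `chem_attach_count` proteins of community k at high scores
#' and `noise_attach_count` off-community proteins at low scores.
#' Deterministic per `spec$seed`.
#'
#' @param spec a `fixture_spec`.
#' @return list with `graph` (an `interaction_graph`) and `truth` (list with
#'   `chemical` and `protein` named label vectors).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  rng <- .local_rng(spec$seed)
  prot_ids <- sprintf("PROT%04d", seq_len(spec$n_proteins))
  community <- stats::setNames(
    rep(seq_len(spec$n_communities), length.out = spec$n_proteins)[
      order(rep(seq_len(spec$n_communities),
                length.out = spec$n_proteins))], prot_ids)
  # protein-protein planted partition
  pairs <- utils::combn(spec$n_proteins, 2)
  same <- community[pairs[1, ]] == community[pairs[2, ]]
  p <- ifelse(same, spec$intra_community_edge_prob,
              spec$inter_community_edge_prob)
  draw <- rng$runif(ncol(pairs)) < p
  hi <- spec$score_range_high; lo <- spec$score_range_low
  score_hi <- function(n) hi[1] + rng$int(n, hi[2] - hi[1] + 1L) - 1L
  score_lo <- function(n) lo[1] + rng$int(n, lo[2] - lo[1] + 1L) - 1L
  pp <- data.frame(
    protein1 = prot_ids[pairs[1, draw]],
    protein2 = prot_ids[pairs[2, draw]],
    combined_score = ifelse(same[draw], score_hi(sum(draw)),
                            score_lo(sum(draw))),
    stringsAsFactors = FALSE)
  # chemical attachments
  chem_rows <- list(); chem_labels <- character()
  cid <- 0L
  for (k in seq_len(spec$n_clusters)) {
    comm_prot <- prot_ids[community == k]
    other_prot <- prot_ids[community != k]
    if (length(comm_prot) < spec$chem_attach_count)
      stop("community ", k, " has fewer proteins than chem_attach_count")
    for (j in seq_len(spec$chemicals_per_cluster[k])) {
      cid <- cid + 1L
      chem <- sprintf("CHEM%04d", cid)
      chem_labels[chem] <- paste0("cluster", k)
      targ <- comm_prot[rng$sample(length(comm_prot), spec$chem_attach_count)]
      rows <- data.frame(chemical = chem, protein = targ,
                         combined_score = score_hi(length(targ)),
                         stringsAsFactors = FALSE)
      if (spec$noise_attach_count > 0L && length(other_prot) > 0L) {
        noise <- other_prot[rng$sample(length(other_prot),
                                       min(spec$noise_attach_count,
                                           length(other_prot)))]
        rows <- rbind(rows, data.frame(
          chemical = chem, protein = noise,
          combined_score = score_lo(length(noise)),
          stringsAsFactors = FALSE))
      }
      chem_rows[[chem]] <- rows
    }
  }
  cp <- do.call(rbind, unname(chem_rows))
  list(graph = interaction_graph(cp, pp),
       truth = list(chemical = chem_labels, protein = community))
}

SUBSTITUENT_ALPHABET <- c("F", "Cl", "OC", "N", "CC")

#' Generate a motif-structured SMILES library for planted clusters
#'
#' Every chemical's molecule contains its cluster's motif as a substructure
#' (by construction: the motif graph is the scaffold) decorated with 0-3
#' random substituents from a fixed small alphabet at valence-legal
#' positions.  Deterministic per seed; all outputs are valid, canonicalizable
#' SMILES of molecules under 30 heavy atoms.
#'
#' @param truth ground truth from [generate_network()] (or any named
#'   chemical -> cluster label vector).
#' @param motifs named or positional character vector of SMILES fragments,
#'   one per cluster label (names are cluster labels; unnamed vectors are
#'   matched to sorted labels).
#' @param seed integer seed.
#' @return data.frame with columns `id`, `smiles`, `cluster`.
#' @export
generate_smiles_library <- function(truth, motifs, seed = 1L) {
  labels <- if (is.list(truth)) truth$chemical else truth
  ulab <- sort(unique(labels))
  if (is.null(names(motifs))) {
    if (length(motifs) != length(ulab))
      stop("need one motif per cluster label")
    names(motifs) <- ulab
  }
  mols <- lapply(motifs, smiles_parse)  # validates fragments up front
  rng <- .local_rng(seed)
  out <- data.frame(id = names(labels), smiles = NA_character_,
                    cluster = unname(labels), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    mol <- mols[[labels[i]]]
    n_sub <- rng$int(1L, 4L) - 1L          # 0-3 substituents
    for (s in seq_len(n_sub)) {
      hc <- mol_hcount(mol)
      sites <- which(hc >= 1L)
      if (length(sites) == 0L) break
      site <- sites[rng$sample(length(sites), 1L)]
      frag <- SUBSTITUENT_ALPHABET[rng$sample(length(SUBSTITUENT_ALPHABET), 1L)]
      mol <- .attach_fragment(mol, site, frag)
    }
    out$smiles[i] <- canonicalize_smiles(mol)
  }
  out
}

# attach the first atom of `frag_smiles` to atom `site` with a single bond
.attach_fragment <- function(mol, site, frag_smiles) {
  frag <- smiles_parse(frag_smiles)
  off <- nrow(mol$atoms)
  mol$atoms <- rbind(mol$atoms, frag$atoms)
  if (nrow(frag$bonds) > 0L) {
    fb <- frag$bonds
    fb$a1 <- fb$a1 + off; fb$a2 <- fb$a2 + off
    mol$bonds <- rbind(mol$bonds, fb)
  }
  mol$bonds <- rbind(mol$bonds,
                     data.frame(a1 = site, a2 = off + 1L, type = "-",
                                stringsAsFactors = FALSE))
  mol
}

#' Write a complete fixture to disk
#'
#' Emits STITCH-style and STRING-style TSVs, a `.smi` file
#' (`SMILES<TAB>id` per line) and a labels CSV (`id,cluster`).
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_network(spec)
  lib <- generate_smiles_library(net$truth, spec$motif_per_cluster,
                                 seed = spec$seed)
  paths <- list(
    cp = file.path(dir, "chemical_protein.tsv"),
    pp = file.path(dir, "protein_protein.tsv"),
    smi = file.path(dir, "library.smi"),
    labels = file.path(dir, "labels.csv"))
  write_interactions(net$graph, paths$cp, paths$pp)
  writeLines(paste(lib$smiles, lib$id, sep = "\t"), paths$smi)
  utils::write.csv(lib[c("id", "cluster")], paths$labels,
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a `.smi` file (`SMILES<TAB>id` per line)
#'
#' @param path file path.
#' @return data.frame with columns `id`, `smiles`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(id = vapply(parts, `[`, character(1), 2),
             smiles = vapply(parts, `[`, character(1), 1),
             stringsAsFactors = FALSE)
}
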