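# Biological-distance clustering from chemical-protein interaction networks.
#
# Pipeline: scored edge tables -> per-chemical protein profiles (direct edges
# plus one-step propagation through the protein-protein network) -> cosine
# distance matrix -> hierarchical clustering cut at a fixed threshold ->
# support filter -> protein-set annotation at a high (Qcutoff) and a low
# (Lcutoff) confidence cutoff.

#' Construct an interaction graph from edge tables
#'
#' @param cp data.frame with columns `chemical`, `protein`, `combined_score`.
#' @param pp data.frame with columns `protein1`, `protein2`, `combined_score`.
#' @return an `interaction_graph`: list of the two normalized edge tables.
#'   Protein-protein edges are stored undirected (lexicographically ordered
#'   endpoints), duplicates collapse to the maximum score, self-loops dropped.
#' @export
interaction_graph <- function(cp, pp) {
  stopifnot(all(c("chemical", "protein", "combined_score") %in% names(cp)),
            all(c("protein1", "protein2", "combined_score") %in% names(pp)))
  for (sc in list(cp$combined_score, pp$combined_score)) {
    if (length(sc) && (any(is.na(sc)) || any(sc != round(sc)) ||
                       any(sc < 0 | sc > 1000)))
      stop("combined_score must be integers in [0, 1000]")
  }
  cp <- data.frame(chemical = as.character(cp$chemical),
                   protein = as.character(cp$protein),
                   combined_score = as.integer(cp$combined_score),
                   stringsAsFactors = FALSE)
  cp <- cp[order(cp$chemical, cp$protein, -cp$combined_score), ]
  cp <- cp[!duplicated(cp[c("chemical", "protein")]), ]
  p1 <- pmin(as.character(pp$protein1), as.character(pp$protein2))
  p2 <- pmax(as.character(pp$protein1), as.character(pp$protein2))
  pp <- data.frame(protein1 = p1, protein2 = p2,
                   combined_score = as.integer(pp$combined_score),
                   stringsAsFactors = FALSE)
  pp <- pp[pp$protein1 != pp$protein2, ]
  pp <- pp[order(pp$protein1, pp$protein2, -pp$combined_score), ]
  pp <- pp[!duplicated(pp[c("protein1", "protein2")]), ]
  rownames(cp) <- rownames(pp) <- NULL
  structure(list(chem_protein = cp, protein_protein = pp),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("<interaction_graph> ", nrow(x$chem_protein), " chemical-protein and ",
      nrow(x$protein_protein), " protein-protein edges; ",
      length(unique(x$chem_protein$chemical)), " chemicals\n", sep = "")
  invisible(x)
}

#' Read STITCH-style and STRING-style edge tables
#'
#' @param cp_path TSV with header `chemical<TAB>protein<TAB>combined_score`.
#' @param pp_path TSV with header `protein1<TAB>protein2<TAB>combined_score`.
#' @param quality_cutoff minimum score for an edge to be retained (applied to
#'   both tables); default 150, the permissive end of the STITCH convention.
#' @return an `interaction_graph`.
#' @export
read_interactions <- function(cp_path, pp_path, quality_cutoff = 150L) {
  cp <- as.data.frame(data.table::fread(cp_path, sep = "\t",
                                        colClasses = "character"))
  pp <- as.data.frame(data.table::fread(pp_path, sep = "\t",
                                        colClasses = "character"))
  need_cp <- c("chemical", "protein", "combined_score")
  need_pp <- c("protein1", "protein2", "combined_score")
  if (!all(need_cp %in% names(cp)))
    stop("chemical-protein table must have columns ",
         paste(need_cp, collapse = ", "))
  if (!all(need_pp %in% names(pp)))
    stop("protein-protein table must have columns ",
         paste(need_pp, collapse = ", "))
  for (tab in c("cp", "pp")) {
    x <- get(tab)
    if (any(!grepl("^[0-9]+$", x$combined_score)))
      stop("non-integer combined_score in ", tab, " table")
  }
  cp$combined_score <- as.integer(cp$combined_score)
  pp$combined_score <- as.integer(pp$combined_score)
  g <- interaction_graph(cp, pp)
  g$chem_protein <- g$chem_protein[g$chem_protein$combined_score >=
                                     quality_cutoff, ]
  g$protein_protein <- g$protein_protein[g$protein_protein$combined_score >=
                                           quality_cutoff, ]
  rownames(g$chem_protein) <- rownames(g$protein_protein) <- NULL
  g
}

#' Write an interaction graph as STITCH/STRING-style TSV files
#'
#' @param graph an `interaction_graph`.
#' @param cp_path,pp_path output paths.
#' @export
write_interactions <- function(graph, cp_path, pp_path) {
  utils::write.table(graph$chem_protein, cp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph$protein_protein, pp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(cp_path, pp_path))
}

#' Build per-chemical network profiles
#'
#' The profile of a chemical is a sparse protein-weight vector: the normalized
#' direct edge score (score/1000) for each directly bound protein, plus
#' `propagation_weight * (direct/1000) * (ppi/1000)` for every one-step
#' protein-protein neighbor of a direct target, summed over paths.  Profiles
#' are L2-normalized.  This is the package's concrete stand-in for a network
#' topology distance: chemicals are close when they share direct targets
#' and/or pathway context.
#'
#' @param graph an `interaction_graph`.
#' @param propagation_weight weight of the one-step propagation term in
#'   `[0, 1]`; 0 uses direct targets only.  Default 0.5.
#' @return a `chem_profiles` object: named list of named numeric vectors.
#' @export
build_profiles <- function(graph, propagation_weight = 0.5) {
  stopifnot(propagation_weight >= 0, propagation_weight <= 1)
  cp <- graph$chem_protein
  if (nrow(cp) == 0L) {
    warning("no qualifying chemical-protein edges; empty profile set")
    return(structure(list(), class = "chem_profiles"))
  }
  pp <- graph$protein_protein
  nbrs <- new.env(parent = emptyenv())
  if (nrow(pp) > 0L) for (k in seq_len(nrow(pp))) {
    a <- pp$protein1[k]; b <- pp$protein2[k]; w <- pp$combined_score[k] / 1000
    nbrs[[a]] <- rbind(nbrs[[a]], data.frame(p = b, w = w))
    nbrs[[b]] <- rbind(nbrs[[b]], data.frame(p = a, w = w))
  }
  profiles <- lapply(split(cp, cp$chemical), function(ed) {
    acc <- new.env(parent = emptyenv())
    bump <- function(p, v)
      assign(p, (if (is.null(acc[[p]])) 0 else acc[[p]]) + v, envir = acc)
    for (k in seq_len(nrow(ed))) {
      p <- ed$protein[k]; s <- ed$combined_score[k] / 1000
      bump(p, s)
      nb <- nbrs[[p]]
      if (propagation_weight > 0 && !is.null(nb))
        for (j in seq_len(nrow(nb)))
          bump(nb$p[j], propagation_weight * s * nb$w[j])
    }
    v <- vapply(ls(acc), function(p) acc[[p]], numeric(1))
    v / sqrt(sum(v^2))
  })
  structure(profiles, class = "chem_profiles")
}

#' Cosine distance matrix between chemical profiles
#'
#' @param profiles a `chem_profiles` object (>= 2 profiles).
#' @return symmetric matrix of `1 - cosine` distances in `[0, 1]` with zero
#'   diagonal, dimnames set to the chemical ids (sorted).
#' @export
compute_distance_matrix <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  ids <- sort(names(profiles))
  prots <- sort(unique(unlist(lapply(profiles, names))))
  M <- matrix(0, nrow = length(ids), ncol = length(prots),
              dimnames = list(ids, prots))
  for (id in ids) M[id, names(profiles[[id]])] <- profiles[[id]]
  M <- M / sqrt(rowSums(M^2))
  D <- 1 - tcrossprod(M)
  D[D < 0] <- 0; D[D > 1] <- 1
  diag(D) <- 0
  D
}

#' Hierarchical clustering of a distance matrix at a fixed threshold
#'
#' @param dist symmetric distance matrix with chemical-id dimnames.
#' @param threshold cut height in `(0, 1)`.
#' @param linkage_method one of `"average"` (default), `"single"`,
#'   `"complete"`.
#' @return a `chem_clustering`: list with `threshold`, `assignment` (named
#'   integer vector), `support` (member counts), `hclust` (retained linkage),
#'   and `cophenetic` (matrix for inter-cluster distance queries).  Cluster
#'   ids are assigned in order of each cluster's smallest member id.
#' @export
hierarchical_cluster <- function(dist, threshold,
                                 linkage_method = "average") {
  if (!(linkage_method %in% c("average", "single", "complete")))
    stop("unsupported linkage method '", linkage_method, "'")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  hc <- stats::hclust(stats::as.dist(dist), method = linkage_method)
  raw <- stats::cutree(hc, h = threshold)
  # stable ids: order clusters by their smallest member id
  first <- tapply(names(raw), raw, function(x) min(x))
  remap <- stats::setNames(seq_along(first), names(first)[order(first)])
  assignment <- stats::setNames(as.integer(remap[as.character(raw)]),
                                names(raw))
  structure(list(
    threshold = threshold,
    assignment = assignment,
    support = table(assignment),
    hclust = hc,
    cophenetic = as.matrix(stats::cophenetic(hc))
  ), class = "chem_clustering")
}

#' @export
print.chem_clustering <- function(x, ...) {
  cat("<chem_clustering> ", length(x$assignment), " chemicals in ",
      length(x$support), " clusters (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Filter clusters by support
#'
#' Keeps clusters with strictly more than `min_support` members; everything
#' else goes to the discard list.
#'
#' @param clustering a `chem_clustering`.
#' @param min_support support threshold (strict inequality); default 100.
#' @return the filtered `chem_clustering`, with a `discarded` character vector
#'   of removed chemical ids.  Cluster ids are preserved (not renumbered) so
#'   linkage-based distance queries remain valid.
#' @export
filter_by_support <- function(clustering, min_support = 100L) {
  keep_cl <- as.integer(names(clustering$support)[
    clustering$support > min_support])
  keep <- clustering$assignment %in% keep_cl
  out <- clustering
  out$discarded <- names(clustering$assignment)[!keep]
  out$assignment <- clustering$assignment[keep]
  out$support <- table(out$assignment)
  out
}

#' Annotate clusters with protein sets at a score cutoff
#'
#' A cluster's protein set is the union over its member chemicals of proteins
#' bound with edge score at least `score_cutoff`.  Lowering the cutoff never
#' shrinks any set, which is the Qcutoff/Lcutoff monotonicity the two-level
#' annotation relies on.
#'
#' @param clustering a `chem_clustering`.
#' @param graph an `interaction_graph`.
#' @param score_cutoff integer score threshold (e.g. 700 for Qcutoff, 400 for
#'   Lcutoff).
#' @return a `cluster_annotation`: list with `proteins` (cluster id ->
#'   character vector) and `cutoff_used`.
#' @export
annotate_cluster <- function(clustering, graph, score_cutoff) {
  cp <- graph$chem_protein[graph$chem_protein$combined_score >= score_cutoff, ]
  missing <- setdiff(names(clustering$assignment),
                     unique(graph$chem_protein$chemical))
  if (length(missing) > 0L)
    message(length(missing), " clustered chemical(s) absent from the graph; skipped")
  prot <- lapply(split(names(clustering$assignment), clustering$assignment),
                 function(members)
                   sort(unique(cp$protein[cp$chemical %in% members])))
  structure(list(proteins = prot, cutoff_used = as.integer(score_cutoff)),
            class = "cluster_annotation")
}

#' Cophenetic distance between two clusters
#'
#' The merge height at which the two clusters first join on the retained
#' linkage tree.  Flat clusters cut from the tree are subtrees, so the
#' cophenetic distance is constant across member pairs; a representative
#' member of each cluster is used.
#'
#' @param clustering a `chem_clustering` (must retain its linkage).
#' @param cid_a,cid_b cluster ids.
#' @return a single distance; 0 when `cid_a == cid_b`.
#' @export
cluster_distance <- function(clustering, cid_a, cid_b) {
  for (cid in c(cid_a, cid_b))
    if (!(cid %in% clustering$assignment))
      stop("unknown cluster id ", cid)
  if (cid_a == cid_b) return(0)
  a <- names(clustering$assignment)[clustering$assignment == cid_a][1]
  b <- names(clustering$assignment)[clustering$assignment == cid_b][1]
  clustering$cophenetic[a, b]
}

#' Write a clustering as CSV and its annotation as TSV
#'
#' @param clustering a `chem_clustering`.
#' @param path output CSV path (columns `id`, `cluster`).
#' @export
write_clustering <- function(clustering, path) {
  utils::write.csv(data.frame(id = names(clustering$assignment),
                              cluster = unname(clustering$assignment)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
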