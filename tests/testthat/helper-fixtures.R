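# Shared fixtures, built once per test run.  Everything is generated in code;
# sizes are desk-scale so the whole suite stays well under the time budget.

ASPIRIN <- "CC(=O)Oc1ccccc1C(=O)O"

# small planted-network world: 4 balanced clusters of 12 chemicals
fx_spec <- fixture_spec(n_proteins = 40L, n_communities = 4L, n_clusters = 4L,
                        chemicals_per_cluster = rep(12L, 4L),
                        chem_attach_count = 4L, seed = 11L)
fx_net <- generate_network(fx_spec)
fx_lib <- generate_smiles_library(fx_net$truth, fx_spec$motif_per_cluster,
                                  seed = 11L)

# >1000 random valid SMILES: sampled traversal variants of the library
# molecules plus the full aspirin and toluene-phenol enumeration spaces
fx_variants <- local({
  out <- character()
  for (i in seq_len(nrow(fx_lib))) {
    out <- c(out, enumerate_smiles(fx_lib$smiles[i], max_variants = 25L,
                                   seed = 100L + i))
  }
  c(out, enumerate_smiles(ASPIRIN), enumerate_smiles("Cc1ccccc1O"),
    enumerate_smiles("CCC(=O)Oc1ccccc1C(=O)O"),
    enumerate_smiles("CC(=O)Oc1ccc(Cl)cc1"))
})

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sa <- sum(choose(rowSums(tab), 2)); sb <- sum(choose(colSums(tab), 2))
  sab <- sum(choose(tab, 2)); n <- sum(tab)
  expected <- sa * sb / choose(n, 2)
  (sab - expected) / ((sa + sb) / 2 - expected)
}

# tiny 2-class labeled set used by model conformance tests
fx_tiny <- local({
  idx <- fx_lib$cluster %in% c("cluster1", "cluster2")
  df <- fx_lib[idx, ]
  df[seq_len(20), ]
})
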