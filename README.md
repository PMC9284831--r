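# chemclust

Chemicals with similar biological function touch similar proteins.
`chemclust` turns that observation into a working pipeline for R:

1. **Function from networks.** From scored chemical–protein (STITCH-style)
   and protein–protein (STRING-style) edge tables, each chemical gets a
   protein profile — direct targets plus one-step network propagation —
   and chemicals are compared by cosine distance of those profiles:

   *w<sub>c</sub>(p) = s<sub>cp</sub>/1000 + λ · Σ<sub>q</sub>
   (s<sub>cq</sub>/1000)(s<sub>qp</sub>/1000)*,
   &nbsp; *d(a,b) = 1 − cos(w<sub>a</sub>, w<sub>b</sub>)*.

   Hierarchical clustering cut at a fixed threshold, a support filter
   (clusters with **more than** `min_support` members survive), and
   protein-set annotation at a high (Qcutoff) and a permissive (Lcutoff)
   score cutoff produce labeled functional clusters.

2. **Structure to function.** Classifiers trained only on structure assign
   new compounds to those clusters: a fully connected net on 1024-bit
   radius-2 Morgan fingerprints, a 1-D CNN on 42 × L per-character feature
   matrices, a 3-layer LSTM encoder on token sequences (atom-wise or
   learned pair-encoding tokenization), and a fine-tuned LSTM language
   model (DropConnect, averaging trigger, gradual unfreezing).  Class
   imbalance is corrected by class-wise SMILES augmentation: equivalent
   SMILES spellings generated by exhaustive traversal enumeration
   (aspirin has exactly 144).  Architectures are compared by fold-wise
   macro F1 with paired sign-flip randomization tests.

Everything — including a SMILES parser, canonicalizer, enumerator and the
neural networks — is implemented in plain R with no compiled or GPU
dependencies, and a synthetic-fixture module makes the whole pipeline
testable offline.

## Worked example

```r
library(chemclust)

spec <- fixture_spec(seed = 7)                      # 4 clusters x 30 chemicals
net  <- generate_network(spec)
prof <- build_profiles(net$graph, propagation_weight = 0.5)
D    <- compute_distance_matrix(prof)
cl   <- filter_by_support(hierarchical_cluster(D, 0.5), 10)
cl
#> <chem_clustering> 120 chemicals in 4 clusters (threshold 0.5)

lib <- generate_smiles_library(net$truth, spec$motif_per_cluster, seed = 7)
sp  <- make_tvt(lib$id, lib$cluster, seed = 7)      # stratified 80/10/10
tr  <- lib[lib$id %in% c(sp$train, sp$validation), ]
te  <- lib[lib$id %in% sp$test, ]

enc <- encode_dataset(tr$smiles, tr$cluster, "fingerprint")
m   <- train_classifier(enc, desk_config("dnn", epochs = 30, seed = 1))
f1  <- f1_scores(te$cluster, predict(m, encode_like(enc, te$smiles)))
sprintf("held-out macro F1: %.3f", f1$macro)
#> "held-out macro F1: 1.000"

q <- annotate_cluster(cl, net$graph, 700)           # Qcutoff protein sets
l <- annotate_cluster(cl, net$graph, 400)           # Lcutoff protein sets
rep <- predict_and_annotate(m, c(demo = te$smiles[1]), cl, q, l, top_k = 3)
rep$predictions$demo$top[, c("cluster", "probability")]
#>    cluster  probability
#> 1 cluster1 0.9964419115
#> 2 cluster3 0.0025200250
#> 3 cluster4 0.0006263915

length(enumerate_smiles("CC(=O)Oc1ccccc1C(=O)O"))   # aspirin variants
#> 144
```

The demo molecules carry cluster-specific substructure motifs by
construction, so a perfect held-out F1 says the pipeline works, not that
real chemistry is this easy; see `vignettes/methods.Rmd` for what the
synthetic world does and does not establish.

## Command line

A thin CLI ships in `inst/cli/chemclust`:

```sh
Rscript inst/cli/chemclust fixtures --out fixture_dir --seed 1
Rscript inst/cli/chemclust cluster  --cp fixture_dir/chemical_protein.tsv \
        --pp fixture_dir/protein_protein.tsv --threshold 0.5 \
        --min-support 10 --out out_dir
Rscript inst/cli/chemclust encode   --scheme fingerprint \
        --in fixture_dir/library.smi --out encoded_dir
Rscript inst/cli/chemclust augment  --in labeled.csv --k 5 --seed 7 \
        --out augmented.csv
```

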