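# orthoclust

Identify clusters of orthologous DNA sequences from a GenBank-like
corpus **without relying on gene names**.

Name-based sequence retrieval breaks on the realities of public
repositories: one marker deposited under many names (COI / CO1 / COX1 /
COXI), different regions under one name, mislabeled and chimeric
records. orthoclust determines orthology from sequence similarity
instead. For a user-chosen root taxon it

1. **taxise** — resolves the taxon in an NCBI-taxdump-style taxonomy and
   partitions its subtree into clade work units of at most 50,000
   sequences and 100,000 nodes (smaller clades pooled *paraphyletically*
   so no taxon is dropped);
2. **download** — pulls records per unit from a pluggable source
   (annotated FASTA or GenBank flat file), keeps sequences in the
   250–3000 nt window, rescues over-long records by slicing annotated
   gene/CDS/rRNA features into segments, and caps over-sequenced model
   organisms by seeded random subsampling;
3. **cluster** — runs all-vs-all similarity search within each unit
   (built-in aligner backend, or BLAST+), filters hits (e-value ≤ 1e-10,
   query coverage ≥ 0.5, union-symmetrized) and takes single-linkage
   clusters = connected components of the hit graph, recording each
   cluster's most connected member as its *seed*;
4. **cluster²** — searches only the seeds against each other and merges
   clusters whose seeds hit, reconnecting gene families split across
   clade units.

A selection toolkit then filters clusters for supermatrix construction:
**MAD** (maximum alignment density, `sum(len) / (n · max(len))`,
in (0, 1], 1 iff all members equal length), GC and ambiguity metrics,
phylogenetic informativeness (> 4 unique taxa), top-*k* by rank-group
coverage, per-rank representative selection, presence/absence matrices,
and export as PhyLoTa-style tables plus FASTA. A synthetic-corpus
generator (ranked taxonomy + gene families evolved under i.i.d.
substitutions, with optional model-organism/mislabeled/chimeric/long
decoys) makes every stage testable offline against known truth.

## Worked example

```r
library(orthoclust)

corpus_dir <- file.path(tempdir(), "corpus")
sim <- simulate_corpus(sim_config(rng_seed = 7), out_dir = corpus_dir)

cfg <- run_config(
  root_taxon   = "Simulandia",
  wd           = file.path(tempdir(), "run"),
  nodes_path   = file.path(corpus_dir, "nodes.dmp"),
  names_path   = file.path(corpus_dir, "names.dmp"),
  records_path = file.path(corpus_dir, "records.fasta"),
  seed         = 7)
clusters <- run_pipeline(cfg)
#> Pipeline summary
#>   taxa with sequences: 20
#>   segments: 200
#>   reported clusters: 10
#>     subtree: 10
#>     paraphyletic: 0
#>     direct: 0
#>     merged: 0
```

The default corpus plants 10 gene families across 20 species; the
pipeline recovers exactly 10 subtree clusters (one per family — the
run's `results/` directory holds the exported tables and per-cluster
FASTA). Selection then mirrors a typical demonstration recipe — MAD at
least 0.75, more than four unique taxa, best clusters by genus
coverage:

```r
best <- filter_clusters(clusters, min_mad = 0.75, min_taxa = 5,
                        top_k = 3, top_by = "n_rank_groups",
                        rank = "genus")
cluster_stats(best)[, c("cluster_id", "kind", "n_segments",
                        "n_unique_taxids", "n_genera", "mad")]
#>   cluster_id    kind n_segments n_unique_taxids n_genera mad
#> 1          0 subtree         20              20        7   1
#> 2          1 subtree         20              20        7   1
#> 3          2 subtree         20              20        7   1

presence_absence(best, rank = "genus")
#>        0 1 2
#> Genus1 1 1 1
#> Genus2 1 1 1
#> ...
```

Each selected cluster holds all 20 species across all 7 genera
(`mad = 1` because the generator introduces no indels, so family
members share their root's length). `representatives_per_rank()`
reduces clusters to the best 2 sequences per genus and
`export_clusters()` writes the tables/FASTA for alignment and tree
building. A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/orthoclust.R run --taxon Simulandia --wd run/ \
    --nodes nodes.dmp --names names.dmp --records records.fasta --seed 7
Rscript inst/scripts/orthoclust.R export --wd run/ --out sel/ \
    --min-mad 0.75 --min-taxa 5 --top 10 --reps 2
```

Runs are cached per clade unit and restartable:
`restart_pipeline(wd)` resumes an interrupted run and reproduces the
uninterrupted run's exports byte for byte.

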