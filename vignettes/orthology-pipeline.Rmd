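---
title: "Identifying orthologous sequence clusters without gene names"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying orthologous sequence clusters without gene names}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoclust)
```

## The problem

Assembling a multi-gene supermatrix from a public sequence repository
starts with a deceptively hard step: deciding which deposited sequences
are orthologous. Name-based retrieval is fragile — the same marker is
deposited as COI, CO1, COX1 or COXI; different regions share one name;
records are mislabeled or chimeric. orthoclust instead determines
orthology from the sequences themselves: all-vs-all similarity search
within taxonomically bounded groups, single-linkage clustering of the
filtered hit graph, and a second, seed-level search that reconnects
clusters across those groups. No gene name is consulted at any point.

## The pipeline

The pipeline runs as four independent, individually cached stages.

**taxise.** The taxonomy (NCBI taxdump dialect: `nodes.dmp`,
`names.dmp`) is loaded, the user's root taxon is resolved (by name,
case-insensitively and with homonyms treated as errors, or by id), and
the root's subtree is partitioned into *clade units*. A clade whose
whole subtree holds at most `max_seqs` sequences (default 50,000) and
`max_nodes` taxonomy nodes (default 100,000) becomes one *subtree*
unit. Larger clades are split into their children recursively; when a
node is split, its directly assigned sequences and any child subtrees
too small to stand alone (fewer than `min_unit_seqs = 3` sequences —
below that no reportable within-clade cluster can form) are pooled into
one *paraphyletic* unit owned by the split node, chunked if necessary so
pooled units also respect `max_seqs`. Every sequence-bearing taxon lands
in exactly one unit; this invariant is property-tested against a
brute-force subtree-sum oracle.

**download.** Records for each unit are fetched from a pluggable record
source — an annotated-FASTA reader, a GenBank flat-file reader (the
LOCUS/DEFINITION/FEATURES/ORIGIN subset, with 1-based inclusive spans
converted to the internal 0-based half-open convention at parse time),
or any object honoring the same two-function contract. Records inside
the length window (`min_len = 250`, `max_len = 3000` nt — bracketing
typical phylogenetic markers) become whole-record segments. Over-long
records are not discarded: each annotated gene/CDS/rRNA feature whose
span fits the window is sliced out as its own segment, overlapping
features deduplicated (earlier-starting, then longer, wins),
reverse-strand features reverse-complemented into canonical orientation
with an `:rc` id suffix. Finally, taxa with more than `cap = 100`
segments — over-sequenced model organisms — are down-sampled uniformly
at random with the run's seeded generator, so results are reproducible.

**cluster.** Within each unit, all segments are searched all-vs-all.
Hits are filtered (`evalue_max = 1e-10`, query coverage ≥ 0.5, no
identity floor by default) and symmetrized by union: an undirected edge
survives if either direction passes, so a short fragment aligned
full-length to a long sequence keeps its edge even though coverage on
the long side is poor. Clusters are the connected components
(single-linkage: no density parameter, one passing hit joins two
segments), computed by union-find and verified exactly against a
brute-force transitive-closure oracle. Each component's *seed* is its
most connected member (degree, then summed bitscore, then length, then
id). Subtree units yield *subtree* clusters plus, for every taxon, the
restriction of each component to that taxon's own segments as a
*direct* cluster — the same edge evidence, no extra search; we restrict
membership rather than re-running components within the restriction,
since single linkage inside one taxon's segments would depend on edges
through other taxa anyway. Components smaller than
`min_cluster_seqs = 3` are retained but flagged `below_threshold`, and
excluded from default reporting rather than deleted, preserving
auditability.

**cluster².** Only the seed of each cluster is searched against the
other seeds — this is what keeps the cross-clade step affordable. A
passing seed-to-seed hit draws an edge between the owning clusters;
components of two or more clusters become *merged* clusters whose
membership is the exact union of their parents. Parents are retained
and flagged, so merged and non-merged clusters are reported together.
Direct clusters sit out this stage (they are restrictions of subtree
clusters and would merge trivially with their own parents). The merged
cluster's seed is the parent seed with the highest degree among the
seed-level edges — without a full within-merged-cluster search no
better-informed choice exists — and its owning taxon is the parents'
most recent common ancestor. One merge round is the default;
`fixpoint = TRUE` iterates to closure.

## Search backends

Two backends honor one contract (directed hits in BLAST tabular
semantics; 1-based inclusive coordinates, minus-strand subjects with
`s_start > s_end`).

The **builtin backend** runs with no external software. Candidate pairs
are seeded by shared 11-mers on either strand, with a two-hit rule: a
pair must share at least two distinct words before it is aligned, since
a single chance 11-mer between unrelated ~700 nt sequences is common
and would cost a full alignment each time. Candidates are aligned
locally (match +1, mismatch −1, gap −2 per gap position) via
`Biostrings::pairwiseAlignment`, and e-values follow a
Karlin–Altschul-style approximation `E = K·m·n·exp(−λS)` with
`λ = ln 3` and `K = 0.333` — the analytic values for ±1 scoring under
uniform base composition — where `n` is the total residue count of the
run's database. This is an approximation of, not a substitute for,
BLAST statistics: scores of well-separated homologs sit orders of
magnitude away from the 1e-10 threshold, so the approximation's slack
does not move cluster boundaries on realistic marker data.

The **external backend** shells out to BLAST+ (`makeblastdb`, then
`blastn -task blastn -word_size 11` with 12-column tabular output). We
pin classic blastn rather than the megablast default because megablast
is tuned for ≥95% identity and drops ~88%-identity within-family pairs,
which would make the two backends disagree on data they should both
handle; with this setting the two backends induce identical filtered
hit graphs on well-separated families, and the suite asserts exactly
that.

## Post-pipeline selection toolkit

Cluster selection works on per-cluster statistics: member counts,
unique taxa, genus counts, length quantiles, median GC, median
ambiguity, and MAD. *MAD* (maximum alignment density) is
operationalized as `sum(lengths) / (n · max(lengths))` — the fraction
of a gapless alignment as wide as the longest member that the members
would fill. It is 1 exactly on constant lengths and strictly decreases
as any member shrinks below the maximum; clusters mixing a genomic
record with short markers score low and align badly. The citation
trail for MAD gives no closed formula, so this operationalization is a
documented choice of this package. GC is computed over unambiguous
bases only; an all-ambiguous sequence has no defined GC and is reported
as 0 with a `degenerate` attribute instead of erroring, keeping batch
statistics total. The ambiguity proportion counts everything outside
A/C/G/T.

The demonstration-style selection — drop MAD < 0.75, keep
phylogenetically informative clusters (more than four unique taxa, i.e.
`min_taxa = 5`), take the top ten by genus-group count, then keep two
representatives per genus (fewest ambiguous bases, then longest; two
rather than one so downstream trees can confirm same-genus sequences
come out as sisters) — is a single `filter_clusters()` +
`representatives_per_rank()` call, with `top_k` applied last and ties
broken deterministically (statistic descending, cluster id ascending).
`presence_absence()` tabulates rank groups against clusters, and
`export_clusters()` writes PhyLoTa-style tables (the published schema
is not reproduced anywhere we can cite, so the three-table form —
clusters, memberships, taxa — is documented as "PhyLoTa-style") plus
70-column-wrapped FASTA, all atomically (temp file, then rename).
`import_clusters()` round-trips the export.

## The synthetic corpus generator

Because live repository access is neither reproducible nor testable,
the generator builds corpora with known ground truth. A ranked taxonomy
(family → tribe → genus → species) is drawn; each of `n_families` gene
families gets a uniform-random root sequence (500–900 nt, re-drawn if
per-site identity to an existing root exceeds 40%, guaranteeing
between-family separation at the random ~25% baseline); tips evolve
along the taxonomy under i.i.d. substitutions, per-edge probability
`divergence/depth`, so root-to-tip divergence meets the target and
within-family pairwise identity stays ≥ 0.90 at the 5% default. There
are no indels by default, which keeps identity expectations analytic
and — since every family member then has its family's root length —
makes recovered clusters sit at MAD = 1. Decoys are opt-in counts:
over-duplicated "model organism" records, long feature-bearing records
(three family genes embedded in random spacer, pushed past the 3000 nt
window so only the splitting path can save them), mislabeled records
(wrong taxid, right family) and chimeras (two half-families, no
annotation). The defaults — 20 taxa, 10 families, 5% divergence, no
decoys — are the corpus on which end-to-end recovery is asserted:
adjusted Rand index of recovered clusters against planted families
≥ 0.95 averaged over 5 seeds (observed: 1.0), with feature slices of
long records rejoining their true families.

What passing these tests does *not* show: robustness to indels,
rate heterogeneity, codon structure, or the skewed taxon sampling of
real repositories. Chimeric decoys illustrate a genuine limitation of
coverage-based filtering: a half-and-half chimera reaches coverage 0.5
on its own length and can bridge two families under union
symmetrization, exactly the failure mode single-linkage clustering is
known for.

## Determinism, caching, restart

Every stochastic step draws from generators seeded from the run
configuration; all orderings are radix-sorted (C collation). Identical
config + corpus + seed gives byte-identical exports, and the suite
asserts this across an interrupted-and-restarted run versus an
uninterrupted one. Caches are per-clade-unit for download and cluster
(the expensive, resumable boundaries) and per-run for taxise and
cluster²; each cache entry carries a fingerprint of exactly the
parameters that affect it, so changing a threshold invalidates only the
stages it touches. Corrupted entries are discarded with a warning and
recomputed. The effective configuration is persisted as YAML in the
working directory; `restart_pipeline(wd)` re-reads it and skips
completed units. A log records parameters, stage boundaries, per-unit
progress and external invocations before the stages that use them.

## Problem sizes used in the checks

The shipped checks run the full pipeline on 200-record corpora (20 taxa
× 10 families) per seed, five seeds for the recovery average; graph and
partition oracles use 200 random graphs (≤ 100 nodes) and 100 random
trees (≤ 200 nodes) including the default 50,000/100,000 limits; these
sizes exercise every code path — splitting, pooling, merging, caching —
while keeping a full check run in minutes on one core. The same
machinery scales to the tens of thousands of sequences per clade unit
that the default limits anticipate, where the external BLAST+ backend
is the appropriate choice.
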