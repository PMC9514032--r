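# ttcassettes

Transcription and translation are physically coupled in prokaryotes: the
leading ribosome tracks the RNA polymerase, bridged by factors such as NusG
and NusA. One genomic signature of this coupling is the **gene cassette** —
an operonic run of adjacent, co-transcribed genes — that mixes
transcription-machinery genes (RNA polymerase subunits, Nus factors) with
translation-machinery genes (ribosomal proteins, initiation factors).
`ttcassettes` is an R package for discovering and quantifying such mixed
cassettes across a corpus of annotated prokaryotic genomes with precomputed
operon (cassette) tables. It is aimed at comparative genomicists who have
per-genome annotations plus operon calls (or want to predict them) and who
want reproducible, auditable counts of cassette architectures.

## What it computes

Given a corpus (annotation tables + operon tables), the pipeline:

1. **Resolves** every gene against a curated catalog of
   transcription/translation genes — case-insensitive, synonym-aware, with
   tiered precedence *name > synonym > COG id > product keyword*.
2. **Classifies** each cassette into the four-way categorization
   {transcription-only, translation-only, both, none}; genomes holding at
   least one *both* cassette form the denominator for all downstream counts.
3. **Ranks** genes three ways by genome-occurrence frequency — by gene name,
   by product function and by COG id — with a configurable occurrence cutoff
   (strictly more than `min_genomes` genomes, default 300), and takes the
   consensus genes across the three rankings.
4. **Links** consensus genes with three corpus-internal evidence channels —
   gene fusion, gene neighborhood, gene co-occurrence, each a fraction in
   [0, 1] over genomes containing both genes — and extracts candidate
   cassettes as connected components of edges whose score strictly exceeds
   the confidence threshold (default 0.7). A k-means bipartition (k = 2) of
   the combined score matrix separates the transcriptional and translational
   sub-networks.
5. **Counts** genomes matching a queried cassette under three rules:
   *exact* (the cassette is the query, in written order), *reordered* (same
   gene set, any order), *subset* (the query embedded in a larger cassette,
   any order). A genome counts once, with the strongest rule recorded.
   Co-occurring partner genes and the fraction of genomes where the cassette
   stands alone are reported alongside.
6. **Tests enrichment** of gene sets against user-supplied term maps by the
   hypergeometric upper tail, `p = sum_{i>=k} C(K,i) C(N-K,n-i) / C(N,n)`,
   with Benjamini–Hochberg FDR control (alpha <= 0.05).
7. **Summarizes** the taxonomic distribution (genus / phylum / label) of the
   genomes carrying each cassette.

For corpora without operon tables, a logistic operon-pair classifier on
adjacent-gene-pair features — intergenic distance
`D_I = downstream_start - (upstream_end + 1)` with cutoffs [-50, 250] nt,
log length-ratio, neighborhood conservation, phylogenetic-profile distance
and upstream-window motif frequencies — chains predicted operon pairs into
cassettes.

A fully deterministic corpus **simulator** plants cassettes at exact
frequencies (exact / reordered / subset placements), with separated
intergenic-gap distributions for operon-internal vs boundary pairs, synonym
substitution, annotation dropout, taxonomy labels and optional sequences
with planted motifs — and emits a manifest that downstream stages are
validated against.

## Worked example

```r
library(ttcassettes)

catalog <- default_catalog()
cfg <- simulation_config(
  n_genomes = 200, seed = 7,
  planted = list(
    list(query = c("rplK", "nusG"),  n_exact = 60, n_reordered = 30, n_subset = 20),
    list(query = c("rpoA", "rplQ", "rpsD", "rpsK", "rpsM"),
         n_exact = 80, n_reordered = 20, n_subset = 0),
    list(query = c("nusA", "infB"),  n_exact = 90, n_reordered = 20, n_subset = 0)),
  genes_per_genome = c(40, 60))
sim <- simulate_corpus(cfg, catalog = catalog)

count_genomes(cassette_query(c("rplK", "nusG")), sim$corpus, catalog)
#> <match_report> query {rplK, nusG}: 110 genome(s) [exact=60, reordered=30, subset=20]
```

The report says the two-gene cassette was found in 110 of the 200 genomes:
in 60 it is the cassette itself in the written order, in 30 the same two
genes in another order, and in 20 it is embedded inside a larger cassette.
Continuing to the linkage stage:

```r
resolved <- cassette_gene_table(sim$corpus, catalog)
cls  <- classify_corpus(sim$corpus, catalog, resolved = resolved)
rc   <- ranking_config(top_n = 20, min_genomes = 50)
tops <- lapply(c("gene", "function", "cog"), function(ax)
  top_ranked(build_frequency_table(sim$corpus, ax, catalog, rc,
                                   resolved, cls), rc))
cons  <- consensus_genes(tops[[1]], tops[[2]], tops[[3]], catalog, 2)
graph <- build_linkage_graph(cons, sim$corpus, catalog, threshold = 0.7)
extract_candidates(graph, sim$corpus, catalog, resolved = resolved,
                   denominator = length(cls$both_genomes))
#>        channel                    genes genome_count frequency
#> 1 cooccurrence                infB,nusA          110 0.6077348
#> 2 cooccurrence                nusG,rplK          110 0.6077348
#> 3 neighborhood                infB,nusA          110 0.6077348
#> 4 neighborhood                nusG,rplK          110 0.6077348
#> 5 cooccurrence rplQ,rpoA,rpsD,rpsK,rpsM          100 0.5524862
#> 6 neighborhood rplQ,rpoA,rpsD,rpsK,rpsM          100 0.5524862
```

Exactly the three planted cassettes surface as high-confidence candidates
(per channel); `frequency` is the genome count over the 181 genomes holding
at least one mixed cassette. `run_pipeline(pipeline_config(...))` performs
all stages in one call and writes every intermediate table, byte-identically
for a fixed configuration and seed.

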