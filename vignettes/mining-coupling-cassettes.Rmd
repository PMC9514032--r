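---
title: "Mining transcription–translation gene cassettes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining transcription-translation gene cassettes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttcassettes)
```

## The problem and the model

Prokaryotic transcription and translation are coupled in space and time;
factors such as NusG and NusA physically bridge the RNA polymerase and the
leading ribosome. If coupling is under selection, genes of the two
machineries should co-occur in *gene cassettes* — operonic runs of adjacent,
co-transcribed genes. This package quantifies that architecture over a
corpus of annotated genomes with per-genome cassette (operon) tables: it
resolves genes against a curated catalog, classifies cassettes by the mix of
machinery genes they carry, ranks genes by genome occurrence, links frequent
genes through corpus-internal evidence channels, and counts genomes
matching candidate cassettes under explicit matching rules.

The unit of observation is the *genome*: every count in the package is a
genome-occurrence count (a gene, pair or cassette present several times in
one genome contributes once). The denominator for all downstream frequency
claims is the set of genomes holding at least one *both* cassette — this
keeps the corpus-wide and coupled-subset denominators explicit and auditable.

## Gene resolution and the catalog

The curated catalog maps each canonical gene to a category (`transcription`
or `translation`), synonyms, function keywords and COG ids. Resolution is
case-insensitive with tiered precedence:

1. exact canonical name;
2. synonym (the record's name or any of its listed synonyms);
3. COG id;
4. function keyword matched against the product string.

The first tier with a hit wins; within a tier, a hit on two different
entries is ambiguous and yields *no-match* (with a warning) rather than a
guess. Keyword matching is substring-based but **word-bounded**, so
"50S ribosomal protein L1" does not also fire inside
"50S ribosomal protein L17". Dual-role coupling factors (nusA, nusG) are
filed under `transcription`: the cassette-level `both` category arises from
the mixture of categories within a cassette, not from per-gene dual labels.

The bundled default catalog seeds the core machinery (RNA polymerase
subunits, Nus factors, mfd, ribosomal proteins, initiation factors,
rimP/rbfA/truB, secE/secY). It is a documented, extensible seed — not an
attempt to reconstruct any complete published gene list, whose membership is
not reproducible from printed tables.

## Cassette categorization and ranking

A cassette is `both` iff it resolves at least one transcription gene and at
least one translation gene; `transcription_only` / `translation_only` if it
resolves genes of exactly one category; `none` otherwise. The four
categories are mutually exclusive and exhaustive, so per-genome tallies sum
to the cassette count — a property the tests assert on every simulated
corpus.

Frequency tables count genome-level presence of keys along three axes:
canonical genes, lower-cased product strings, and verbatim COG ids.
Product strings are compared exactly (after lower-casing) rather than
fuzzily: exactness keeps counts auditable, at the price of treating
spelling variants as distinct keys. `top_ranked()` applies the occurrence
cutoff **strictly** (`count > min_genomes`, default 300 — the published
convention reads "greater than"), sorts by count with lexicographic
tie-break (ties are otherwise unspecified), and truncates to `top_n`
(default 20). `consensus_genes()` canonicalizes the three lists through the
catalog (so a synonym and its canonical name unify) and keeps genes present
in at least `min_rankings` lists; the result is monotone in `min_rankings`.

## Linkage channels and candidate extraction

Published pipelines delegate gene-linkage evidence to external
protein-network databases. Here the three channels are recomputed from the
corpus itself, taking the channel definitions literally:

- **fusion** — fraction of genomes containing both genes in which a single
  locus carries both identities, or the two are adjacent cassette members
  with intergenic distance <= 0;
- **neighborhood** — fraction in which they are consecutive members of one
  cassette;
- **cooccurrence** — fraction in which both sit in the same cassette,
  intervening genes allowed.

On corpora without multi-copy genes these nest:
fusion <= neighborhood <= cooccurrence. There are deliberately no
text-mining or experimental channels — that is the documented divergence
from database-backed evidence. The confidence threshold applies **per
channel** and **strictly** (score > 0.7; whether a combined or per-channel
score was thresholded upstream is not stated, so the per-channel reading is
implemented and noted). Candidates are connected components (size >= 2) of
confident edges, per channel; their genome counts are recomputed by the
matching rules, never carried over from the graph. The combined score is
the per-pair maximum over channels (no combination rule is published;
`combine = "mean"` is available).

`bipartition()` clusters the rows of the symmetric combined-score matrix
with k-means, k = 2. For up to 12 nodes the optimal 2-partition is found by
exhaustive enumeration — at these sizes enumeration is cheap and makes the
"k-means attains the brute-force optimum" invariant a guarantee rather than
a hope; larger problems use seeded multi-restart `stats::kmeans()`. Ties
(e.g. identical rows) are broken deterministically: the cluster containing
the lexicographically smallest gene is reported first.

## Matching rules and genome counting

A query (a set of >= 2 canonical genes, whose written order defines
"exact") matches a cassette by set arithmetic on canonical genes after
synonym resolution:

- *exact* — the cassette's canonical set equals the query and the order of
  first occurrences equals the written order;
- *reordered* — same set, any other order;
- *subset* — the query strictly contained in a larger cassette, any order.

Unresolved cassette members are transparent (matching is by gene identity,
not locus count), and duplicate canonical genes within one cassette collapse
to a set, since the rules are set-phrased. A genome counts once regardless
of how many of its cassettes match; the per-genome rule is the strongest
present (exact > reordered > subset) — a reporting convention only, counts
are rule-agnostic. `independence_fraction()` is the fraction of matched
genomes where some matching cassette equals the query exactly (the cassette
"stands alone"); `cooccurring_partners()` reports non-query genes riding in
matching cassettes in strictly more than `min_fraction` of matched genomes.

## Operon-pair classifier

Where operon tables are absent, adjacent same-strand gene pairs are
classified *in* / *not in* the same operon by logistic regression. The five
pair features follow the established operon-prediction feature set; only the
intergenic distance is fully specified there, so the remaining four carry
concrete definitions chosen here and stated in their docs:

- **intergenic distance** `D_I = downstream_start - (upstream_end + 1)`
  (nt; negative = overlap), with cutoffs `d_i_min = -50`, `d_i_max = 250`:
  pairs outside the band are boundary pairs regardless of the classifier;
- **neighborhood conservation** — Laplace-smoothed negative log-likelihood
  `-ln((n_adj + 1) / (n_both + 2))`, strictly decreasing in the number of
  genomes where the pair is adjacent; `-ln(1/2)` when no genome holds both;
- **functional relatedness** — phylogenetic-profile distance
  `h / (eps + (H1 + H2)/2)` with `h` the normalized Hamming distance and
  `H` the binary Shannon entropy of each profile's presence frequency;
  0 for identical profiles;
- **length ratio** — `ln(L_up / L_down)`;
- **motif frequencies** — overlapping IUPAC motif counts in the 100 nt
  window 5' of the downstream gene's translational start (strand-aware:
  reverse-complemented for minus-strand genes; truncation at contig edges is
  flagged), each normalized by the number of scan positions. The motif list
  is an input; no motif discovery is attempted.

"Upstream/downstream" means coordinate order throughout — the distance
formula is written in coordinate terms — except the motif window, which
follows the translational start and is therefore strand-aware. Features are
z-score standardized before the fit (standardization is otherwise
unspecified); the means and scales are stored in the model, using the
population (1/n) scale so that replicating the training set leaves the
fitted model unchanged. The pair-probability threshold is 0.5 and
configurable. Prediction chains positive pairs (probability > threshold AND
distance within cutoffs) into maximal runs; every gene lands in exactly one
predicted cassette.

## Enrichment

Over-representation uses the hypergeometric upper tail, computed directly in
log-space, with Benjamini–Hochberg step-up FDR control; "alpha <= 0.05" is
read inclusively on the adjusted p-value. The background universe defaults
to the canonical catalog genes present in the corpus (no background set is
published; it is configurable), and term maps are plain input files — no
ontology retrieval or DAG propagation.

## The simulator and what it does (not) show

`simulate_corpus()` generates the study conditions the analysis assumes:

- planted queries at **exact** frequencies — genome slots are sampled
  without replacement and placements are written as exact / reordered /
  subset (subset placements embed the query plus 1–3 partner-pool genes,
  which is what makes partner co-occurrence testable);
- operon-internal gaps drawn from Normal(20, 15) nt clamped into the
  [-50, 250] band, boundary gaps from Normal(300, 80) truncated to >= 251 nt.
  The two populations are separated by construction, mirroring the
  empirical separation that motivates the distance cutoffs; the parameter
  values are artifact defaults, not published values;
- gene lengths uniform in [300, 1500] nt; genomes of 40–60 genes by default
  (configurable; the bundled analyses use 200-genome corpora, a size at
  which every stage completes in seconds while leaving planted frequencies
  comfortably above ranking cutoffs);
- synonym substitution, annotation dropout (name blanked, COG and product
  retained), exact-proportion taxonomy labels (largest-remainder
  allocation), and optional sequences with motifs written into upstream
  windows.

Everything is deterministic given the seed, and the manifest records every
placement, boundary label and taxonomy assignment; `verify_manifest()`
checks the emitted corpus against it. Passing tests on this corpus shows
the *bookkeeping* is right — resolution, classification, counting, linkage
and statistics behave exactly as specified under controlled conditions. It
does **not** show robustness to the messiness of real annotations:
inconsistent product vocabularies, mis-called operon boundaries, split or
merged loci, multi-replicon genomes (treated here as one concatenated
replicon per genome id, since no merging rule is published) or genuinely
ambiguous paralogs. Published genome counts from any specific
database snapshot are likewise out of reach by design; the package
reproduces the *procedure*, and its numbers are counts over whatever corpus
it is given.

## Numerical choices and degenerate inputs

- All TSV outputs are byte-stable: fixed column order, fixed number
  formatting, no timestamps; pipeline artifacts carry a hash of the
  configuration that produced them, and rerunning with one seed reproduces
  identical bytes.
- `eps = 1e-9` guards the profile-distance denominator (two all-present or
  all-absent profiles have zero entropy).
- Empty corpora, empty catalogs, zero-match queries and single-gene genomes
  are all defined: empty tables, `NA` independence, singleton cassettes.
- The matcher's per-genome "strongest rule" makes reports deterministic even
  when several cassettes match.
- Seeds are plumbed through every stochastic step (simulation, k-means
  restarts, classifier provenance); R's default RNG is used as seeded.

## Known limitations

- The catalog seed is small; corpus genes outside it are invisible to
  gene-axis ranking (they still appear on the function and COG axes).
- Linkage evidence is corpus-internal only; a sparse corpus under-powers
  the fusion channel in particular.
- The four classifier features beyond intergenic distance are
  interpretations of briefly-described quantities, not reimplementations of
  any reference scoring code; they are configuration-visible and tested
  against their own stated definitions.
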