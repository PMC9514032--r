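# Internal genus metadata used when the taxonomy config is a plain named
# vector of proportions.
.genus_meta <- data.frame(
  genus = c("Escherichia", "Salmonella", "Neisseria", "Treponema",
            "Prevotella", "Leptospira", "Fusobacterium", "Helicobacter",
            "Campylobacter", "Pseudomonas", "Hahella", "Halomonas",
            "Chlorobium", "Pyrococcus", "Thermococcus"),
  phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Spirochaetes", "Bacteroidetes", "Spirochaetes",
             "Fusobacteria", "Proteobacteria", "Proteobacteria",
             "Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Chlorobi", "Euryarchaeota", "Euryarchaeota"),
  labels = c("pathogenic", "pathogenic", "pathogenic", "pathogenic",
             "pathogenic", "pathogenic", "pathogenic", "pathogenic",
             "pathogenic", "soil", "soil", "soil", "soil",
             "archaea", "archaea"),
  stringsAsFactors = FALSE)

#' Simulation configuration for the synthetic corpus generator
#'
#' Defines the study conditions the simulator emulates: genome and operon
#' sizes, the separated intergenic-distance distributions for operon-internal
#' vs boundary pairs, planted query cassettes at exact frequencies with
#' exact/reordered/subset placement rules, synonym usage, annotation
#' dropout, taxonomy label proportions and optional sequence/motif emission.
#'
#' @param n_genomes Number of genomes.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param planted List of plant specs, each
#'   `list(query = <character>, n_exact, n_reordered, n_subset)`; per query
#'   the three counts must not exceed `n_genomes`. Genome slots are sampled
#'   without replacement, so planted counts are exact.
#' @param decoy_gene_pool Number of distinct decoy genes (default 200); decoy
#'   genes never resolve against the catalog.
#' @param genes_per_genome Integer range (default `c(40, 60)`).
#' @param operon_size Integer range for decoy cassette sizes (default
#'   `c(1, 5)`).
#' @param d_i_operon,d_i_boundary `(mean, sd)` in nt of the intergenic-gap
#'   distributions (defaults `c(20, 15)` and `c(300, 80)`): operon-internal
#'   draws are clamped into the `[-50, 250]` cutoff band, boundary draws
#'   truncated to at least 251 nt, so the two populations are separated by
#'   construction.
#' @param synonym_use_rate Probability that a catalog gene is annotated under
#'   one of its synonyms instead of its canonical name (default 0).
#' @param annotation_dropout Probability that a gene's name is blanked (COG
#'   and product retained; default 0).
#' @param taxonomy Named numeric vector of genus proportions summing to 1, or
#'   `NULL` for a single genus "Escherichia". Counts are allocated by largest
#'   remainder, so emitted proportions are exact.
#' @param partner_pool Canonical genes drawn (1-3 per cassette) as extra
#'   members of subset placements (default `c("rplA", "secE")`).
#' @param motif_spec Optional `list(motif = <IUPAC string>, rate = <real>)`:
#'   the motif is written into the upstream window of operon-internal
#'   downstream genes at the given rate (requires `emit_sequence`).
#' @param emit_sequence Emit per-genome nucleotide sequences (default FALSE).
#' @param gene_length Integer range of gene lengths in nt (default
#'   `c(300, 1500)`).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genomes, seed = 1L, planted = list(),
                              decoy_gene_pool = 200L,
                              genes_per_genome = c(40L, 60L),
                              operon_size = c(1L, 5L),
                              d_i_operon = c(20, 15),
                              d_i_boundary = c(300, 80),
                              synonym_use_rate = 0,
                              annotation_dropout = 0,
                              taxonomy = NULL,
                              partner_pool = c("rplA", "secE"),
                              motif_spec = NULL,
                              emit_sequence = FALSE,
                              gene_length = c(300L, 1500L)) {
  stopifnot(n_genomes >= 0, length(genes_per_genome) == 2,
            length(operon_size) == 2, operon_size[1] >= 1,
            synonym_use_rate >= 0, synonym_use_rate <= 1,
            annotation_dropout >= 0, annotation_dropout <= 1,
            gene_length[1] >= 60)
  for (p in planted) {
    stopifnot(is.character(p$query), length(p$query) >= 2)
    tot <- p$n_exact + p$n_reordered + p$n_subset
    if (tot > n_genomes)
      stop("simulation_config: infeasible plant counts for query {",
           paste(p$query, collapse = ","), "}: ", tot, " > ", n_genomes)
  }
  if (!is.null(taxonomy)) {
    if (abs(sum(taxonomy) - 1) > 1e-9)
      stop("simulation_config: taxonomy proportions must sum to 1")
  }
  structure(list(n_genomes = as.integer(n_genomes), seed = as.integer(seed),
                 planted = planted,
                 decoy_gene_pool = as.integer(decoy_gene_pool),
                 genes_per_genome = as.integer(genes_per_genome),
                 operon_size = as.integer(operon_size),
                 d_i_operon = d_i_operon, d_i_boundary = d_i_boundary,
                 synonym_use_rate = synonym_use_rate,
                 annotation_dropout = annotation_dropout,
                 taxonomy = taxonomy, partner_pool = partner_pool,
                 motif_spec = motif_spec, emit_sequence = emit_sequence,
                 gene_length = as.integer(gene_length)),
            class = "simulation_config")
}

# Largest-remainder allocation of n items to proportions.
.allocate_counts <- function(props, n) {
  raw <- props * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(-(raw - counts), names(props))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

# Catalog-backed annotation fields for a canonical gene.
.catalog_fields <- function(gene, catalog) {
  i <- match(gene, catalog$entries$canonical_gene)
  if (is.na(i)) stop("planted gene not in catalog: ", gene)
  kw <- .split_multi(catalog$entries$function_keywords[i])
  list(gene_name = gene,
       synonyms = catalog$entries$synonyms[i],
       product = if (length(kw)) kw[1] else gene,
       cog_ids = catalog$entries$cog_ids[i])
}

#' Simulate a ground-truth cassette corpus
#'
#' Generates an annotated genome corpus with planted query cassettes, decoy
#' operons, separated operon/boundary intergenic-gap distributions, optional
#' synonym substitution, annotation dropout, taxonomy labels and optional
#' sequences with planted motifs. Deterministic given the config seed. The
#' returned manifest records every planted placement, every true
#' operon-boundary label and all taxonomy assignments, and serves as the
#' oracle for downstream stages.
#'
#' @param config A [simulation_config()].
#' @param catalog A `curated_catalog` supplying annotation fields for planted
#'   genes (default [default_catalog()]).
#' @param out_dir Optional directory: when given, the corpus TSVs (and FASTA
#'   if sequences are emitted) plus the manifest tables under `truth/` are
#'   written there.
#' @return List with `corpus` (a `cassette_corpus`), `manifest` (see
#'   [write_manifest()]) and `paths` (written files, or `NULL`).
#' @export
simulate_corpus <- function(config, catalog = default_catalog(),
                            out_dir = NULL) {
  set.seed(config$seed)
  n <- config$n_genomes
  gids <- sprintf("G%04d", seq_len(n))
  # taxonomy assignment (exact proportions, deterministic order)
  tax_props <- config$taxonomy %||% c(Escherichia = 1)
  counts <- .allocate_counts(tax_props, n)
  genus <- rep(names(tax_props), counts)
  meta_i <- match(genus, .genus_meta$genus)
  tax <- data.frame(genome_id = gids, genus = genus,
                    phylum = ifelse(is.na(meta_i), "UnknownPhylum",
                                    .genus_meta$phylum[meta_i]),
                    labels = ifelse(is.na(meta_i), "unlabeled",
                                    .genus_meta$labels[meta_i]),
                    stringsAsFactors = FALSE)
  # planted placements: sample genome slots without replacement per query
  placements <- data.frame(genome_id = character(0), query_id = character(0),
                           query = character(0), rule = character(0),
                           stringsAsFactors = FALSE)
  for (qi in seq_along(config$planted)) {
    p <- config$planted[[qi]]
    tot <- p$n_exact + p$n_reordered + p$n_subset
    slots <- if (tot > 0) sample(gids, tot) else character(0)
    placements <- rbind(placements, data.frame(
      genome_id = slots,
      query_id = sprintf("q%d", qi),
      query = paste(p$query, collapse = ","),
      rule = rep(c("exact", "reordered", "subset"),
                 c(p$n_exact, p$n_reordered, p$n_subset)),
      stringsAsFactors = FALSE))
  }
  # decoy gene pool (never resolves against the catalog)
  pool <- data.frame(gene_name = sprintf("dg%04d",
                                         seq_len(config$decoy_gene_pool)),
                     product = sprintf("hypothetical protein %04d",
                                       seq_len(config$decoy_gene_pool)),
                     cog_ids = sprintf("DCOG%04d",
                                       seq_len(config$decoy_gene_pool)),
                     stringsAsFactors = FALSE)
  annotations <- list()
  operons <- list()
  sequences <- character(0)
  boundaries <- list()
  cass_truth <- list()
  for (g in seq_len(n)) {
    gid <- gids[g]
    # -- assemble the genome's cassette gene lists (planted first, shuffled
    #    into position later)
    plant_here <- placements[placements$genome_id == gid, , drop = FALSE]
    cass_genes <- list()   # each: data.frame(gene_name, synonyms, product, cog_ids)
    cass_meta <- list()    # each: list(planted_query, rule)
    for (pi in seq_len(nrow(plant_here))) {
      q <- strsplit(plant_here$query[pi], ",", fixed = TRUE)[[1]]
      rule <- plant_here$rule[pi]
      ord <- switch(rule,
        exact = q,
        reordered = {
          o <- sample(q)
          while (identical(o, q)) o <- sample(q)
          o
        },
        subset = {
          avail <- setdiff(config$partner_pool, q)
          if (!length(avail))
            stop("simulate_corpus: partner_pool has no gene outside query {",
                 paste(q, collapse = ","), "}")
          extra <- sample(avail, min(length(avail), sample(1:3, 1)))
          sample(c(q, extra))
        })
      recs <- do.call(rbind, lapply(ord, function(gene) {
        f <- .catalog_fields(gene, catalog)
        data.frame(gene_name = f$gene_name, synonyms = f$synonyms,
                   product = f$product, cog_ids = f$cog_ids,
                   stringsAsFactors = FALSE)
      }))
      cass_genes[[length(cass_genes) + 1L]] <- recs
      cass_meta[[length(cass_meta) + 1L]] <-
        list(planted_query = plant_here$query_id[pi], rule = rule)
    }
    # -- decoy cassettes up to the genome's gene budget
    target <- sample(config$genes_per_genome[1]:config$genes_per_genome[2], 1)
    n_genes <- sum(vapply(cass_genes, nrow, 0L))
    while (n_genes < target) {
      sz <- sample(config$operon_size[1]:config$operon_size[2], 1)
      sz <- min(sz, target - n_genes)
      picks <- sample(nrow(pool), sz, replace = FALSE)
      recs <- data.frame(gene_name = pool$gene_name[picks], synonyms = "",
                         product = pool$product[picks],
                         cog_ids = pool$cog_ids[picks],
                         stringsAsFactors = FALSE)
      cass_genes[[length(cass_genes) + 1L]] <- recs
      cass_meta[[length(cass_meta) + 1L]] <-
        list(planted_query = NA_character_, rule = NA_character_)
      n_genes <- n_genes + sz
    }
    # -- shuffle cassette order along the replicon
    ord <- sample(seq_along(cass_genes))
    cass_genes <- cass_genes[ord]
    cass_meta <- cass_meta[ord]
    # -- lay out coordinates with drawn gaps
    rows <- list()
    memb <- list()
    pos <- 101L
    locus_i <- 0L
    motif <- config$motif_spec
    planted_motif_at <- integer(0)  # window starts where the motif goes
    for (ci in seq_along(cass_genes)) {
      cg <- cass_genes[[ci]]
      cid <- sprintf("op%03d", ci)
      strand <- sample(c("+", "-"), 1)
      for (k in seq_len(nrow(cg))) {
        len <- sample(config$gene_length[1]:config$gene_length[2], 1)
        if (k > 1) {
          gap <- round(stats::rnorm(1, config$d_i_operon[1],
                                    config$d_i_operon[2]))
          gap <- max(-50, min(250, gap))
          if (!is.null(motif) && strand == "+" &&
              stats::runif(1) < motif$rate)
            planted_motif_at <- c(planted_motif_at, pos + gap)
          pos <- pos + gap
        }
        locus_i <- locus_i + 1L
        lt <- sprintf("%s_t%04d", gid, locus_i)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = gid, locus_tag = lt, gene_name = cg$gene_name[k],
          synonyms = cg$synonyms[k], product = cg$product[k],
          cog_ids = cg$cog_ids[k], start = pos, end = pos + len - 1L,
          strand = strand, stringsAsFactors = FALSE)
        memb[[length(memb) + 1L]] <- data.frame(
          cassette_id = cid, locus_tag = lt, rank = k,
          stringsAsFactors = FALSE)
        pos <- pos + len
      }
      cass_truth[[length(cass_truth) + 1L]] <- data.frame(
        genome_id = gid, cassette_id = cid, size = nrow(cg),
        strand = strand,
        planted_query = cass_meta[[ci]]$planted_query,
        rule = cass_meta[[ci]]$rule, stringsAsFactors = FALSE)
      bgap <- round(stats::rnorm(1, config$d_i_boundary[1],
                                 config$d_i_boundary[2]))
      pos <- pos + max(251, bgap)
    }
    genes <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    # -- synonym substitution and annotation dropout
    if (config$synonym_use_rate > 0) {
      for (i in seq_len(nrow(genes))) {
        syns <- .split_multi(genes$synonyms[i])
        if (length(syns) && stats::runif(1) < config$synonym_use_rate) {
          genes$gene_name[i] <- syns[1]
          genes$synonyms[i] <- ""
        }
      }
    }
    if (config$annotation_dropout > 0) {
      drop <- stats::runif(nrow(genes)) < config$annotation_dropout
      genes$gene_name[drop] <- NA_character_
      genes$synonyms[drop] <- ""
    }
    # -- true pair labels (adjacent genes in coordinate order)
    if (nrow(genes) > 1) {
      mtab <- do.call(rbind, memb)
      cass_of <- stats::setNames(mtab$cassette_id, mtab$locus_tag)
      i <- seq_len(nrow(genes) - 1L)
      boundaries[[length(boundaries) + 1L]] <- data.frame(
        genome_id = gid,
        upstream = genes$locus_tag[i], downstream = genes$locus_tag[i + 1L],
        label = ifelse(cass_of[genes$locus_tag[i]] ==
                         cass_of[genes$locus_tag[i + 1L]],
                       "operon_pair", "boundary_pair"),
        stringsAsFactors = FALSE)
    }
    sequence <- NULL
    if (config$emit_sequence) {
      seqlen <- max(genes$end) + 150L
      sequence <- paste(sample(c("A", "C", "G", "T"), seqlen,
                               replace = TRUE), collapse = "")
      if (!is.null(motif)) {
        for (ws in planted_motif_at) {
          at <- ws - nchar(motif$motif)
          if (at >= 1)
            substr(sequence, at, ws - 1L) <- motif$motif
        }
      }
      sequences[gid] <- sequence
    }
    annotations[[gid]] <- genome_annotation(
      gid, genes,
      taxon = list(genus = tax$genus[g], phylum = tax$phylum[g],
                   labels = .split_multi(tax$labels[g])),
      sequence = sequence)
    operons[[gid]] <- do.call(rbind, c(memb, list(make.row.names = FALSE)))
  }
  corpus <- if (n > 0) assemble_corpus(annotations, operons)
            else structure(list(genomes = list(), cassettes = list(),
                                flags = data.frame(genome_id = character(0),
                                                   has_cassettes = logical(0))),
                           class = "cassette_corpus")
  cassettes <- if (length(cass_truth))
    do.call(rbind, c(cass_truth, list(make.row.names = FALSE)))
  else data.frame(genome_id = character(0), cassette_id = character(0),
                  size = integer(0), strand = character(0),
                  planted_query = character(0), rule = character(0),
                  stringsAsFactors = FALSE)
  placements$cassette_id <- cassettes$cassette_id[
    match(paste(placements$genome_id, placements$query_id),
          paste(cassettes$genome_id, cassettes$planted_query))]
  manifest <- structure(list(
    config = config,
    taxonomy = tax,
    placements = placements,
    cassettes = cassettes,
    boundaries = if (length(boundaries))
      do.call(rbind, c(boundaries, list(make.row.names = FALSE)))
    else data.frame(genome_id = character(0), upstream = character(0),
                    downstream = character(0), label = character(0),
                    stringsAsFactors = FALSE)),
    class = "corpus_manifest")
  paths <- NULL
  if (!is.null(out_dir)) paths <- write_corpus(corpus, manifest, out_dir)
  list(corpus = corpus, manifest = manifest, paths = paths)
}

#' Write a simulated corpus and its manifest to disk
#'
#' Emits `annotations.tsv`, `operons.tsv`, `taxonomy.tsv` (and
#' `genomes.fasta` when sequences are present) under `dir`, plus the
#' manifest truth tables under `dir/truth/`.
#'
#' @param corpus A `cassette_corpus`.
#' @param manifest A `corpus_manifest` (or `NULL` to skip truth tables).
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_corpus <- function(corpus, manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotations = file.path(dir, "annotations.tsv"),
             operons = file.path(dir, "operons.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"))
  write_annotation(corpus$genomes, paths["annotations"])
  write_operon_table(corpus$cassettes, paths["operons"])
  seqs <- Filter(Negate(is.null),
                 lapply(corpus$genomes, function(g) g$sequence))
  if (length(seqs)) {
    paths["fasta"] <- file.path(dir, "genomes.fasta")
    write_genome_fasta(unlist(seqs), paths["fasta"])
  }
  if (!is.null(manifest)) {
    .write_tsv(manifest$taxonomy, paths["taxonomy"])
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    paths["placements"] <- file.path(tdir, "placements.tsv")
    paths["cassettes"] <- file.path(tdir, "cassettes.tsv")
    paths["boundaries"] <- file.path(tdir, "boundaries.tsv")
    .write_tsv(manifest$placements, paths["placements"])
    .write_tsv(manifest$cassettes, paths["cassettes"])
    .write_tsv(manifest$boundaries, paths["boundaries"])
  } else {
    tx <- data.frame(genome_id = names(corpus$genomes),
                     genus = vapply(corpus$genomes,
                                    function(g) g$taxon$genus %||% NA, ""),
                     phylum = vapply(corpus$genomes,
                                     function(g) g$taxon$phylum %||% NA, ""),
                     labels = vapply(corpus$genomes, function(g)
                       .join_multi(g$taxon$labels), ""),
                     stringsAsFactors = FALSE)
    .write_tsv(tx, paths["taxonomy"])
  }
  invisible(paths)
}

#' @rdname write_corpus
#' @param manifest A `corpus_manifest`.
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(manifest$placements, file.path(dir, "placements.tsv"))
  .write_tsv(manifest$cassettes, file.path(dir, "cassettes.tsv"))
  .write_tsv(manifest$boundaries, file.path(dir, "boundaries.tsv"))
  .write_tsv(manifest$taxonomy, file.path(dir, "taxonomy.tsv"))
  invisible(dir)
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    df[] <- lapply(df, function(col) {
      if (is.character(col)) { col[is.na(col)] <- ""; col } else col
    })
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, eol = "\n")
  }
  invisible(path)
}

#' Verify a corpus against its simulation manifest
#'
#' Checks that every manifest claim is realized in the corpus: genome set,
#' per-genome cassette counts, and per planted query the matched-genome set
#' with per-genome strongest rules.
#'
#' @param corpus A `cassette_corpus`.
#' @param manifest A `corpus_manifest`.
#' @param catalog A `curated_catalog`.
#' @return List with `ok` (logical) and `discrepancies` (character vector,
#'   empty when `ok`).
#' @export
verify_manifest <- function(corpus, manifest, catalog) {
  disc <- character(0)
  gids <- sort(names(corpus$genomes))
  if (!identical(gids, sort(manifest$taxonomy$genome_id)))
    disc <- c(disc, "genome id sets differ")
  truth_counts <- table(manifest$cassettes$genome_id)
  for (gid in names(truth_counts)) {
    got <- length(unique(corpus$cassettes[[gid]]$cassette_id))
    if (got != truth_counts[[gid]])
      disc <- c(disc, sprintf("genome %s: %d cassettes, manifest says %d",
                              gid, got, truth_counts[[gid]]))
  }
  resolved <- cassette_gene_table(corpus, catalog)
  pl <- manifest$placements
  for (qid in unique(pl$query_id)) {
    sub <- pl[pl$query_id == qid, , drop = FALSE]
    query <- cassette_query(strsplit(sub$query[1], ",", fixed = TRUE)[[1]])
    rep_ <- count_genomes(query, corpus, catalog, resolved = resolved)
    want <- sub[order(sub$genome_id), c("genome_id", "rule")]
    rownames(want) <- NULL
    got <- rep_$by_genome
    if (!identical(got$genome_id, want$genome_id))
      disc <- c(disc, sprintf(
        "query %s: matched genomes differ (got %d, manifest %d)",
        qid, nrow(got), nrow(want)))
    else if (!identical(got$rule, want$rule))
      disc <- c(disc, sprintf("query %s: per-genome rules differ", qid))
  }
  list(ok = length(disc) == 0, discrepancies = disc)
}
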