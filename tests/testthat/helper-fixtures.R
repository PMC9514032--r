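# Shared fixtures: all built in code at test time.

the_catalog <- local({
  cat_ <- NULL
  function() {
    if (is.null(cat_)) cat_ <<- default_catalog()
    cat_
  }
})

# A genome whose cassette structure is given literally:
# cassette_specs = list(c("rplK","nusG"), c("dgA","dgB"), ...).
# Gene names resolve through the default catalog when they are catalog
# genes; anything else becomes a decoy with a hypothetical product.
make_genome <- function(genome_id, cassette_specs, gap_within = 20L,
                        gap_between = 400L, strand = "+",
                        gene_len = 600L, sequence = FALSE) {
  cat_ <- the_catalog()
  rows <- list()
  memb <- list()
  pos <- 101L
  li <- 0L
  for (ci in seq_along(cassette_specs)) {
    genes <- cassette_specs[[ci]]
    st <- if (length(strand) == length(cassette_specs)) strand[ci]
          else strand
    for (k in seq_along(genes)) {
      if (k > 1) pos <- pos + gap_within
      li <- li + 1L
      g <- genes[k]
      i <- match(g, cat_$entries$canonical_gene)
      kw <- if (!is.na(i))
        .split_multi_test(cat_$entries$function_keywords[i])[1]
      else paste("hypothetical protein", g)
      cogs <- if (!is.na(i)) cat_$entries$cog_ids[i] else ""
      lt <- sprintf("%s_t%03d", genome_id, li)
      rows[[li]] <- data.frame(
        genome_id = genome_id, locus_tag = lt, gene_name = g,
        synonyms = if (!is.na(i)) cat_$entries$synonyms[i] else "",
        product = kw, cog_ids = cogs, start = pos,
        end = pos + gene_len - 1L, strand = st, stringsAsFactors = FALSE)
      memb[[li]] <- data.frame(cassette_id = sprintf("op%02d", ci),
                               locus_tag = lt, rank = k,
                               stringsAsFactors = FALSE)
      pos <- pos + gene_len
    }
    pos <- pos + gap_between
  }
  genes <- do.call(rbind, rows)
  seq_ <- NULL
  if (sequence)
    seq_ <- paste(rep("A", max(genes$end) + 150L), collapse = "")
  list(annotation = genome_annotation(genome_id, genes, sequence = seq_),
       operons = do.call(rbind, memb))
}

# Corpus from a list of per-genome cassette spec lists.
make_corpus <- function(spec_list, ...) {
  gids <- sprintf("G%03d", seq_along(spec_list))
  built <- lapply(seq_along(spec_list),
                  function(i) make_genome(gids[i], spec_list[[i]], ...))
  anns <- lapply(built, `[[`, "annotation")
  names(anns) <- gids
  ops <- lapply(built, `[[`, "operons")
  names(ops) <- gids
  assemble_corpus(anns, ops)
}

.split_multi_test <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

# A small randomized corpus of catalog + decoy genes, for matcher stress
# tests. Returns the corpus; cassettes are random samples of the gene pool.
random_corpus <- function(n_genomes = 6, n_cassettes = 4,
                          cassette_size = 2:5) {
  cat_ <- the_catalog()
  pool <- c(cat_$entries$canonical_gene, sprintf("zz%02d", 1:10))
  spec_list <- lapply(seq_len(n_genomes), function(i) {
    lapply(seq_len(n_cassettes), function(j)
      sample(pool, sample(cassette_size, 1)))
  })
  make_corpus(spec_list)
}

# Independent brute-force matcher: set inclusion over every cassette,
# genome-level presence. Shares no code with count_genomes.
brute_force_matched_genomes <- function(query, corpus, catalog) {
  hits <- character(0)
  for (gid in names(corpus$cassettes)) {
    memb <- corpus$cassettes[[gid]]
    if (is.null(memb) || !nrow(memb)) next
    genes <- corpus$genomes[[gid]]$genes
    for (cid in unique(memb$cassette_id)) {
      tags <- memb$locus_tag[memb$cassette_id == cid]
      canon <- resolve_genes(genes[match(tags, genes$locus_tag), ,
                                   drop = FALSE], catalog)$canonical
      if (all(query %in% canon)) {
        hits <- c(hits, gid)
        break
      }
    }
  }
  sort(unique(hits))
}
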