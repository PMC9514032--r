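test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(n_genomes = 10, seed = 17,
                           planted = list(list(query = c("rplK", "nusG"),
                                               n_exact = 3, n_reordered = 2,
                                               n_subset = 1)),
                           genes_per_genome = c(10, 14),
                           emit_sequence = TRUE,
                           motif_spec = list(motif = "TATAAT", rate = 0.5))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_corpus(cfg, out_dir = d1)
  simulate_corpus(cfg, out_dir = d2)
  for (f in c("annotations.tsv", "operons.tsv", "taxonomy.tsv",
              "genomes.fasta", file.path("truth", "placements.tsv"))) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("degenerate and infeasible configurations are handled", {
  sim0 <- simulate_corpus(simulation_config(n_genomes = 0, seed = 1))
  expect_equal(length(sim0$corpus$genomes), 0L)
  expect_equal(nrow(sim0$manifest$placements), 0L)
  expect_error(simulation_config(n_genomes = 5,
                                 planted = list(list(query = c("a", "b"),
                                                     n_exact = 4,
                                                     n_reordered = 2,
                                                     n_subset = 0))),
               "infeasible")
})

test_that("manifest verification passes on a fresh corpus and catches edits", {
  cat_ <- the_catalog()
  cfg <- simulation_config(n_genomes = 25, seed = 23,
                           planted = list(list(query = c("nusA", "infB"),
                                               n_exact = 8, n_reordered = 4,
                                               n_subset = 3)),
                           genes_per_genome = c(10, 14))
  sim <- simulate_corpus(cfg)
  v <- verify_manifest(sim$corpus, sim$manifest, cat_)
  expect_true(v$ok)
  # delete one planted cassette: verification must flag it
  broken <- sim$corpus
  pl <- sim$manifest$placements[1, ]
  memb <- broken$cassettes[[pl$genome_id]]
  broken$cassettes[[pl$genome_id]] <-
    memb[memb$cassette_id != pl$cassette_id, ]
  v2 <- verify_manifest(broken, sim$manifest, cat_)
  expect_false(v2$ok)
  expect_gte(length(v2$discrepancies), 1L)
})

test_that("manifest claims hold across seeds", {
  cat_ <- the_catalog()
  for (seed in c(1, 2, 3, 11, 42)) {
    cfg <- simulation_config(n_genomes = 12, seed = seed,
                             planted = list(list(query = c("rplK", "nusG"),
                                                 n_exact = 4,
                                                 n_reordered = 2,
                                                 n_subset = 2)),
                             genes_per_genome = c(8, 12))
    sim <- simulate_corpus(cfg)
    expect_true(verify_manifest(sim$corpus, sim$manifest, cat_)$ok,
                label = paste("seed", seed))
  }
})

test_that("intergenic gaps follow the two configured distributions", {
  cfg <- simulation_config(n_genomes = 20, seed = 29,
                           genes_per_genome = c(25, 35),
                           operon_size = c(2, 5),
                           d_i_operon = c(20, 15), d_i_boundary = c(300, 80))
  sim <- simulate_corpus(cfg)
  d_op <- c(); d_bd <- c()
  for (gid in names(sim$corpus$genomes)) {
    genes <- sim$corpus$genomes[[gid]]$genes
    memb <- sim$corpus$cassettes[[gid]]
    cass_of <- stats::setNames(memb$cassette_id, memb$locus_tag)
    i <- seq_len(nrow(genes) - 1L)
    d <- genes$start[i + 1L] - (genes$end[i] + 1L)
    same <- cass_of[genes$locus_tag[i]] == cass_of[genes$locus_tag[i + 1L]]
    d_op <- c(d_op, d[same])
    d_bd <- c(d_bd, d[!same])
  }
  # operon-internal gaps stay inside the cutoff band and near their mean
  expect_true(all(d_op >= -50 & d_op <= 250))
  expect_lt(abs(mean(d_op) - 20), 3 * 15 / sqrt(length(d_op)) + 1)
  # boundary gaps never enter the band
  expect_true(all(d_bd >= 251))
})

test_that("synonym substitution does not break counting (synonym closure)", {
  cat_ <- the_catalog()
  # rimP (synonym yhbC) planted with a partner; all names swapped to synonyms
  cfg <- simulation_config(n_genomes = 15, seed = 37,
                           planted = list(list(query = c("rimP", "rbfA"),
                                               n_exact = 6, n_reordered = 3,
                                               n_subset = 0)),
                           synonym_use_rate = 1,
                           genes_per_genome = c(8, 12))
  sim <- simulate_corpus(cfg)
  # the rimP records are now annotated as yhbC
  tab <- cassette_gene_table(sim$corpus)
  expect_true(any(tab$gene_name == "yhbC"))
  rep_ <- count_genomes(cassette_query(c("rimP", "rbfA")), sim$corpus, cat_)
  expect_equal(rep_$genome_count, 9L)
  expect_true(verify_manifest(sim$corpus, sim$manifest, cat_)$ok)
})

test_that("annotation dropout degrades counts monotonically without fallback", {
  cat_ <- the_catalog()
  base <- list(n_genomes = 20L,
               planted = list(list(query = c("rplK", "nusG"), n_exact = 10,
                                   n_reordered = 0, n_subset = 0)),
               genes_per_genome = c(8L, 12L))
  cfg0 <- do.call(simulation_config,
                  c(base, list(seed = 41, annotation_dropout = 0)))
  cfg1 <- do.call(simulation_config,
                  c(base, list(seed = 41, annotation_dropout = 0.6)))
  # catalog stripped of COG and keyword fallbacks: names are the only route
  stripped <- the_catalog()$entries
  stripped$cog_ids <- ""
  stripped$function_keywords <- ""
  name_only <- new_catalog(stripped)
  q <- cassette_query(c("rplK", "nusG"))
  n0 <- count_genomes(q, simulate_corpus(cfg0)$corpus, name_only)$genome_count
  n1 <- count_genomes(q, simulate_corpus(cfg1)$corpus, name_only)$genome_count
  expect_equal(n0, 10L)
  expect_lte(n1, n0)
  # with the full catalog the COG/product fallback rescues dropped names
  nfull <- count_genomes(q, simulate_corpus(cfg1)$corpus,
                         cat_)$genome_count
  expect_equal(nfull, 10L)
})

test_that("planted motifs appear in emitted sequences at upstream windows", {
  cfg <- simulation_config(n_genomes = 6, seed = 43,
                           genes_per_genome = c(10, 14),
                           operon_size = c(2, 4),
                           emit_sequence = TRUE,
                           motif_spec = list(motif = "TATTACGA", rate = 1))
  sim <- simulate_corpus(cfg)
  fc <- feature_config(motifs = "TATTACGA")
  hit <- 0L; tries <- 0L
  for (gid in names(sim$corpus$genomes)) {
    ann <- sim$corpus$genomes[[gid]]
    memb <- sim$corpus$cassettes[[gid]]
    cass_of <- stats::setNames(memb$cassette_id, memb$locus_tag)
    genes <- ann$genes
    for (i in seq_len(nrow(genes) - 1L)) {
      same <- cass_of[genes$locus_tag[i]] == cass_of[genes$locus_tag[i + 1]]
      if (!same || genes$strand[i + 1] != "+") next
      tries <- tries + 1L
      f <- motif_frequencies(ann, genes[i + 1, , drop = FALSE], fc)
      if (f[1] > 0) hit <- hit + 1L
    }
  }
  expect_gt(tries, 0L)
  expect_equal(hit, tries)  # rate 1: every + strand operon-internal window
})
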