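test_that("gene-axis counts are genome-level presence in both-cassettes", {
  cat_ <- the_catalog()
  # rpoA in both-cassettes of 4 genomes (twice in one of them); a fifth
  # genome carries it only in a transcription-only cassette
  corpus <- make_corpus(list(
    list(c("rpoA", "rplQ")),
    list(c("rpoA", "rpsD"), c("rpoA", "rpsK")),
    list(c("rpoA", "rplK")),
    list(c("rpoA", "rpsM")),
    list(c("rpoA", "rpoB"))))
  ft <- build_frequency_table(corpus, "gene", cat_, ranking_config())
  expect_equal(unname(ft$counts["rpoA"]), 4L)
  expect_equal(ft$denominator, 4L)
})

test_that("frequency tables match a brute-force recount", {
  cat_ <- the_catalog()
  set.seed(21)
  corpus <- random_corpus(n_genomes = 6, n_cassettes = 4)
  cls <- classify_corpus(corpus, cat_)
  ft <- build_frequency_table(corpus, "gene", cat_, ranking_config())
  # independent recount: loop genomes, collect canonical genes of both-
  # cassettes, count genome-level presence
  recount <- new.env()
  for (gid in names(corpus$cassettes)) {
    memb <- corpus$cassettes[[gid]]
    genes <- corpus$genomes[[gid]]$genes
    seen <- character(0)
    for (cid in unique(memb$cassette_id)) {
      cc <- cls$cassette_categories
      if (cc$category[cc$genome_id == gid & cc$cassette_id == cid] != "both")
        next
      tags <- memb$locus_tag[memb$cassette_id == cid]
      canon <- resolve_genes(genes[match(tags, genes$locus_tag), ,
                                   drop = FALSE], cat_)$canonical
      seen <- union(seen, canon[!is.na(canon)])
    }
    for (g in seen) assign(g, (mget(g, recount, ifnotfound = 0L))[[1]] + 1L,
                           recount)
  }
  expected <- unlist(as.list(recount))
  expect_equal(ft$counts[sort(names(expected))],
               expected[sort(names(expected))])
  expect_true(all(ft$counts <= ft$denominator))
})

test_that("empty corpus yields an empty table with denominator 0", {
  cat_ <- the_catalog()
  empty <- assemble_corpus(stats::setNames(list(), character(0)),
                           stats::setNames(list(), character(0)))
  ft <- build_frequency_table(empty, "gene", cat_, ranking_config())
  expect_length(ft$counts, 0L)
  expect_equal(ft$denominator, 0L)
  expect_equal(nrow(top_ranked(ft)), 0L)
})

test_that("top_ranked applies the strict >min_genomes cutoff and tie-break", {
  ft <- structure(list(axis = "gene",
                       counts = c(a = 400L, b = 301L, c = 300L),
                       denominator = 500L),
                  class = "frequency_table")
  top <- top_ranked(ft, ranking_config(min_genomes = 300))
  expect_equal(top$key, c("a", "b"))  # 300 excluded: strictly greater
  ft2 <- structure(list(axis = "gene", counts = c(y = 5L, x = 5L),
                        denominator = 10L),
                   class = "frequency_table")
  top2 <- top_ranked(ft2, ranking_config(min_genomes = 0))
  expect_equal(top2$key, c("x", "y"))  # lexicographic at equal counts
  expect_identical(top_ranked(ft2, ranking_config(min_genomes = 0)), top2)
})

test_that("consensus over the three published top-20 columns", {
  cat_ <- the_catalog()
  gene_col <- c("rpoA", "rplQ", "rpsM", "rpsK", "nusA", "infB", "rpsD",
                "nusG", "rplK", "yhbc", "rplA", "rbfA", "rpmJ", "secE",
                "secY", "rpoB", "rplO", "truB", "mfd", "infA")
  fun_col <- c("DNA-directed RNA polymerase subunit alpha",
               "50S ribosomal protein L17", "30S ribosomal protein S11",
               "30S ribosomal protein S13",
               "transcription elongation factor NusA",
               "30S ribosomal protein S4",
               "translation initiation factor IF-2",
               "50S ribosomal protein L11", "50S ribosomal protein L1",
               "ribosome-binding factor A", "50S ribosomal protein L36",
               "50S ribosomal protein L15",
               "preprotein translocase subunit SecE",
               "transcription termination factor",
               "transcription-repair coupling factor",
               "preprotein translocase subunit SecY",
               "tRNA pseudouridine synthase B", "50S ribosomal protein L18",
               "30S ribosomal protein S5", "30S ribosomal protein S8")
  cog_col <- c("COG0202K", "COG0203J", "COG0099J", "COG0100J", "COG0195K",
               "COG0522J", "COG0532J", "COG0779S", "COG0250K", "COG0080J",
               "COG0081J", "COG0858J", "COG0257J", "COG0690U", "COG1197LK",
               "COG0201U", "COG0200J", "COG0130J", "COG2740K", "COG0361J")
  # independent hand-intersection with explicit canonical maps
  fun_map <- c("DNA-directed RNA polymerase subunit alpha" = "rpoA",
               "50S ribosomal protein L17" = "rplQ",
               "30S ribosomal protein S11" = "rpsK",
               "30S ribosomal protein S13" = "rpsM",
               "transcription elongation factor NusA" = "nusA",
               "30S ribosomal protein S4" = "rpsD",
               "translation initiation factor IF-2" = "infB",
               "50S ribosomal protein L11" = "rplK",
               "50S ribosomal protein L1" = "rplA",
               "ribosome-binding factor A" = "rbfA",
               "50S ribosomal protein L36" = "rpmJ",
               "50S ribosomal protein L15" = "rplO",
               "preprotein translocase subunit SecE" = "secE",
               "transcription termination factor" = "nusG",
               "transcription-repair coupling factor" = "mfd",
               "preprotein translocase subunit SecY" = "secY",
               "tRNA pseudouridine synthase B" = "truB",
               "50S ribosomal protein L18" = "rplR",
               "30S ribosomal protein S5" = "rpsE",
               "30S ribosomal protein S8" = "rpsH")
  cog_map <- c(COG0202K = "rpoA", COG0203J = "rplQ", COG0099J = "rpsM",
               COG0100J = "rpsK", COG0195K = "nusA", COG0522J = "rpsD",
               COG0532J = "infB", COG0779S = "rimP", COG0250K = "nusG",
               COG0080J = "rplK", COG0081J = "rplA", COG0858J = "rbfA",
               COG0257J = "rpmJ", COG0690U = "secE", COG1197LK = "mfd",
               COG0201U = "secY", COG0200J = "rplO", COG0130J = "truB",
               COG2740K = "ylxR", COG0361J = "infA")
  gene_canon <- ifelse(gene_col == "yhbc", "rimP", gene_col)
  by_hand <- sort(Reduce(intersect, list(gene_canon,
                                         unname(fun_map[fun_col]),
                                         unname(cog_map[cog_col]))))
  got <- consensus_genes(gene_col, fun_col, cog_col, cat_, min_rankings = 3)
  expect_equal(got, by_hand)
  expect_length(got, 17L)
  # monotone in min_rankings
  g2 <- consensus_genes(gene_col, fun_col, cog_col, cat_, min_rankings = 2)
  g1 <- consensus_genes(gene_col, fun_col, cog_col, cat_, min_rankings = 1)
  expect_true(all(got %in% g2))
  expect_true(all(g2 %in% g1))
  # a gene in only one list is excluded at min_rankings = 2
  expect_false("rpoB" %in% g2)
})

test_that("taxonomy summaries report exact fractions summing to one", {
  tax <- data.frame(genome_id = sprintf("G%02d", 1:10),
                    genus = c(rep("Escherichia", 7), rep("Pyrococcus", 3)),
                    phylum = c(rep("Proteobacteria", 7),
                               rep("Euryarchaeota", 3)),
                    labels = c(rep("pathogenic", 7), rep("archaea;soil", 3)),
                    stringsAsFactors = FALSE)
  st <- summarize_taxa(sprintf("G%02d", 1:10), tax, "label")
  expect_equal(st$fraction[st$group == "pathogenic"], 0.7)
  expect_equal(sum(st$fraction), 1, tolerance = 1e-12)
  # unmapped genomes fall into "unclassified"
  st2 <- summarize_taxa(c("X1", "X2"), tax, "genus")
  expect_equal(st2$group, "unclassified")
  expect_equal(st2$fraction, 1)
  # simulator-planted genus proportions are recovered exactly
  cfg <- simulation_config(n_genomes = 20, seed = 2,
                           taxonomy = c(Escherichia = 0.5, Neisseria = 0.3,
                                        Pyrococcus = 0.2),
                           genes_per_genome = c(6, 8))
  sim <- simulate_corpus(cfg)
  st3 <- summarize_taxa(names(sim$corpus$genomes), sim$manifest$taxonomy,
                        "genus")
  expect_equal(st3$fraction[match(c("Escherichia", "Neisseria", "Pyrococcus"),
                                  st3$group)],
               c(0.5, 0.3, 0.2))
  expect_equal(sum(st3$fraction), 1, tolerance = 1e-12)
})
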