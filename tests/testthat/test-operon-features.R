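mk <- function(lt, start, end, strand = "+", genome = "G") {
  gene_record(genome, lt, start = start, end = end, strand = strand)
}

test_that("intergenic distance follows the coordinate formula", {
  expect_equal(intergenic_distance(mk("a", 1, 1000), mk("b", 1001, 1500)), 0L)
  expect_equal(intergenic_distance(mk("a", 1, 200), mk("b", 151, 600)), -50L)
  expect_equal(intergenic_distance(mk("a", 1, 100), mk("b", 351, 700)), 250L)
  expect_error(intergenic_distance(mk("a", 1, 100),
                                   mk("b", 351, 700, genome = "H")),
               "different genomes")
  # translation invariance
  set.seed(4)
  for (i in 1:20) {
    e1 <- sample(100:5000, 1); s2 <- sample(100:5000, 1)
    off <- sample(1:10000, 1)
    d1 <- intergenic_distance(mk("a", 1, e1), mk("b", s2 + e1, s2 + e1 + 99))
    d2 <- intergenic_distance(mk("a", 1 + off, e1 + off),
                              mk("b", s2 + e1 + off, s2 + e1 + 99 + off))
    expect_identical(d1, d2)
  }
})

test_that("cutoff filter is inclusive at both bounds", {
  cfg <- feature_config()
  expect_true(within_cutoffs(-50L, cfg))
  expect_true(within_cutoffs(0L, cfg))
  expect_true(within_cutoffs(250L, cfg))
  expect_false(within_cutoffs(-51L, cfg))
  expect_false(within_cutoffs(251L, cfg))
})

test_that("phylogenetic profiles recover planted presence patterns", {
  cat_ <- the_catalog()
  corpus <- make_corpus(list(list(c("rpoA", "rplQ")),
                             list(c("zzA", "zzB")),
                             list(c("rpoA", "zzC"))))
  p <- phylogenetic_profile("rpoA", corpus, cat_)
  expect_equal(p, c(G001 = 1L, G002 = 0L, G003 = 1L))
  expect_equal(sum(phylogenetic_profile("mfd", corpus, cat_)), 0L)
})

test_that("profile distance is symmetric, zero iff identical", {
  cfg <- feature_config()
  p <- c(1L, 0L, 1L, 0L)
  expect_equal(profile_distance(p, p, cfg), 0)
  q <- 1L - p
  # complementary profiles at presence 0.5: h = 1, H = 1 each
  expect_equal(profile_distance(p, q, cfg), 1 / (cfg$epsilon + 1))
  expect_equal(profile_distance(rep(1L, 5), rep(1L, 5), cfg), 0)
  expect_error(profile_distance(p, c(1L, 0L)), "length mismatch")
  set.seed(8)
  for (i in 1:25) {
    a <- sample(0:1, 12, replace = TRUE)
    b <- sample(0:1, 12, replace = TRUE)
    expect_equal(profile_distance(a, b, cfg), profile_distance(b, a, cfg))
    expect_gte(profile_distance(a, b, cfg), 0)
  }
})

test_that("neighborhood conservation uses Laplace-smoothed likelihood", {
  cat_ <- the_catalog()
  # always adjacent in all 8 genomes containing both
  corpus <- make_corpus(rep(list(list(c("nusA", "infB"))), 8))
  expect_equal(neighborhood_conservation("nusA", "infB", corpus, cat_),
               -log(9 / 10), tolerance = 1e-12)
  # both present in 8 genomes, never adjacent (separate cassettes)
  corpus2 <- make_corpus(rep(list(list(c("nusA", "zzA"), c("infB", "zzB"))),
                             8))
  expect_equal(neighborhood_conservation("nusA", "infB", corpus2, cat_),
               -log(1 / 10), tolerance = 1e-12)
  # never co-resident: the smoothed fallback -ln(1/2)
  corpus3 <- make_corpus(list(list(c("nusA", "zzA"))))
  expect_equal(neighborhood_conservation("nusA", "infB", corpus3, cat_),
               -log(1 / 2), tolerance = 1e-12)
  # strictly decreasing in n_adj at fixed n_both (brute force on the
  # smoothing formula realized by corpora is quadratic; assert the
  # realized endpoints bracket every mixture)
  for (n_adj in c(0, 3, 8)) {
    specs <- c(rep(list(list(c("nusA", "infB"))), n_adj),
               rep(list(list(c("nusA", "zzA"), c("infB", "zzB"))), 8 - n_adj))
    s <- neighborhood_conservation("nusA", "infB", make_corpus(specs), cat_)
    expect_equal(s, -log((n_adj + 1) / 10), tolerance = 1e-12)
  }
})

test_that("length ratio is the log ratio of gene lengths", {
  expect_equal(length_ratio_score(mk("a", 1, 300), mk("b", 400, 699)), 0)
  expect_equal(length_ratio_score(mk("a", 1, 600), mk("b", 700, 999)),
               log(2), tolerance = 1e-12)
  expect_equal(length_ratio_score(mk("a", 1, 300), mk("b", 400, 999)),
               -log(2), tolerance = 1e-12)
})

test_that("motif frequencies scan the strand-aware upstream window", {
  win <- 100L
  cfg <- feature_config(motifs = c("TATAAT"))
  # plus strand: window is the 100 nt before start
  seq_plus <- paste0(strrep("C", 50), "TATAAT", strrep("C", 94),
                     strrep("G", 60))
  genes <- rbind(
    gene_record("G", "up", start = 1, end = 50, strand = "+"),
    gene_record("G", "dn", start = 151, end = 210, strand = "+"))
  genes$length <- genes$end - genes$start + 1L
  ann <- genome_annotation("G", genes, sequence = seq_plus)
  f <- motif_frequencies(ann, ann$genes[2, ], cfg)
  expect_equal(unname(f["TATAAT"]), 1 / 95)
  expect_false(attr(f, "truncated"))
  # all-C window: zero
  seqC <- paste0(strrep("C", 150), strrep("G", 60))
  annC <- genome_annotation("G", genes, sequence = seqC)
  expect_equal(unname(motif_frequencies(annC, annC$genes[2, ], cfg)[1]), 0)
  # minus strand: window is the reverse complement 3' of end
  m_genes <- rbind(
    gene_record("G", "dn", start = 1, end = 60, strand = "-"),
    gene_record("G", "up", start = 200, end = 260, strand = "-"))
  m_genes$length <- m_genes$end - m_genes$start + 1L
  # place ATTATA (revcomp of TATAAT) right after the - strand gene end
  seq_minus <- paste0(strrep("C", 60), "ATTATA", strrep("C", 94),
                      strrep("G", 120))
  annM <- genome_annotation("G", m_genes, sequence = seq_minus)
  fM <- motif_frequencies(annM, annM$genes[1, ], cfg)
  expect_equal(unname(fM["TATAAT"]), 1 / 95)
  # missing sequence errors
  ann0 <- genome_annotation("G", genes)
  expect_error(motif_frequencies(ann0, ann0$genes[2, ], cfg), "no sequence")
  # frequencies are bounded and translation-invariant
  expect_true(all(f >= 0 & f <= 1))
})

test_that("IUPAC ambiguity codes in motifs are honored", {
  cfg <- feature_config(motifs = c("TANNNT"))
  seq_ <- paste0(strrep("C", 50), "TACGGT", strrep("C", 94), strrep("G", 60))
  genes <- rbind(
    gene_record("G", "up", start = 1, end = 50, strand = "+"),
    gene_record("G", "dn", start = 151, end = 210, strand = "+"))
  genes$length <- genes$end - genes$start + 1L
  ann <- genome_annotation("G", genes, sequence = seq_)
  expect_equal(unname(motif_frequencies(ann, ann$genes[2, ], cfg)[1]),
               1 / 95)
})
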