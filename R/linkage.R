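# Logical matrix: rows = annotation records of the whole corpus, columns =
# the given canonical genes; TRUE where the record carries that gene's
# identity (name, synonym or COG). Detects fused loci annotated with
# several gene identities.
.record_hits_matrix <- function(corpus, genes, catalog) {
  tabs <- lapply(names(corpus$genomes), function(gid) {
    g <- corpus$genomes[[gid]]$genes
    if (!nrow(g)) return(NULL)
    g[c("genome_id", "locus_tag", "gene_name", "synonyms", "cog_ids")]
  })
  tabs <- tabs[!vapply(tabs, is.null, TRUE)]
  if (!length(tabs))
    return(list(records = data.frame(genome_id = character(0)),
                hits = matrix(FALSE, 0, length(genes),
                              dimnames = list(NULL, genes))))
  rec <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  nm <- tolower(ifelse(is.na(rec$gene_name), "", rec$gene_name))
  syn <- lapply(strsplit(rec$synonyms, ";", fixed = TRUE), tolower)
  cog <- strsplit(rec$cog_ids, ";", fixed = TRUE)
  hits <- vapply(genes, function(g) {
    ids <- tolower(c(g, names(catalog$syn_lut)[catalog$syn_lut == g]))
    gcogs <- catalog$cog_tab$cog[catalog$cog_tab$canonical == g]
    nm %in% ids |
      vapply(syn, function(s) any(s %in% ids), TRUE) |
      vapply(cog, function(cc) any(cc %in% gcogs), TRUE)
  }, logical(nrow(rec)))
  list(records = rec, hits = hits)
}

# All three channel scores for one gene pair, sharing one counting pass.
# Presence of a gene in a genome counts either through full resolution or
# through a record carrying the gene's identity (so a fused dual-identity
# locus makes the genome count as containing both genes).
.pair_scores <- function(geneA, geneB, corpus, catalog, resolved = NULL,
                         resolved_genomes = NULL, hits = NULL) {
  if (is.null(hits))
    hits <- .record_hits_matrix(corpus, c(geneA, geneB), catalog)
  counts <- .pair_genome_counts(geneA, geneB, corpus, catalog, resolved,
                                resolved_genomes)
  presA <- unique(hits$records$genome_id[hits$hits[, geneA]])
  presB <- unique(hits$records$genome_id[hits$hits[, geneB]])
  both <- union(counts$both, intersect(presA, presB))
  if (!length(both))
    return(list(fusion = 0, neighborhood = 0, cooccurrence = 0))
  dual <- unique(hits$records$genome_id[hits$hits[, geneA] &
                                          hits$hits[, geneB]])
  fused <- union(counts$fused, dual)
  list(fusion = length(fused) / length(both),
       neighborhood = counts$n_adj / length(both),
       cooccurrence = counts$n_same / length(both))
}

#' Gene-fusion linkage score
#'
#' Fraction, over genomes containing both genes, in which the two are fused:
#' either a single annotated locus carries both gene identities, or the two
#' are adjacent cassette members with no intergenic sequence (intergenic
#' distance <= 0). 0 when no genome contains both.
#'
#' @param geneA,geneB Canonical catalog genes.
#' @param corpus A `cassette_corpus`.
#' @param catalog A `curated_catalog`.
#' @param resolved,resolved_genomes Optional precomputed
#'   [cassette_gene_table()] / [resolve_annotations()] results.
#' @return Real in `[0, 1]`.
#' @export
fusion_score <- function(geneA, geneB, corpus, catalog, resolved = NULL,
                         resolved_genomes = NULL) {
  .pair_scores(geneA, geneB, corpus, catalog, resolved,
               resolved_genomes)$fusion
}

#' Gene-neighborhood linkage score
#'
#' Fraction, over genomes containing both genes, in which they are
#' consecutive members of the same cassette.
#'
#' @inheritParams fusion_score
#' @return Real in `[0, 1]`.
#' @export
neighborhood_score <- function(geneA, geneB, corpus, catalog, resolved = NULL,
                               resolved_genomes = NULL) {
  .pair_scores(geneA, geneB, corpus, catalog, resolved,
               resolved_genomes)$neighborhood
}

#' Gene co-occurrence linkage score
#'
#' Fraction, over genomes containing both genes, in which both occur in the
#' same cassette (any positions; intervening genes allowed).
#'
#' @inheritParams fusion_score
#' @return Real in `[0, 1]`.
#' @export
cooccurrence_score <- function(geneA, geneB, corpus, catalog, resolved = NULL,
                               resolved_genomes = NULL) {
  .pair_scores(geneA, geneB, corpus, catalog, resolved,
               resolved_genomes)$cooccurrence
}

#' Build the three-channel linkage graph over a gene set
#'
#' Computes, for every unordered gene pair, the fusion, neighborhood and
#' co-occurrence scores, plus a combined score. An edge is "confident" in a
#' channel iff its score is strictly greater than the threshold.
#'
#' @param gene_set Character vector of >= 2 canonical genes.
#' @param corpus A `cassette_corpus`.
#' @param catalog A `curated_catalog`.
#' @param threshold Confidence threshold (default 0.7, strict `>`).
#' @param combine `"max"` (default) or `"mean"` over the three channels.
#' @return An object of class `linkage_graph`: `nodes`, `edges` (data.frame
#'   `geneA, geneB, fusion, neighborhood, cooccurrence, combined`),
#'   `threshold`, `combine`.
#' @export
build_linkage_graph <- function(gene_set, corpus, catalog, threshold = 0.7,
                                combine = c("max", "mean")) {
  combine <- match.arg(combine)
  gene_set <- sort(unique(as.character(gene_set)))
  if (length(gene_set) < 2)
    stop("build_linkage_graph: need at least 2 genes")
  resolved <- cassette_gene_table(corpus, catalog)
  resolved_genomes <- resolve_annotations(corpus, catalog)
  hits <- .record_hits_matrix(corpus, gene_set, catalog)
  pairs <- utils::combn(gene_set, 2)
  edges <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sc <- .pair_scores(a, b, corpus, catalog, resolved, resolved_genomes,
                       hits = hits)
    data.frame(geneA = a, geneB = b, fusion = sc$fusion,
               neighborhood = sc$neighborhood,
               cooccurrence = sc$cooccurrence, stringsAsFactors = FALSE)
  }))
  edges$combined <- if (combine == "max")
    pmax(edges$fusion, edges$neighborhood, edges$cooccurrence)
  else (edges$fusion + edges$neighborhood + edges$cooccurrence) / 3
  structure(list(nodes = gene_set, edges = edges, threshold = threshold,
                 combine = combine),
            class = "linkage_graph")
}

#' @export
print.linkage_graph <- function(x, ...) {
  conf <- confident_edges(x)
  cat("<linkage_graph> ", length(x$nodes), " genes, ",
      nrow(x$edges), " scored pairs, threshold ", x$threshold, " (",
      sum(conf$fusion), "/", sum(conf$neighborhood), "/",
      sum(conf$cooccurrence),
      " confident fusion/neighborhood/cooccurrence edges)\n", sep = "")
  invisible(x)
}

#' Confident-edge indicator per channel
#'
#' @param graph A `linkage_graph`.
#' @return Data.frame of logicals (`fusion, neighborhood, cooccurrence`),
#'   one row per edge, `TRUE` iff the channel score exceeds the threshold
#'   strictly.
#' @export
confident_edges <- function(graph) {
  data.frame(fusion = graph$edges$fusion > graph$threshold,
             neighborhood = graph$edges$neighborhood > graph$threshold,
             cooccurrence = graph$edges$cooccurrence > graph$threshold)
}

#' Extract candidate cassettes from a linkage graph
#'
#' Per channel, the connected components (size >= 2) of the confident edges
#' become candidate cassettes; each candidate's genome count and frequency
#' are computed by the matching rules over the corpus.
#'
#' @param graph A `linkage_graph`.
#' @param corpus A `cassette_corpus`.
#' @param catalog A `curated_catalog`.
#' @param resolved Optional precomputed [cassette_gene_table()].
#' @param denominator Genome count used for the frequency column (defaults
#'   to the corpus `both`-genome set size).
#' @return Data.frame `channel, genes` (comma-joined, sorted),
#'   `genome_count, frequency`, sorted by genome_count descending.
#' @export
extract_candidates <- function(graph, corpus, catalog, resolved = NULL,
                               denominator = NULL) {
  tab <- resolved %||% cassette_gene_table(corpus, catalog)
  if (is.null(denominator)) {
    cls <- classify_corpus(corpus, catalog, resolved = tab)
    denominator <- length(cls$both_genomes)
  }
  conf <- confident_edges(graph)
  out <- list()
  for (ch in c("fusion", "neighborhood", "cooccurrence")) {
    e <- graph$edges[conf[[ch]], c("geneA", "geneB"), drop = FALSE]
    if (!nrow(e)) next
    g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                       vertices = graph$nodes)
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
      genes <- sort(names(comp$membership)[comp$membership == ci])
      if (length(genes) < 2) next
      rep_ <- count_genomes(cassette_query(genes), corpus, catalog,
                            resolved = tab)
      out[[length(out) + 1L]] <- data.frame(
        channel = ch, genes = paste(genes, collapse = ","),
        genome_count = rep_$genome_count,
        frequency = if (denominator > 0)
          rep_$genome_count / denominator else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(channel = character(0), genes = character(0),
                      genome_count = integer(0), frequency = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(-res$genome_count, res$channel, res$genes), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Within-cluster sum of squares of a 2-partition of matrix rows.
.wss2 <- function(m, assign) {
  s <- 0
  for (k in unique(assign)) {
    rows <- m[assign == k, , drop = FALSE]
    ctr <- colMeans(rows)
    s <- s + sum(sweep(rows, 2, ctr)^2)
  }
  s
}

#' Bipartition the linkage graph by k-means (k = 2)
#'
#' Clusters genes into two groups by k-means on the rows of the symmetric
#' combined-score matrix (diagonal 1). For up to 12 nodes the optimal
#' 2-partition is found exactly by enumerating all assignments; larger
#' problems use seeded multi-restart k-means keeping the best
#' within-cluster sum of squares. The cluster containing the
#' lexicographically smallest gene is always reported first, making the
#' output deterministic under ties.
#'
#' @param graph A `linkage_graph`.
#' @param k Number of clusters (only 2 supported).
#' @param seed Integer seed for the k-means restarts.
#' @param restarts Number of random initializations (default 10).
#' @return List with `clusters` (list of two sorted gene vectors) and
#'   `withinss` (the achieved objective).
#' @export
bipartition <- function(graph, k = 2L, seed = 1L, restarts = 10L) {
  if (k != 2L) stop("bipartition: only k = 2 is supported")
  nodes <- graph$nodes
  n <- length(nodes)
  if (n < k) stop("bipartition: need at least ", k, " nodes")
  m <- diag(1, n)
  dimnames(m) <- list(nodes, nodes)
  e <- graph$edges
  m[cbind(e$geneA, e$geneB)] <- e$combined
  m[cbind(e$geneB, e$geneA)] <- e$combined
  if (n <= 12L) {
    best <- NULL; best_wss <- Inf
    # enumerate assignments with node 1 fixed in cluster 1 (halves the space)
    for (code in 0:(2^(n - 1L) - 1L)) {
      assign <- c(1L, 1L + as.integer(intToBits(code))[seq_len(n - 1L)])
      if (length(unique(assign)) < 2L) next
      w <- .wss2(m, assign)
      if (w < best_wss - 1e-12) { best_wss <- w; best <- assign }
    }
    assign <- best; wss <- best_wss
  } else {
    set.seed(seed)
    best <- NULL; best_wss <- Inf
    for (r in seq_len(restarts)) {
      km <- tryCatch(stats::kmeans(m, centers = 2L, nstart = 1L),
                     error = function(e) NULL)
      if (is.null(km)) next
      if (km$tot.withinss < best_wss - 1e-12) {
        best_wss <- km$tot.withinss; best <- km$cluster
      }
    }
    assign <- unname(best); wss <- best_wss
  }
  first <- assign[1L]  # nodes are sorted: cluster of the smallest gene leads
  clusters <- list(sort(nodes[assign == first]),
                   sort(nodes[assign != first]))
  list(clusters = clusters, withinss = wss)
}

#' Write a linkage graph's edge list as TSV
#'
#' @param graph A `linkage_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linkage_edges <- function(graph, path) {
  conf <- confident_edges(graph)
  chans <- apply(conf, 1, function(r)
    paste(c("fusion", "neighborhood", "cooccurrence")[r], collapse = ";"))
  df <- cbind(graph$edges, confident_channels = chans)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(format(df, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}
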