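# Multiplicative 31-bit string hash; stamps artifact tables with the
# configuration that produced them.
.string_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.config_hash <- function(config) {
  .string_hash(paste(deparse(config[setdiff(names(config), "out_dir")]),
                     collapse = ""))
}

#' Pipeline configuration
#'
#' Bundles every stage's inputs and parameters: either a simulation config
#' (the corpus is generated) or paths to annotation/operon/taxonomy tables,
#' the catalog, the ranking and feature configurations, the linkage
#' threshold, the enrichment alpha, explicit queries to count, and the seed.
#'
#' @param out_dir Artifact directory (created).
#' @param simulate Optional [simulation_config()]; when given, the corpus is
#'   simulated under `out_dir/corpus`.
#' @param annotations,operons,taxonomy Input paths (TSV dialects) when
#'   `simulate` is `NULL`.
#' @param catalog Path to a catalog TSV, or `NULL` for the bundled default.
#' @param term_map Optional path to a term-to-gene TSV for enrichment.
#' @param ranking A [ranking_config()].
#' @param features A [feature_config()].
#' @param linkage_threshold Confidence threshold for linkage edges
#'   (default 0.7, strict).
#' @param min_rankings Consensus requirement across the three ranked axes
#'   (default 2).
#' @param alpha BH-FDR significance level (default 0.05).
#' @param queries Optional list of character vectors: cassette queries to
#'   count in addition to the linkage candidates.
#' @param seed Integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, annotations = NULL,
                            operons = NULL, taxonomy = NULL, catalog = NULL,
                            term_map = NULL, ranking = ranking_config(),
                            features = feature_config(),
                            linkage_threshold = 0.7, min_rankings = 2L,
                            alpha = 0.05, queries = NULL, seed = 1L) {
  if (is.null(simulate)) {
    if (is.null(annotations) || is.null(operons))
      stop("pipeline_config: need either a simulation config or ",
           "annotations + operons paths")
    for (p in c(annotations, operons, taxonomy, catalog, term_map))
      if (!is.null(p) && !file.exists(p))
        stop("pipeline_config: missing input file: ", p)
  }
  if (!is.null(catalog) && !file.exists(catalog))
    stop("pipeline_config: missing catalog file: ", catalog)
  structure(list(out_dir = out_dir, simulate = simulate,
                 annotations = annotations, operons = operons,
                 taxonomy = taxonomy, catalog = catalog,
                 term_map = term_map, ranking = ranking,
                 features = features,
                 linkage_threshold = linkage_threshold,
                 min_rankings = as.integer(min_rankings), alpha = alpha,
                 queries = queries, seed = as.integer(seed)),
            class = "pipeline_config")
}

.artifact <- function(df, path, hash) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("# config_hash: ", hash),
               paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    df[] <- lapply(df, function(col) {
      if (is.character(col)) { col[is.na(col)] <- ""; col } else col
    })
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, eol = "\n")
  }
  invisible(path)
}

#' Run the full cassette-mining pipeline
#'
#' Executes simulate (optional) -> ingest -> classify -> rank -> link ->
#' count -> enrich -> summarize, writing every intermediate table under
#' `config$out_dir`. Identical config and seed produce byte-identical
#' artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`corpus`,
#'   `classification`, `rankings`, `consensus`, `graph`, `candidates`,
#'   `counts`, `enrichment`, `taxa`) and `artifacts` (named file paths).
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  catalog <- if (is.null(config$catalog)) default_catalog()
             else load_catalog(config$catalog)
  # -- ingest / simulate
  if (!is.null(config$simulate)) {
    sim <- simulate_corpus(config$simulate, catalog = catalog,
                           out_dir = file.path(out, "corpus"))
    corpus <- sim$corpus
    taxonomy <- sim$manifest$taxonomy
  } else {
    anns <- read_annotations(config$annotations, format = "tsv")
    ops <- read_operon_table(config$operons)
    corpus <- assemble_corpus(anns, ops)
    taxonomy <- if (!is.null(config$taxonomy))
      read_taxonomy_map(config$taxonomy)
    else data.frame(genome_id = names(corpus$genomes), genus = "",
                    phylum = "", labels = "", stringsAsFactors = FALSE)
  }
  artifacts <- character(0)
  resolved <- cassette_gene_table(corpus, catalog)
  # -- classify
  cls <- classify_corpus(corpus, catalog, resolved = resolved)
  artifacts["category_tallies"] <- .artifact(
    cls$tallies, file.path(out, "category_tallies.tsv"), hash)
  artifacts["both_genomes"] <- .artifact(
    data.frame(genome_id = cls$both_genomes, stringsAsFactors = FALSE),
    file.path(out, "both_genomes.tsv"), hash)
  # -- rank
  rankings <- list()
  tops <- list()
  for (axis in c("gene", "function", "cog")) {
    ft <- build_frequency_table(corpus, axis, catalog, config$ranking,
                                resolved = resolved, classification = cls)
    rankings[[axis]] <- ft
    tops[[axis]] <- top_ranked(ft, config$ranking)
    artifacts[paste0("ranked_", axis)] <- .artifact(
      tops[[axis]], file.path(out, paste0("ranked_", axis, ".tsv")), hash)
  }
  consensus <- consensus_genes(tops$gene, tops$`function`, tops$cog,
                               catalog, min_rankings = config$min_rankings)
  artifacts["consensus_genes"] <- .artifact(
    data.frame(gene = consensus, stringsAsFactors = FALSE),
    file.path(out, "consensus_genes.tsv"), hash)
  # -- link
  graph <- NULL
  candidates <- data.frame(channel = character(0), genes = character(0),
                           genome_count = integer(0), frequency = numeric(0),
                           stringsAsFactors = FALSE)
  if (length(consensus) >= 2) {
    graph <- build_linkage_graph(consensus, corpus, catalog,
                                 threshold = config$linkage_threshold)
    artifacts["linkage_edges"] <- .artifact(
      cbind(graph$edges,
            confident_channels = apply(confident_edges(graph), 1,
                                       function(r) paste(
                                         c("fusion", "neighborhood",
                                           "cooccurrence")[r],
                                         collapse = ";"))),
      file.path(out, "linkage_edges.tsv"), hash)
    candidates <- extract_candidates(graph, corpus, catalog,
                                     resolved = resolved,
                                     denominator = length(cls$both_genomes))
    if (length(consensus) >= 2) {
      bp <- bipartition(graph, seed = config$seed)
      artifacts["clusters"] <- .artifact(
        data.frame(gene = unlist(bp$clusters),
                   cluster = rep(c(1L, 2L), lengths(bp$clusters)),
                   stringsAsFactors = FALSE),
        file.path(out, "clusters.tsv"), hash)
    }
  } else {
    artifacts["linkage_edges"] <- .artifact(
      data.frame(geneA = character(0), geneB = character(0),
                 fusion = numeric(0), neighborhood = numeric(0),
                 cooccurrence = numeric(0), combined = numeric(0),
                 confident_channels = character(0), stringsAsFactors = FALSE),
      file.path(out, "linkage_edges.tsv"), hash)
  }
  artifacts["candidates"] <- .artifact(
    candidates, file.path(out, "candidates.tsv"), hash)
  # -- count: linkage candidates plus explicit queries
  qsets <- unique(c(lapply(unique(candidates$genes),
                           function(s) strsplit(s, ",", fixed = TRUE)[[1]]),
                    config$queries))
  counts <- list()
  rows <- list()
  for (q in qsets) {
    query <- cassette_query(q)
    rep_ <- count_genomes(query, corpus, catalog, resolved = resolved)
    indep <- independence_fraction(query, corpus, catalog,
                                   resolved = resolved, report = rep_)
    partners <- cooccurring_partners(query, corpus, catalog,
                                     resolved = resolved, report = rep_)
    counts[[paste(q, collapse = ",")]] <-
      list(report = rep_, independence = indep, partners = partners)
    rows[[length(rows) + 1L]] <- data.frame(
      query = paste(q, collapse = ","),
      genome_count = rep_$genome_count,
      n_exact = rep_$rule_tallies[["exact"]],
      n_reordered = rep_$rule_tallies[["reordered"]],
      n_subset = rep_$rule_tallies[["subset"]],
      independence_fraction = if (is.na(indep)) NA_real_ else indep,
      top_partners = paste(utils::head(partners$partner, 3), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  count_tab <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(query = character(0), genome_count = integer(0),
                  n_exact = integer(0), n_reordered = integer(0),
                  n_subset = integer(0), independence_fraction = numeric(0),
                  top_partners = character(0), stringsAsFactors = FALSE)
  count_tab <- count_tab[order(-count_tab$genome_count, count_tab$query), ,
                         drop = FALSE]
  artifacts["cassette_counts"] <- .artifact(
    count_tab, file.path(out, "cassette_counts.tsv"), hash)
  # -- enrich
  enr <- NULL
  if (!is.null(config$term_map)) {
    universe <- sort(unique(stats::na.omit(resolved$canonical)))
    query <- intersect(consensus, universe)
    enr <- run_ora(query, read_term_map(config$term_map), universe,
                   alpha = config$alpha)
    artifacts["enrichment"] <- .artifact(
      enr, file.path(out, "enrichment.tsv"), hash)
  }
  # -- summarize taxa of each counted query's matched genomes
  taxa_rows <- list()
  for (qn in names(counts)) {
    rep_ <- counts[[qn]]$report
    if (rep_$genome_count == 0) next
    st <- summarize_taxa(rep_$by_genome$genome_id, taxonomy, "genus")
    taxa_rows[[length(taxa_rows) + 1L]] <-
      cbind(data.frame(query = qn, stringsAsFactors = FALSE), st)
  }
  taxa_tab <- if (length(taxa_rows))
    do.call(rbind, c(taxa_rows, list(make.row.names = FALSE)))
  else data.frame(query = character(0), group = character(0),
                  count = integer(0), fraction = numeric(0),
                  stringsAsFactors = FALSE)
  artifacts["taxonomy_summary"] <- .artifact(
    taxa_tab, file.path(out, "taxonomy_summary.tsv"), hash)
  # -- run manifest
  manifest <- data.frame(
    key = c("config_hash", "seed", "n_genomes", "n_cassettes",
            "n_both_genomes", "n_consensus_genes", "n_candidates",
            "n_counted_queries"),
    value = c(hash, config$seed, length(corpus$genomes), n_cassettes(corpus),
              length(cls$both_genomes), length(consensus),
              nrow(candidates), length(counts)),
    stringsAsFactors = FALSE)
  artifacts["run_manifest"] <- .artifact(
    manifest, file.path(out, "run_manifest.tsv"), hash)
  invisible(list(corpus = corpus, classification = cls, rankings = rankings,
                 tops = tops, consensus = consensus, graph = graph,
                 candidates = candidates, counts = counts, enrichment = enr,
                 taxa = taxa_tab, artifacts = artifacts, config_hash = hash))
}
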