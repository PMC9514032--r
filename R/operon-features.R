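#' Feature configuration for operon-pair classification
#'
#' Houses the intergenic-distance cutoffs (nt), the upstream motif window and
#' motif list, and the numerical smoothing constants.
#'
#' @param d_i_min,d_i_max Intergenic-distance cutoffs in nt (defaults -50 and
#'   250): pairs whose distance falls outside this band are treated as
#'   operon-boundary pairs regardless of the classifier.
#' @param upstream_window Length (nt) of the window 5' of the downstream
#'   gene's translational start scanned for motifs (default 100).
#' @param motifs Character vector of IUPAC motif strings (default none).
#' @param pseudocount Laplace pseudocount for the conservation score
#'   (default 1).
#' @param epsilon Small constant guarding divisions (default 1e-9).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(d_i_min = -50L, d_i_max = 250L,
                           upstream_window = 100L, motifs = character(0),
                           pseudocount = 1, epsilon = 1e-9) {
  stopifnot(d_i_min < d_i_max, upstream_window >= 1)
  structure(list(d_i_min = as.integer(d_i_min),
                 d_i_max = as.integer(d_i_max),
                 upstream_window = as.integer(upstream_window),
                 motifs = as.character(motifs),
                 pseudocount = pseudocount, epsilon = epsilon),
            class = "feature_config")
}

#' Intergenic distance between an adjacent gene pair
#'
#' `D_I = downstream_start - (upstream_end + 1)`; negative values mean the
#' two genes overlap. Depends only on the upstream end and downstream start,
#' so it is invariant to shifting both genes by a constant offset.
#'
#' @param upstream,downstream One-row gene tables (coordinate order:
#'   `upstream$start <= downstream$start`), from the same genome.
#' @return Signed integer distance in nt.
#' @export
#' @examples
#' a <- gene_record("G", "a", start = 1, end = 1000, strand = "+")
#' b <- gene_record("G", "b", start = 1001, end = 1500, strand = "+")
#' intergenic_distance(a, b)  # 0: abutting genes
intergenic_distance <- function(upstream, downstream) {
  if (!identical(upstream$genome_id[1], downstream$genome_id[1]))
    stop("intergenic_distance: genes from different genomes")
  as.integer(downstream$start[1] - (upstream$end[1] + 1L))
}

#' Is an intergenic distance within the operon-pair cutoffs?
#'
#' @param d_i Signed intergenic distance(s) in nt.
#' @param config A [feature_config()].
#' @return Logical: `d_i_min <= d_i <= d_i_max` (both inclusive).
#' @export
within_cutoffs <- function(d_i, config = feature_config()) {
  d_i >= config$d_i_min & d_i <= config$d_i_max
}

#' Phylogenetic (presence/absence) profile of a gene
#'
#' @param canonical_gene Canonical catalog gene.
#' @param corpus A `cassette_corpus`.
#' @param catalog A `curated_catalog`.
#' @param resolved_genomes Optional precomputed result of
#'   [resolve_annotations()] (named list of per-genome canonical gene sets).
#' @return Named integer (0/1) vector over sorted genome ids; 1 iff the gene
#'   is present anywhere in that genome's annotation.
#' @export
phylogenetic_profile <- function(canonical_gene, corpus, catalog,
                                 resolved_genomes = NULL) {
  sets <- resolved_genomes %||% resolve_annotations(corpus, catalog)
  gids <- sort(names(corpus$genomes))
  stats::setNames(
    as.integer(vapply(sets[gids], function(s) canonical_gene %in% s, TRUE)),
    gids)
}

#' Resolve every genome's annotation to canonical gene sets
#'
#' @param corpus A `cassette_corpus`.
#' @param catalog A `curated_catalog`.
#' @return Named list: genome id -> character vector of canonical genes
#'   present in the annotation.
#' @export
resolve_annotations <- function(corpus, catalog) {
  lapply(corpus$genomes, function(g) {
    if (!nrow(g$genes)) return(character(0))
    unique(stats::na.omit(resolve_genes(g$genes, catalog)$canonical))
  })
}

.binary_entropy <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' Phylogenetic-profile distance (functional relatedness)
#'
#' Distance between two presence/absence profiles combining the normalized
#' Hamming distance with the profiles' Shannon entropies:
#' `d = h / (eps + (H(p1) + H(p2)) / 2)` where `h` is the fraction of
#' disagreeing genomes and `H(p)` is the binary entropy of a profile's mean
#' presence frequency. Identical profiles give 0; smaller distances indicate
#' stronger functional relatedness.
#'
#' @param p1,p2 Equal-length 0/1 vectors over the same genome set.
#' @param config A [feature_config()] (supplies `epsilon`).
#' @return Non-negative real.
#' @export
profile_distance <- function(p1, p2, config = feature_config()) {
  if (length(p1) != length(p2))
    stop("profile_distance: profile length mismatch")
  if (length(p1) == 0) stop("profile_distance: empty profiles")
  h <- mean(p1 != p2)
  H <- (.binary_entropy(mean(p1)) + .binary_entropy(mean(p2))) / 2
  h / (config$epsilon + H)
}

#' Neighborhood conservation score of a gene pair
#'
#' Laplace-smoothed negative log-likelihood of observing the pair adjacent,
#' given co-residence: `s = -ln((n_adj + 1) / (n_both + 2))`, with `n_adj`
#' the number of genomes where the two genes are consecutive members of one
#' cassette and `n_both` the number of genomes containing both. Strictly
#' decreasing in `n_adj` at fixed `n_both`; small scores mark pairs that are
#' conserved neighbors (functionally related).
#'
#' @param geneA,geneB Canonical catalog genes.
#' @param corpus A `cassette_corpus`.
#' @param catalog A `curated_catalog`.
#' @param resolved Optional precomputed [cassette_gene_table()] with catalog
#'   columns.
#' @param resolved_genomes Optional precomputed [resolve_annotations()].
#' @return Non-negative real score.
#' @export
neighborhood_conservation <- function(geneA, geneB, corpus, catalog,
                                      resolved = NULL,
                                      resolved_genomes = NULL) {
  counts <- .pair_genome_counts(geneA, geneB, corpus, catalog, resolved,
                                resolved_genomes)
  -log((counts$n_adj + 1) / (counts$n_both + 2))
}

# Genome-level co-residence/adjacency/same-cassette counts for a gene pair.
.pair_genome_counts <- function(geneA, geneB, corpus, catalog,
                                resolved = NULL, resolved_genomes = NULL) {
  sets <- resolved_genomes %||% resolve_annotations(corpus, catalog)
  both <- names(sets)[vapply(sets, function(s) geneA %in% s && geneB %in% s,
                             TRUE)]
  tab <- resolved %||% cassette_gene_table(corpus, catalog)
  tab <- tab[tab$genome_id %in% both &
               !is.na(tab$canonical) &
               tab$canonical %in% c(geneA, geneB), , drop = FALSE]
  adj <- same <- fused <- character(0)
  if (nrow(tab)) {
    for (gid in unique(tab$genome_id)) {
      g <- tab[tab$genome_id == gid, , drop = FALSE]
      for (cid in unique(g$cassette_id)) {
        cg <- g[g$cassette_id == cid, , drop = FALSE]
        cg <- cg[order(cg$rank), , drop = FALSE]
        if (geneA %in% cg$canonical && geneB %in% cg$canonical) {
          same <- union(same, gid)
          pos <- cg$rank[cg$canonical %in% c(geneA, geneB)]
          pairs <- which(diff(cg$rank) == 1L)
          for (k in pairs) {
            if (setequal(cg$canonical[c(k, k + 1L)], c(geneA, geneB))) {
              adj <- union(adj, gid)
              d <- cg$start[k + 1L] - (cg$end[k] + 1L)
              if (d <= 0) fused <- union(fused, gid)
            }
          }
        }
      }
    }
  }
  list(n_both = length(both), n_adj = length(adj), n_same = length(same),
       n_fused = length(fused), both = both, adj = adj, same = same,
       fused = fused)
}

#' Log length-ratio of an adjacent gene pair
#'
#' @param upstream,downstream One-row gene tables.
#' @return `ln(length(upstream) / length(downstream))`.
#' @export
length_ratio_score <- function(upstream, downstream) {
  stopifnot(upstream$length[1] >= 1, downstream$length[1] >= 1)
  log(upstream$length[1] / downstream$length[1])
}

#' Motif frequencies in the upstream window of a gene
#'
#' Extracts the `upstream_window` nucleotides 5' of the downstream gene's
#' translational start on its coding strand (for `-` strand genes: the window
#' 3' of `end` in genome coordinates, reverse-complemented), counts each
#' configured IUPAC motif allowing overlaps, and normalizes each count by
#' `window length - motif length + 1`. Windows truncated at a contig edge are
#' flagged via the `"truncated"` attribute.
#'
#' @param genome A `genome_annotation` with a sequence.
#' @param downstream One-row gene table of the downstream gene.
#' @param config A [feature_config()] with a non-empty `motifs` list.
#' @return Named numeric vector in `[0, 1]`, one entry per motif, with
#'   attribute `truncated` (logical).
#' @export
motif_frequencies <- function(genome, downstream, config = feature_config()) {
  if (is.null(genome$sequence))
    stop("motif_frequencies: genome ", genome$genome_id, " has no sequence")
  w <- config$upstream_window
  seqlen <- nchar(genome$sequence)
  if (downstream$strand[1] == "+") {
    to <- downstream$start[1] - 1L
    from <- max(1L, to - w + 1L)
    truncated <- (to - from + 1L) < w || to < 1L
    win <- if (to >= from)
      Biostrings::DNAString(substr(genome$sequence, from, to))
    else Biostrings::DNAString("")
  } else {
    from <- downstream$end[1] + 1L
    to <- min(seqlen, from + w - 1L)
    truncated <- (to - from + 1L) < w || from > seqlen
    win <- if (to >= from)
      Biostrings::reverseComplement(
        Biostrings::DNAString(substr(genome$sequence, from, to)))
    else Biostrings::DNAString("")
  }
  wl <- length(win)
  freqs <- vapply(config$motifs, function(m) {
    ml <- nchar(m)
    denom <- wl - ml + 1L
    if (denom < 1L) return(0)
    n <- Biostrings::countPattern(Biostrings::DNAString(m), win,
                                  fixed = FALSE)
    n / denom
  }, 0)
  structure(freqs, truncated = truncated)
}

#' Feature rows for the adjacent gene pairs of one genome
#'
#' Walks the genome's genes in coordinate order and emits one row per
#' adjacent same-strand pair with the pair features the classifier consumes:
#' intergenic distance, log length-ratio, and (when a sequence and motifs are
#' available) per-motif upstream-window frequencies.
#'
#' @param genome A `genome_annotation`.
#' @param config A [feature_config()].
#' @return Data.frame with columns `upstream, downstream` (locus tags),
#'   `strand`, `d_i`, `length_ratio` and one `motif_<i>` column per motif.
#' @export
adjacent_pair_features <- function(genome, config = feature_config()) {
  genes <- genome$genes
  use_motifs <- length(config$motifs) > 0 && !is.null(genome$sequence)
  cols <- c("d_i", "length_ratio",
            if (use_motifs) paste0("motif_", seq_along(config$motifs)))
  if (nrow(genes) < 2) {
    out <- data.frame(upstream = character(0), downstream = character(0),
                      strand = character(0), stringsAsFactors = FALSE)
    for (cl in cols) out[[cl]] <- numeric(0)
    return(out)
  }
  i <- seq_len(nrow(genes) - 1L)
  same <- genes$strand[i] == genes$strand[i + 1L]
  i <- i[same]
  out <- data.frame(upstream = genes$locus_tag[i],
                    downstream = genes$locus_tag[i + 1L],
                    strand = genes$strand[i],
                    d_i = genes$start[i + 1L] - (genes$end[i] + 1L),
                    length_ratio = log(genes$length[i] /
                                         genes$length[i + 1L]),
                    stringsAsFactors = FALSE)
  if (use_motifs && nrow(out)) {
    mf <- t(vapply(i, function(k)
      as.numeric(motif_frequencies(genome, genes[k + 1L, , drop = FALSE],
                                   config)),
      numeric(length(config$motifs))))
    colnames(mf) <- paste0("motif_", seq_along(config$motifs))
    out <- cbind(out, mf)
  }
  out
}

#' Train the logistic operon-pair classifier
#'
#' Fits a logistic regression separating operon-internal from boundary pairs
#' on z-score standardized features; the standardization parameters are
#' stored with the model so prediction is reproducible.
#'
#' @param features Data.frame of numeric feature columns (e.g. from
#'   [adjacent_pair_features()], feature columns only).
#' @param labels Vector with values `"operon_pair"` / `"boundary_pair"` (or a
#'   logical, `TRUE` = operon pair).
#' @param seed Integer seed (the maximum-likelihood fit is deterministic; the
#'   seed is recorded for provenance).
#' @return An object of class `pair_classifier` with elements
#'   `feature_order`, `means`, `scales`, `weights` (including `(Intercept)`).
#' @export
train_pair_classifier <- function(features, labels, seed = 1L) {
  if (is.logical(labels))
    labels <- ifelse(labels, "operon_pair", "boundary_pair")
  y <- labels == "operon_pair"
  if (length(unique(y)) < 2)
    stop("train_pair_classifier: need both operon_pair and boundary_pair ",
         "examples")
  feats <- as.data.frame(features)
  feats <- feats[vapply(feats, is.numeric, TRUE)]
  if (ncol(feats) == 0) stop("train_pair_classifier: no numeric features")
  means <- vapply(feats, mean, 0)
  # population (1/n) scale: invariant under replicating the training set
  scales <- vapply(feats, function(x) sqrt(mean((x - mean(x))^2)), 0)
  scales[scales == 0 | !is.finite(scales)] <- 1
  z <- as.data.frame(scale(feats, center = means, scale = scales))
  set.seed(seed)
  # well-separated classes provoke glm's separation warnings; the fitted
  # decision boundary is still the quantity of interest here
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = cbind(y = y, z), family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("glm\\.fit|fitted probabilities", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(feature_order = names(feats), means = means,
                 scales = scales, weights = stats::coef(fit), seed = seed),
            class = "pair_classifier")
}

#' @export
print.pair_classifier <- function(x, ...) {
  cat("<pair_classifier> logistic operon-pair model on",
      length(x$feature_order), "feature(s):",
      paste(x$feature_order, collapse = ", "), "\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
coef.pair_classifier <- function(object, ...) object$weights

#' Predict operon-pair probabilities
#'
#' @param object A `pair_classifier`.
#' @param newdata Data.frame containing the classifier's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities that each pair is operon-internal.
#' @export
predict.pair_classifier <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_order, names(newdata))
  if (length(miss))
    stop("predict.pair_classifier: missing feature(s): ",
         paste(miss, collapse = ", "))
  z <- sweep(sweep(as.matrix(newdata[object$feature_order]), 2,
                   object$means, "-"),
             2, object$scales, "/")
  eta <- drop(cbind(1, z) %*%
                object$weights[c("(Intercept)", object$feature_order)])
  stats::plogis(eta)
}

#' Serialize / deserialize a pair classifier as TSV
#'
#' Plain, bit-stable TSV: one row per feature (name, mean, scale, weight)
#' plus an intercept row.
#'
#' @param classifier A `pair_classifier`.
#' @param path File path.
#' @return `path` invisibly (write) or the classifier (read).
#' @export
write_classifier <- function(classifier, path) {
  df <- data.frame(feature = c("(Intercept)", classifier$feature_order),
                   mean = c(0, unname(classifier$means)),
                   scale = c(1, unname(classifier$scales)),
                   weight = unname(classifier$weights[
                     c("(Intercept)", classifier$feature_order)]),
                   stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("feature\tmean\tscale\tweight", con)
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  feats <- df$feature[df$feature != "(Intercept)"]
  structure(list(feature_order = feats,
                 means = stats::setNames(df$mean[match(feats, df$feature)],
                                         feats),
                 scales = stats::setNames(df$scale[match(feats, df$feature)],
                                          feats),
                 weights = stats::setNames(df$weight,
                                           df$feature)[c("(Intercept)",
                                                         feats)],
                 seed = NA_integer_),
            class = "pair_classifier")
}

#' Predict operons (cassettes) for one genome
#'
#' Classifies every adjacent same-strand pair; pairs with predicted
#' operon-pair probability strictly above `threshold` AND intergenic distance
#' within the configured cutoffs are chained, maximal chains become
#' cassettes, and every remaining gene becomes a singleton cassette. The
#' output cassettes partition the genome's gene list.
#'
#' @param genome A `genome_annotation`.
#' @param classifier A `pair_classifier`.
#' @param config A [feature_config()].
#' @param threshold Pair-probability threshold (default 0.5).
#' @return Data.frame `cassette_id, locus_tag, rank` in the operon-table
#'   layout (one genome).
#' @export
predict_operons <- function(genome, classifier, config = feature_config(),
                            threshold = 0.5) {
  genes <- genome$genes
  n <- nrow(genes)
  if (n == 0)
    return(data.frame(cassette_id = character(0), locus_tag = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  joined <- rep(FALSE, max(n - 1L, 0L))
  if (n >= 2) {
    feats <- adjacent_pair_features(genome, config)
    if (nrow(feats)) {
      p <- predict(classifier, feats)
      ok <- p > threshold & within_cutoffs(feats$d_i, config)
      idx <- match(feats$upstream, genes$locus_tag)
      joined[idx[ok]] <- TRUE
    }
  }
  grp <- cumsum(c(1L, as.integer(!joined)))
  data.frame(cassette_id = sprintf("pred%04d", grp),
             locus_tag = genes$locus_tag,
             rank = stats::ave(seq_len(n), grp, FUN = seq_along),
             stringsAsFactors = FALSE)
}
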