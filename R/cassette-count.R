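#' Construct a cassette query
#'
#' A query is a set of at least two canonical catalog genes; its written
#' order defines the "exact" gene order for match reporting.
#'
#' @param genes Character vector of canonical genes, no duplicates.
#' @param catalog Optional `curated_catalog` to validate resolvability.
#' @return Character vector of class `cassette_query`.
#' @export
cassette_query <- function(genes, catalog = NULL) {
  genes <- as.character(genes)
  if (length(genes) < 2) stop("cassette_query: need at least 2 genes")
  if (anyDuplicated(genes)) stop("cassette_query: duplicate genes")
  if (!is.null(catalog)) {
    canon <- canonicalize_keys(genes, catalog)
    if (anyNA(canon))
      stop("cassette_query: unresolvable gene(s): ",
           paste(genes[is.na(canon)], collapse = ", "))
    genes <- canon
  }
  structure(genes, class = "cassette_query")
}

# Match one observed canonical gene sequence against a query.
# Returns "exact", "reordered", "subset" or NA (no-match).
.match_rule <- function(query, observed) {
  observed <- observed[!is.na(observed)]
  s <- unique(observed)
  if (!all(query %in% s)) return(NA_character_)
  if (setequal(s, query)) {
    first <- observed[!duplicated(observed)]
    if (identical(first, as.character(query))) "exact" else "reordered"
  } else "subset"
}

#' Match a cassette against a query
#'
#' Implements the three matching rules: a cassette matches a query if the
#' query genes appear in a different order (`reordered`), as a subset of a
#' larger cassette irrespective of order (`subset`), or as the cassette
#' itself in the query's written order (`exact`). Matching operates on
#' canonical gene sets after synonym resolution; unresolved cassette members
#' are transparent, and duplicate canonical genes collapse to a set.
#'
#' @param query A [cassette_query()] (or plain character vector, length >= 2).
#' @param cassette A `cassette` (see [get_cassette()]) or a gene table of its
#'   members in cassette order.
#' @param catalog A `curated_catalog`.
#' @return `"exact"`, `"reordered"`, `"subset"`, or `NA` for no-match.
#' @export
matches <- function(query, cassette, catalog) {
  genes <- if (inherits(cassette, "cassette")) cassette$genes else cassette
  observed <- resolve_genes(genes, catalog)$canonical
  .match_rule(query, observed)
}

.rule_levels <- c("exact", "reordered", "subset")

#' Count genomes containing a queried cassette
#'
#' A genome counts once no matter how many of its cassettes match; the
#' strongest rule present (`exact` > `reordered` > `subset`) is recorded per
#' genome.
#'
#' @param query A [cassette_query()].
#' @param corpus A `cassette_corpus`.
#' @param catalog A `curated_catalog`.
#' @param resolved Optional precomputed [cassette_gene_table()] with catalog
#'   columns.
#' @return An object of class `match_report`: `query`, `genome_count`,
#'   `matched` (data.frame `genome_id, cassette_id, rule`, one row per
#'   matching cassette), `by_genome` (data.frame `genome_id, rule`, strongest
#'   rule), `rule_tallies` (named integer vector over the three rules, by
#'   genome-level strongest rule).
#' @export
count_genomes <- function(query, corpus, catalog, resolved = NULL) {
  tab <- resolved %||% cassette_gene_table(corpus, catalog)
  matched <- data.frame(genome_id = character(0), cassette_id = character(0),
                        rule = character(0), stringsAsFactors = FALSE)
  if (nrow(tab)) {
    tab <- tab[order(tab$genome_id, tab$cassette_id, tab$rank), ,
               drop = FALSE]
    key <- paste(tab$genome_id, tab$cassette_id, sep = "\r")
    obs <- split(tab$canonical, factor(key, levels = unique(key)))
    rules <- vapply(obs, .match_rule, NA_character_, query = query)
    hit <- !is.na(rules)
    if (any(hit)) {
      ids <- do.call(rbind, strsplit(names(rules)[hit], "\r", fixed = TRUE))
      matched <- data.frame(genome_id = ids[, 1], cassette_id = ids[, 2],
                            rule = unname(rules[hit]),
                            stringsAsFactors = FALSE)
    }
  }
  if (nrow(matched)) {
    strongest <- tapply(factor(matched$rule, levels = .rule_levels),
                        matched$genome_id,
                        function(r) .rule_levels[min(as.integer(r))])
    by_genome <- data.frame(genome_id = names(strongest),
                            rule = as.vector(strongest),
                            stringsAsFactors = FALSE)
  } else {
    by_genome <- data.frame(genome_id = character(0), rule = character(0),
                            stringsAsFactors = FALSE)
  }
  by_genome <- by_genome[order(by_genome$genome_id), , drop = FALSE]
  rownames(by_genome) <- NULL
  tallies <- table(factor(by_genome$rule, levels = .rule_levels))
  structure(list(query = as.character(query),
                 genome_count = nrow(by_genome),
                 matched = matched, by_genome = by_genome,
                 rule_tallies = stats::setNames(as.integer(tallies),
                                                .rule_levels)),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report> query {", paste(x$query, collapse = ", "),
      "}: ", x$genome_count, " genome(s) [",
      paste(sprintf("%s=%d", names(x$rule_tallies), x$rule_tallies),
            collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Partner genes co-occurring with a queried cassette
#'
#' For each canonical gene outside the query, the fraction of matched
#' genomes in which some matching cassette also contains the partner.
#' Partners with fraction strictly above `min_fraction` are reported,
#' sorted by fraction descending (ties lexicographic).
#'
#' @inheritParams count_genomes
#' @param min_fraction Reporting threshold (default 0.5, i.e. "more than
#'   half of the matched genomes").
#' @param report Optional precomputed [count_genomes()] result for the query.
#' @return Data.frame `partner, n_genomes, fraction`.
#' @export
cooccurring_partners <- function(query, corpus, catalog, min_fraction = 0.5,
                                 resolved = NULL, report = NULL) {
  tab <- resolved %||% cassette_gene_table(corpus, catalog)
  rep_ <- report %||% count_genomes(query, corpus, catalog, resolved = tab)
  empty <- data.frame(partner = character(0), n_genomes = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE)
  if (rep_$genome_count == 0 || nrow(rep_$matched) == 0) return(empty)
  mkey <- paste(rep_$matched$genome_id, rep_$matched$cassette_id, sep = "\r")
  tab <- tab[paste(tab$genome_id, tab$cassette_id, sep = "\r") %in% mkey &
               !is.na(tab$canonical) &
               !(tab$canonical %in% as.character(query)), , drop = FALSE]
  if (!nrow(tab)) return(empty)
  pres <- unique(tab[c("genome_id", "canonical")])
  counts <- table(pres$canonical)
  out <- data.frame(partner = names(counts), n_genomes = as.integer(counts),
                    fraction = as.numeric(counts) / rep_$genome_count,
                    stringsAsFactors = FALSE)
  out <- out[out$fraction > min_fraction, , drop = FALSE]
  out <- out[order(-out$fraction, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of matched genomes where the cassette stands alone
#'
#' The fraction of matched genomes in which some matching cassette's
#' canonical gene set equals the query exactly (no extra genes), i.e. the
#' cassette exists independently rather than embedded in a larger cassette.
#'
#' @inheritParams cooccurring_partners
#' @return Real in `[0, 1]`, or `NA` when no genome matches.
#' @export
independence_fraction <- function(query, corpus, catalog, resolved = NULL,
                                  report = NULL) {
  rep_ <- report %||% count_genomes(query, corpus, catalog,
                                    resolved = resolved)
  if (rep_$genome_count == 0) return(NA_real_)
  standalone <- unique(
    rep_$matched$genome_id[rep_$matched$rule %in% c("exact", "reordered")])
  length(standalone) / rep_$genome_count
}
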