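#' Ranking configuration
#'
#' @param top_n Number of top keys to keep (default 20, the size of the
#'   published top lists).
#' @param min_genomes Genome-occurrence cutoff; keys must occur in strictly
#'   more than this many genomes (default 300).
#' @param restrict_to_category Cassette category whose cassettes feed the
#'   counts (default `"both"`); use `NA` to count over all cassettes.
#' @return A list of class `ranking_config`.
#' @export
ranking_config <- function(top_n = 20L, min_genomes = 300L,
                           restrict_to_category = "both") {
  stopifnot(top_n >= 1, min_genomes >= 0)
  structure(list(top_n = as.integer(top_n),
                 min_genomes = as.integer(min_genomes),
                 restrict_to_category = restrict_to_category),
            class = "ranking_config")
}

#' Build a genome-occurrence frequency table along one axis
#'
#' Counts, for each key on the chosen axis, the number of genomes in which
#' the key occurs in at least one cassette of the configured category. Keys
#' are: canonical catalog genes (`axis = "gene"`), lower-cased product
#' strings (`"function"`), or verbatim COG ids (`"cog"`). A gene appearing in
#' several cassettes of one genome contributes genome-level presence once.
#'
#' @param corpus A `cassette_corpus`.
#' @param axis `"gene"`, `"function"` or `"cog"`.
#' @param catalog A `curated_catalog`.
#' @param config A [ranking_config()].
#' @param resolved Optional precomputed [cassette_gene_table()] with catalog
#'   columns.
#' @param classification Optional precomputed [classify_corpus()] result.
#' @return A list of class `frequency_table` with `axis`, `counts` (named
#'   integer vector, keys sorted) and `denominator` (number of genomes
#'   considered: the `both`-genome set size when restricted to `both`,
#'   otherwise the corpus genome count).
#' @export
build_frequency_table <- function(corpus, axis = c("gene", "function", "cog"),
                                  catalog, config = ranking_config(),
                                  resolved = NULL, classification = NULL) {
  axis <- match.arg(axis)
  tab <- resolved %||% cassette_gene_table(corpus, catalog)
  cls <- classification %||% classify_corpus(corpus, catalog, resolved = tab)
  restrict <- config$restrict_to_category
  if (!is.na(restrict)) {
    cc <- cls$cassette_categories
    keep_key <- paste(cc$genome_id, cc$cassette_id,
                      sep = "\r")[cc$category == restrict]
    tab <- tab[paste(tab$genome_id, tab$cassette_id, sep = "\r") %in%
                 keep_key, , drop = FALSE]
    denom <- if (identical(restrict, "both")) length(cls$both_genomes)
             else length(unique(cc$genome_id[cc$category == restrict]))
  } else {
    denom <- length(corpus$genomes)
  }
  keys <- switch(axis,
    gene = data.frame(genome_id = tab$genome_id, key = tab$canonical,
                      stringsAsFactors = FALSE),
    `function` = data.frame(genome_id = tab$genome_id,
                            key = ifelse(nzchar(tab$product),
                                         tolower(tab$product), NA),
                            stringsAsFactors = FALSE),
    cog = {
      cogl <- strsplit(tab$cog_ids, ";", fixed = TRUE)
      data.frame(genome_id = rep(tab$genome_id, lengths(cogl)),
                 key = unlist(cogl), stringsAsFactors = FALSE)
    })
  keys <- keys[!is.na(keys$key) & nzchar(keys$key), , drop = FALSE]
  keys <- unique(keys)
  if (nrow(keys)) {
    counts <- table(keys$key)
    counts <- stats::setNames(as.integer(counts), names(counts))
    counts <- counts[order(names(counts))]
  } else {
    counts <- stats::setNames(integer(0), character(0))
  }
  structure(list(axis = axis, counts = counts, denominator = denom),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("<frequency_table> axis=", x$axis, ", ", length(x$counts),
      " keys over ", x$denominator, " genomes\n", sep = "")
  invisible(x)
}

#' Top-ranked keys of a frequency table
#'
#' Keys occurring in strictly more than `min_genomes` genomes, sorted by
#' count descending with lexicographic tie-break, truncated to `top_n`.
#'
#' @param table A `frequency_table`.
#' @param config A [ranking_config()].
#' @return Data.frame `key, count, denominator, axis` (possibly zero rows).
#' @export
top_ranked <- function(table, config = ranking_config()) {
  counts <- table$counts[table$counts > config$min_genomes]
  ord <- order(-counts, names(counts))
  counts <- utils::head(counts[ord], config$top_n)
  data.frame(key = as.character(names(counts)), count = unname(counts),
             denominator = rep(table$denominator, length(counts)),
             axis = rep(table$axis, length(counts)),
             stringsAsFactors = FALSE)
}

#' Consensus genes across the three ranked axes
#'
#' Canonicalizes the three top-key lists (genes via name/synonym, functions
#' via keyword matching, COG ids via the catalog's COG map) and returns the
#' genes present in at least `min_rankings` of the three lists. Synonyms are
#' unified before intersection (e.g. yhbC and rimP count as one gene).
#'
#' @param gene_list,function_list,cog_list Character vectors of top-ranked
#'   keys (or data.frames with a `key` column as from [top_ranked()]).
#' @param catalog A `curated_catalog`.
#' @param min_rankings Minimum number of lists a gene must appear in
#'   (default 2).
#' @return Sorted character vector of canonical genes.
#' @export
consensus_genes <- function(gene_list, function_list, cog_list, catalog,
                            min_rankings = 2L) {
  keys <- function(x) if (is.data.frame(x)) x$key else x
  sets <- lapply(list(keys(gene_list), keys(function_list), keys(cog_list)),
                 function(k) {
                   if (!length(k)) return(character(0))
                   unique(stats::na.omit(canonicalize_keys(k, catalog)))
                 })
  all_genes <- sort(unique(unlist(sets)))
  hits <- vapply(all_genes,
                 function(g) sum(vapply(sets, function(s) g %in% s, TRUE)),
                 0L)
  sort(all_genes[hits >= min_rankings])
}

#' Read a genome taxonomy map
#'
#' TSV columns: `genome_id, genus, phylum, labels` (labels semicolon-joined
#' free-text tags, e.g. "pathogenic", "soil", "archaea").
#'
#' @param source Path to the TSV.
#' @return Data.frame keyed by `genome_id`.
#' @export
read_taxonomy_map <- function(source) {
  df <- utils::read.delim(source, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("genome_id", "genus", "phylum", "labels")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("taxonomy TSV: missing columns: ", paste(miss, collapse = ", "))
  df[need]
}

#' Summarize the taxonomic distribution of a genome set
#'
#' Groups the given genomes by genus, phylum or (primary) label and reports
#' per-group counts and fractions; genomes absent from the taxonomy map fall
#' into the group `"unclassified"`. Fractions sum to 1 over groups.
#'
#' @param genome_ids Character vector of genome ids (e.g. the matched genomes
#'   of one cassette).
#' @param taxonomy_map Data.frame as from [read_taxonomy_map()].
#' @param group_by `"genus"`, `"phylum"` or `"label"` (first listed label).
#' @return Data.frame `group, count, fraction`, sorted by count descending
#'   then group.
#' @export
summarize_taxa <- function(genome_ids, taxonomy_map,
                           group_by = c("genus", "phylum", "label")) {
  group_by <- match.arg(group_by)
  idx <- match(genome_ids, taxonomy_map$genome_id)
  grp <- switch(group_by,
                genus = taxonomy_map$genus[idx],
                phylum = taxonomy_map$phylum[idx],
                label = vapply(strsplit(taxonomy_map$labels[idx], ";",
                                        fixed = TRUE),
                               function(l) if (length(l)) l[[1]] else NA,
                               FUN.VALUE = NA_character_))
  grp[is.na(grp) | !nzchar(grp)] <- "unclassified"
  counts <- table(grp)
  out <- data.frame(group = names(counts), count = as.integer(counts),
                    fraction = as.numeric(counts) / length(genome_ids),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
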