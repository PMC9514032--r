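.class_from_flags <- function(has_tx, has_tl) {
  ifelse(has_tx & has_tl, "both",
         ifelse(has_tx, "transcription_only",
                ifelse(has_tl, "translation_only", "none")))
}

#' Cassette categories
#'
#' The four mutually exclusive, exhaustive cassette categories.
#' @return Character vector of the four category names.
#' @export
cassette_categories <- function() {
  c("both", "transcription_only", "translation_only", "none")
}

#' Extract one cassette from a corpus
#'
#' @param corpus A `cassette_corpus`.
#' @param genome_id,cassette_id Identifiers.
#' @return A list of class `cassette` with `genome_id`, `cassette_id` and
#'   `genes` (gene table rows in rank order).
#' @export
get_cassette <- function(corpus, genome_id, cassette_id) {
  memb <- corpus$cassettes[[genome_id]]
  if (is.null(memb) || !cassette_id %in% memb$cassette_id)
    stop("no cassette ", cassette_id, " in genome ", genome_id)
  memb <- memb[memb$cassette_id == cassette_id, , drop = FALSE]
  memb <- memb[order(memb$rank), , drop = FALSE]
  genes <- corpus$genomes[[genome_id]]$genes
  structure(list(genome_id = genome_id, cassette_id = cassette_id,
                 genes = genes[match(memb$locus_tag, genes$locus_tag), ,
                               drop = FALSE]),
            class = "cassette")
}

#' Classify one cassette into the four-way category
#'
#' A cassette is `both` iff it resolves at least one transcription gene and
#' at least one translation gene; `transcription_only` / `translation_only`
#' if it resolves genes of exactly one category; `none` otherwise.
#'
#' @param cassette A `cassette` (see [get_cassette()]) or a gene table of its
#'   members.
#' @param catalog A `curated_catalog`.
#' @return One of `"both"`, `"transcription_only"`, `"translation_only"`,
#'   `"none"`.
#' @export
classify_cassette <- function(cassette, catalog) {
  genes <- if (inherits(cassette, "cassette")) cassette$genes else cassette
  cats <- resolve_genes(genes, catalog)$category
  .class_from_flags(any(cats == "transcription", na.rm = TRUE),
                    any(cats == "translation", na.rm = TRUE))
}

#' Classify every cassette of a corpus
#'
#' @param corpus A `cassette_corpus`.
#' @param catalog A `curated_catalog`.
#' @param resolved Optional precomputed [cassette_gene_table()] with catalog
#'   columns (avoids re-resolving).
#' @return A list with:
#'   \describe{
#'     \item{cassette_categories}{data.frame `genome_id, cassette_id,
#'       category`.}
#'     \item{tallies}{data.frame, one row per genome, with the four category
#'       counts and their `total`.}
#'     \item{both_genomes}{sorted character vector of genomes possessing at
#'       least one `both` cassette — the denominator for downstream
#'       ranking.}
#'   }
#' @export
classify_corpus <- function(corpus, catalog, resolved = NULL) {
  tab <- resolved %||% cassette_gene_table(corpus, catalog)
  if (nrow(tab)) {
    key <- paste(tab$genome_id, tab$cassette_id, sep = "\r")
    has_tx <- tapply(tab$category == "transcription", key,
                     function(v) any(v, na.rm = TRUE))
    has_tl <- tapply(tab$category == "translation", key,
                     function(v) any(v, na.rm = TRUE))
    ids <- do.call(rbind, strsplit(names(has_tx), "\r", fixed = TRUE))
    cc <- data.frame(genome_id = ids[, 1], cassette_id = ids[, 2],
                     category = .class_from_flags(as.vector(has_tx),
                                                  as.vector(has_tl)),
                     stringsAsFactors = FALSE)
    cc <- cc[order(cc$genome_id, cc$cassette_id), , drop = FALSE]
    rownames(cc) <- NULL
  } else {
    cc <- data.frame(genome_id = character(0), cassette_id = character(0),
                     category = character(0), stringsAsFactors = FALSE)
  }
  gids <- sort(names(corpus$genomes))
  tal <- as.data.frame(matrix(0L, length(gids), 4,
                              dimnames = list(NULL, cassette_categories())))
  tal <- cbind(data.frame(genome_id = gids, stringsAsFactors = FALSE), tal)
  if (nrow(cc)) {
    counts <- table(cc$genome_id, factor(cc$category,
                                         levels = cassette_categories()))
    idx <- match(rownames(counts), tal$genome_id)
    tal[idx, cassette_categories()] <- as.data.frame.matrix(counts)
  }
  tal$total <- rowSums(tal[cassette_categories()])
  list(cassette_categories = cc, tallies = tal,
       both_genomes = sort(unique(cc$genome_id[cc$category == "both"])))
}
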