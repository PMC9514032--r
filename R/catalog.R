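#' Load a curated transcription/translation gene catalog
#'
#' The catalog is the matching authority for gene resolution: each entry maps
#' a canonical gene to its category (`transcription` or `translation`), its
#' synonyms, function keywords (matched as case-insensitive substrings of the
#' product field) and COG ids. TSV columns: `canonical_gene, category,
#' synonyms, function_keywords, cog_ids` (multi-valued fields
#' semicolon-joined). A default catalog seeded from the core transcription-
#' and translation-machinery genes (RNA polymerase subunits, Nus factors,
#' ribosomal proteins, initiation factors, translocase subunits) ships with
#' the package; see [default_catalog()].
#'
#' @param source Path to the catalog TSV.
#' @return A `curated_catalog`: the entry data.frame with attached lookup
#'   tables.
#' @export
load_catalog <- function(source) {
  df <- utils::read.delim(source, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("canonical_gene", "category", "synonyms", "function_keywords",
            "cog_ids")
  if (nrow(df) == 0)
    df <- stats::setNames(data.frame(matrix(character(0), 0, 5),
                                     stringsAsFactors = FALSE), need)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("catalog TSV: missing columns: ", paste(miss, collapse = ", "))
  new_catalog(df[need])
}

#' Construct a catalog from an entry data.frame
#'
#' @param entries Data.frame with columns `canonical_gene, category, synonyms,
#'   function_keywords, cog_ids` (multi-valued fields semicolon-joined).
#' @return A `curated_catalog`.
#' @export
new_catalog <- function(entries) {
  if (nrow(entries)) {
    bad <- which(!entries$category %in% c("transcription", "translation"))
    if (length(bad))
      stop("catalog: unknown category for entry ",
           paste(entries$canonical_gene[bad], collapse = ", "),
           " (need transcription or translation)")
    if (any(!nzchar(entries$canonical_gene)))
      stop("catalog: empty canonical_gene")
  }
  # Name/synonym ownership must be unambiguous across entries.
  owners <- do.call(rbind, lapply(seq_len(nrow(entries)), function(i) {
    nm <- c(entries$canonical_gene[i], .split_multi(entries$synonyms[i]))
    data.frame(name = tolower(nm), canonical = entries$canonical_gene[i],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(owners)) {
    owners <- unique(owners)
    dup <- owners$name[duplicated(owners$name)]
    if (length(dup)) {
      claims <- owners[owners$name %in% dup, ]
      stop("catalog: name(s) claimed by multiple entries: ",
           paste(sprintf("%s (%s)", claims$name, claims$canonical),
                 collapse = "; "))
    }
  } else {
    owners <- data.frame(name = character(0), canonical = character(0),
                         stringsAsFactors = FALSE)
  }
  canon_lut <- stats::setNames(entries$canonical_gene,
                               tolower(entries$canonical_gene))
  syn <- owners[!owners$name %in% tolower(entries$canonical_gene), ]
  cogs <- do.call(rbind, lapply(seq_len(nrow(entries)), function(i) {
    cg <- .split_multi(entries$cog_ids[i])
    if (!length(cg)) return(NULL)
    data.frame(cog = cg, canonical = entries$canonical_gene[i],
               stringsAsFactors = FALSE)
  }))
  kws <- do.call(rbind, lapply(seq_len(nrow(entries)), function(i) {
    kw <- .split_multi(entries$function_keywords[i])
    if (!length(kw)) return(NULL)
    data.frame(keyword = tolower(kw), canonical = entries$canonical_gene[i],
               stringsAsFactors = FALSE)
  }))
  structure(list(
    entries = entries,
    category = stats::setNames(entries$category, entries$canonical_gene),
    name_lut = canon_lut,
    syn_lut = stats::setNames(syn$canonical, syn$name),
    cog_tab = cogs %||% data.frame(cog = character(0),
                                   canonical = character(0)),
    kw_tab = kws %||% data.frame(keyword = character(0),
                                 canonical = character(0))),
    class = "curated_catalog")
}

#' @export
print.curated_catalog <- function(x, ...) {
  cat("<curated_catalog> ", nrow(x$entries), " entries (",
      sum(x$entries$category == "transcription"), " transcription, ",
      sum(x$entries$category == "translation"), " translation)\n", sep = "")
  invisible(x)
}

#' The bundled default catalog
#'
#' Loads the catalog shipped under `extdata/tt_catalog.tsv`: the core
#' transcription machinery (RNA polymerase subunits rpoA/rpoB, elongation and
#' termination factors nusA/nusG, the transcription-repair coupling factor
#' mfd, the regulatory RNA-binding protein ylxR) and translation machinery
#' (ribosomal proteins, initiation factors infA/infB, rRNA/tRNA maturation
#' factors rimP/rbfA/truB, translocase subunits secE/secY). Dual-role
#' coupling factors (nusA, nusG) are filed under transcription; the `both`
#' cassette category emerges from the mixture within a cassette, not from a
#' per-gene dual label.
#'
#' @return A `curated_catalog`.
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "tt_catalog.tsv",
                           package = "ttcassettes", mustWork = TRUE))
}

#' Resolve gene records against a catalog
#'
#' Vectorized synonym-aware resolution. Matching is case-insensitive with
#' tiered precedence: exact canonical gene name, then synonym (of the record's
#' name or any of its listed synonyms), then COG id, then function-keyword
#' substring of the product. The first matching tier wins; within a tier a hit
#' on two different catalog entries is ambiguous and resolves to no-match
#' (with a warning).
#'
#' @param records Gene table (data.frame with `gene_name, synonyms, cog_ids,
#'   product`).
#' @param catalog A `curated_catalog`.
#' @return Data.frame with columns `canonical` and `category`
#'   (`NA` for no-match), one row per record.
#' @export
resolve_genes <- function(records, catalog) {
  n <- nrow(records)
  canonical <- rep(NA_character_, n)
  if (n == 0 || nrow(catalog$entries) == 0)
    return(data.frame(canonical = canonical,
                      category = rep(NA_character_, n),
                      stringsAsFactors = FALSE))
  nm <- tolower(ifelse(is.na(records$gene_name), "", records$gene_name))
  # tier 1: canonical name
  hit <- catalog$name_lut[nm]
  canonical[!is.na(hit)] <- hit[!is.na(hit)]
  # tier 2: synonym (record name or record synonyms vs catalog names/synonyms)
  todo <- which(is.na(canonical))
  if (length(todo)) {
    hit2 <- catalog$syn_lut[nm[todo]]
    canonical[todo[!is.na(hit2)]] <- hit2[!is.na(hit2)]
    todo <- which(is.na(canonical))
    for (i in todo) {
      rsyn <- tolower(.split_multi(records$synonyms[i]))
      if (!length(rsyn)) next
      hits <- unique(stats::na.omit(c(catalog$name_lut[rsyn],
                                      catalog$syn_lut[rsyn])))
      if (length(hits) == 1) canonical[i] <- hits
      else if (length(hits) > 1)
        warning("ambiguous synonym match for locus ", records$locus_tag[i],
                ": ", paste(hits, collapse = ", "), " -> no-match")
    }
  }
  # tier 3: COG id
  todo <- which(is.na(canonical))
  for (i in todo) {
    rc <- .split_multi(records$cog_ids[i])
    if (!length(rc)) next
    hits <- unique(catalog$cog_tab$canonical[catalog$cog_tab$cog %in% rc])
    if (length(hits) == 1) canonical[i] <- hits
    else if (length(hits) > 1)
      warning("ambiguous COG match for locus ", records$locus_tag[i],
              ": ", paste(hits, collapse = ", "), " -> no-match")
  }
  # tier 4: function keyword as substring of the product (word-bounded, so
  # "ribosomal protein l1" does not also hit "ribosomal protein l17")
  todo <- which(is.na(canonical))
  if (length(todo) && nrow(catalog$kw_tab)) {
    kw_re <- paste0("\\b",
                    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                         catalog$kw_tab$keyword),
                    "\\b")
    prods <- tolower(records$product[todo])
    for (j in seq_along(todo)) {
      if (!nzchar(prods[j])) next
      hitrows <- vapply(kw_re, grepl, TRUE, x = prods[j])
      hits <- unique(catalog$kw_tab$canonical[hitrows])
      if (length(hits) == 1) canonical[todo[j]] <- hits
      else if (length(hits) > 1)
        warning("ambiguous keyword match for locus ",
                records$locus_tag[todo[j]], ": ",
                paste(hits, collapse = ", "), " -> no-match")
    }
  }
  data.frame(canonical = canonical,
             category = unname(catalog$category[canonical]),
             stringsAsFactors = FALSE)
}

#' Resolve a single gene record
#'
#' @param record A one-row gene table (see [gene_record()]).
#' @param catalog A `curated_catalog`.
#' @return A list `(canonical_gene, category)`, or `NULL` for no-match.
#' @export
resolve_gene <- function(record, catalog) {
  res <- resolve_genes(record, catalog)
  if (is.na(res$canonical[1])) return(NULL)
  list(canonical_gene = res$canonical[1], category = res$category[1])
}

#' Resolve bare gene identifiers (names, synonyms, COG ids or products)
#'
#' Helper used to canonicalize ranked keys: each string is tried as a gene
#' name/synonym, then as a COG id, then as a product string against function
#' keywords.
#'
#' @param keys Character vector.
#' @param catalog A `curated_catalog`.
#' @return Character vector of canonical genes (`NA` where unresolvable).
#' @export
canonicalize_keys <- function(keys, catalog) {
  fake <- data.frame(locus_tag = keys, gene_name = keys, synonyms = "",
                     product = keys, cog_ids = keys, stringsAsFactors = FALSE)
  resolve_genes(fake, catalog)$canonical
}
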