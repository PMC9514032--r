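# Columns of the annotation TSV dialect, in file order.
.annot_cols <- c("genome_id", "locus_tag", "gene_name", "synonyms", "product",
                 "cog_ids", "start", "end", "strand")

.split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

.join_multi <- function(x) paste(x, collapse = ";")

#' Construct a single gene record
#'
#' A gene record is one row of a gene table: one annotated gene of one genome,
#' with 1-based inclusive nucleotide coordinates. Multi-valued fields
#' (synonyms, COG ids) are semicolon-joined strings.
#'
#' @param genome_id,locus_tag Character scalars; `locus_tag` must be unique
#'   within a genome.
#' @param gene_name Gene symbol, or `NA`/`""` when the annotation lacks one.
#' @param synonyms,cog_ids Semicolon-joined strings (possibly empty).
#' @param product Free-text product description.
#' @param start,end Integer coordinates, 1-based inclusive, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return A one-row `data.frame` with an added `length` column
#'   (`end - start + 1`).
#' @export
#' @examples
#' gene_record("G1", "t0001", "rpoA",
#'             product = "DNA-directed RNA polymerase subunit alpha",
#'             cog_ids = "COG0202K", start = 100, end = 1086, strand = "+")
gene_record <- function(genome_id, locus_tag, gene_name = NA_character_,
                        synonyms = "", product = "", cog_ids = "",
                        start, end, strand) {
  df <- data.frame(genome_id = as.character(genome_id),
                   locus_tag = as.character(locus_tag),
                   gene_name = as.character(gene_name),
                   synonyms = as.character(synonyms),
                   product = as.character(product),
                   cog_ids = as.character(cog_ids),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_gene_table(df)
  df$length <- df$end - df$start + 1L
  df
}

#' Validate a gene table
#'
#' Checks the per-record invariants: integer coordinates with
#' `1 <= start <= end`, strand in `{+, -}`, and locus tags unique within each
#' genome. Errors name the offending row.
#'
#' @param genes A data.frame with the annotation columns.
#' @param context Optional string naming the source (used in error messages).
#' @return `genes`, invisibly, with a `length` column added if absent.
#' @export
validate_gene_table <- function(genes, context = "gene table") {
  need <- .annot_cols
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop(context, ": missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(genes$start) || anyNA(genes$end))
    stop(context, ": non-integer coordinates at row(s) ",
         paste(which(is.na(genes$start) | is.na(genes$end)), collapse = ", "))
  bad <- which(genes$start < 1L | genes$start > genes$end)
  if (length(bad))
    stop(context, ": malformed coordinates (need 1 <= start <= end) at row(s) ",
         paste(bad, collapse = ", "), " (locus ",
         paste(genes$locus_tag[bad], collapse = ", "), ")")
  badstr <- which(!genes$strand %in% c("+", "-"))
  if (length(badstr))
    stop(context, ": unknown strand symbol at row(s) ",
         paste(badstr, collapse = ", "))
  dup <- genes$locus_tag[duplicated(paste(genes$genome_id, genes$locus_tag))]
  if (length(dup))
    stop(context, ": duplicate locus_tag within a genome: ",
         paste(unique(dup), collapse = ", "))
  if (is.null(genes$length)) genes$length <- genes$end - genes$start + 1L
  invisible(genes)
}

#' Construct a genome annotation
#'
#' Bundles a genome's gene table with optional taxonomy labels and an optional
#' nucleotide sequence (a single concatenated replicon). Genes are sorted by
#' ascending start coordinate.
#'
#' @param genome_id Genome identifier.
#' @param genes Gene table (see [gene_record()]); all rows must carry this
#'   `genome_id`.
#' @param taxon List with elements `genus`, `phylum`, `labels` (character
#'   vector of free-text tags).
#' @param sequence Optional nucleotide string; every gene must end within it.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, genes,
                              taxon = list(genus = NA_character_,
                                           phylum = NA_character_,
                                           labels = character(0)),
                              sequence = NULL) {
  if (nrow(genes)) {
    genes <- validate_gene_table(genes, context = paste0("genome ", genome_id))
    if (!all(genes$genome_id == genome_id))
      stop("genome ", genome_id, ": gene table contains foreign genome_id")
    genes <- genes[order(genes$start, genes$locus_tag), , drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes$length <- integer(0)
  }
  if (!is.null(sequence)) {
    if (nrow(genes) && max(genes$end) > nchar(sequence))
      stop("genome ", genome_id, ": gene coordinates exceed sequence length")
  }
  structure(list(genome_id = genome_id, taxon = taxon, genes = genes,
                 sequence = sequence),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$genome_id, ": ", nrow(x$genes), " genes",
      if (!is.null(x$sequence)) paste0(", ", nchar(x$sequence), " nt sequence"),
      "\n", sep = "")
  invisible(x)
}

.empty_gene_table <- function() {
  df <- data.frame(genome_id = character(0), locus_tag = character(0),
                   gene_name = character(0), synonyms = character(0),
                   product = character(0), cog_ids = character(0),
                   start = integer(0), end = integer(0),
                   strand = character(0), length = integer(0),
                   stringsAsFactors = FALSE)
  df
}

#' Read per-genome annotations
#'
#' Reads an annotation source in either the package's TSV dialect or GFF3 and
#' returns one [genome_annotation()] per genome found.
#'
#' The TSV dialect is UTF-8, tab-separated, `#`-comment lines ignored, with a
#' header row and columns `genome_id, locus_tag, gene_name, synonyms, product,
#' cog_ids, start, end, strand`; `synonyms` and `cog_ids` are semicolon-joined;
#' coordinates are 1-based inclusive. GFF3 features of type `gene` (or `CDS`
#' where no `gene` features exist) are used; the gene name is taken from the
#' `gene` attribute, synonyms from `gene_synonym`, COG ids from `Dbxref`
#' entries prefixed `COG:`, and the seqid is used as the genome id (replicons
#' sharing a seqid are concatenated under that id).
#'
#' @param source Path to the file.
#' @param format `"tsv"` or `"gff3"`.
#' @return Named list of `genome_annotation` objects (name = genome id).
#' @export
read_annotations <- function(source, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(source, header = TRUE, sep = "\t", quote = "",
                            comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = "character")
    if (nrow(df) == 0)
      return(stats::setNames(list(), character(0)))
    miss <- setdiff(.annot_cols, names(df))
    if (length(miss))
      stop("annotation TSV: missing columns: ", paste(miss, collapse = ", "))
    start <- suppressWarnings(as.integer(df$start))
    end <- suppressWarnings(as.integer(df$end))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
      stop("annotation TSV: non-integer coordinates at data line(s) ",
           paste(bad, collapse = ", "))
    df$start <- start; df$end <- end
    df$gene_name[df$gene_name == ""] <- NA_character_
  } else {
    df <- .read_gff3_genes(source)
    if (nrow(df) == 0)
      return(stats::setNames(list(), character(0)))
  }
  validate_gene_table(df, context = basename(as.character(source)))
  out <- lapply(split(df, df$genome_id), function(g) {
    genome_annotation(g$genome_id[1], g)
  })
  out[order(names(out))]
}

#' Read a single-genome annotation file
#'
#' Convenience wrapper around [read_annotations()] for sources holding one
#' genome (or one selected genome of a multi-genome file).
#'
#' @inheritParams read_annotations
#' @param genome_id Which genome to return when the file holds several;
#'   required in that case.
#' @return A `genome_annotation`. An empty source yields an annotation with
#'   zero genes (id `""` unless `genome_id` is given).
#' @export
read_annotation <- function(source, format = c("tsv", "gff3"),
                            genome_id = NULL) {
  anns <- read_annotations(source, format)
  if (length(anns) == 0)
    return(genome_annotation(genome_id %||% "", .empty_gene_table()))
  if (is.null(genome_id)) {
    if (length(anns) > 1)
      stop("source holds ", length(anns),
           " genomes; pass genome_id to select one")
    return(anns[[1]])
  }
  if (!genome_id %in% names(anns))
    stop("genome ", genome_id, " not present in source")
  anns[[genome_id]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_gff3_genes <- function(source) {
  gr <- rtracklayer::import(source, format = "gff3")
  md <- S4Vectors::mcols(gr)
  types <- as.character(md$type)
  keep <- types == "gene"
  if (!any(keep)) keep <- types == "CDS"
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  n <- length(gr)
  if (n == 0) return(.empty_gene_table())
  get_chr <- function(col) {
    if (!col %in% names(md)) return(rep("", n))
    v <- md[[col]]
    if (methods::is(v, "List") || is.list(v))
      vapply(as.list(v), function(e) .join_multi(as.character(e)), "")
    else {
      v <- as.character(v)
      v[is.na(v)] <- ""
      v
    }
  }
  lt <- get_chr("locus_tag")
  if (any(!nzchar(lt))) lt[!nzchar(lt)] <- get_chr("ID")[!nzchar(lt)]
  dbx <- md[["Dbxref"]]
  cogs <- if (is.null(dbx)) rep("", n) else vapply(as.list(dbx), function(e) {
    e <- as.character(e)
    .join_multi(sub("^COG:", "", e[startsWith(e, "COG:")]))
  }, "")
  strand <- as.character(BiocGenerics::strand(gr))
  df <- data.frame(genome_id = as.character(GenomicRanges::seqnames(gr)),
                   locus_tag = lt,
                   gene_name = ifelse(nzchar(get_chr("gene")),
                                      get_chr("gene"), NA_character_),
                   synonyms = get_chr("gene_synonym"),
                   product = get_chr("product"),
                   cog_ids = cogs,
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   strand = strand,
                   stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-")))
    stop("GFF3: unknown strand symbol (need + or -): ",
         paste(unique(df$strand[!df$strand %in% c("+", "-")]), collapse = ", "))
  df
}

#' Write annotations to the TSV dialect
#'
#' Output is byte-stable: fixed column order, no quoting, a single header
#' comment stating the coordinate convention.
#'
#' @param annotations A `genome_annotation` or (named) list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotations, path) {
  if (inherits(annotations, "genome_annotation"))
    annotations <- list(annotations)
  tabs <- lapply(annotations, function(a) a$genes[, .annot_cols, drop = FALSE])
  df <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  if (is.null(df)) df <- .empty_gene_table()[, .annot_cols]
  df$gene_name[is.na(df$gene_name)] <- ""
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("# annotation table; coordinates 1-based inclusive",
               paste(.annot_cols, collapse = "\t")), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read an operon (cassette) table
#'
#' TSV columns: `genome_id, cassette_id, locus_tag, rank`. Within each
#' cassette the ranks must be contiguous `1..k`; cassette members are
#' assembled in rank order.
#'
#' @param source Path to the TSV.
#' @return Named list (by genome id) of data.frames with columns
#'   `cassette_id, locus_tag, rank` sorted by cassette then rank.
#' @export
read_operon_table <- function(source) {
  df <- utils::read.delim(source, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0) return(stats::setNames(list(), character(0)))
  need <- c("genome_id", "cassette_id", "locus_tag", "rank")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("operon TSV: missing columns: ", paste(miss, collapse = ", "))
  df$rank <- suppressWarnings(as.integer(df$rank))
  if (anyNA(df$rank)) stop("operon TSV: non-integer rank")
  key <- paste(df$genome_id, df$cassette_id, sep = "\r")
  for (k in unique(key)) {
    r <- sort(df$rank[key == k])
    if (!identical(r, seq_along(r)))
      stop("operon TSV: non-contiguous ranks for cassette ",
           sub("\r", "/", k, fixed = TRUE), " (got ",
           paste(r, collapse = ","), ")")
  }
  df <- df[order(df$genome_id, df$cassette_id, df$rank), , drop = FALSE]
  out <- lapply(split(df[c("cassette_id", "locus_tag", "rank")], df$genome_id),
                function(g) { rownames(g) <- NULL; g })
  out[order(names(out))]
}

#' Write an operon table
#'
#' @param operons Named list (by genome id) of data.frames with columns
#'   `cassette_id, locus_tag, rank`, as returned by [read_operon_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_operon_table <- function(operons, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("# operon table: one row per cassette member, rank 1..k",
               "genome_id\tcassette_id\tlocus_tag\trank"), con)
  for (gid in names(operons)) {
    g <- operons[[gid]]
    if (!nrow(g)) next
    g <- g[order(g$cassette_id, g$rank), , drop = FALSE]
    utils::write.table(data.frame(genome_id = gid, g, stringsAsFactors = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, eol = "\n")
  }
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file; record names are genome ids.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write genome sequences to FASTA
#'
#' @param sequences Named character vector (names are genome ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path,
                              width = 70L)
  invisible(path)
}

#' Assemble a corpus from annotations and operon tables
#'
#' Joins per-genome annotations with per-genome cassette membership and
#' validates that every cassette locus tag resolves to an annotated gene.
#' Genomes without any cassette are retained and flagged, so that corpus-level
#' denominators remain explicit.
#'
#' @param annotations Named list of [genome_annotation()] objects.
#' @param operon_tables Named list (by genome id) of cassette membership
#'   data.frames, as from [read_operon_table()].
#' @return An object of class `cassette_corpus` with elements `genomes`,
#'   `cassettes` (per-genome membership tables) and `flags` (data.frame with
#'   `genome_id`, `has_cassettes`).
#' @export
assemble_corpus <- function(annotations, operon_tables) {
  if (is.null(names(annotations)) || any(!nzchar(names(annotations))))
    names(annotations) <- vapply(annotations, function(a) a$genome_id, "")
  unknown <- setdiff(names(operon_tables), names(annotations))
  if (length(unknown))
    stop("operon tables reference unknown genome(s): ",
         paste(unknown, collapse = ", "))
  n_in <- sum(vapply(operon_tables,
                     function(g) length(unique(g$cassette_id)), 0L))
  for (gid in names(operon_tables)) {
    tags <- annotations[[gid]]$genes$locus_tag
    dangling <- setdiff(operon_tables[[gid]]$locus_tag, tags)
    if (length(dangling))
      stop("genome ", gid, ": cassette locus_tag(s) not in annotation: ",
           paste(dangling, collapse = ", "))
  }
  cassettes <- operon_tables[intersect(names(annotations),
                                       names(operon_tables))]
  flags <- data.frame(genome_id = names(annotations),
                      has_cassettes = names(annotations) %in%
                        names(cassettes)[vapply(cassettes, nrow, 0L) > 0],
                      stringsAsFactors = FALSE)
  corpus <- structure(list(genomes = annotations, cassettes = cassettes,
                           flags = flags),
                      class = "cassette_corpus")
  n_out <- n_cassettes(corpus)
  stopifnot(n_in == n_out)  # no cassette may be silently dropped
  corpus
}

#' Number of cassettes in a corpus
#' @param corpus A `cassette_corpus`.
#' @return Integer count over all genomes.
#' @export
n_cassettes <- function(corpus) {
  sum(vapply(corpus$cassettes, function(g) length(unique(g$cassette_id)), 0L))
}

#' @export
print.cassette_corpus <- function(x, ...) {
  cat("<cassette_corpus> ", length(x$genomes), " genomes, ",
      n_cassettes(x), " cassettes (",
      sum(!x$flags$has_cassettes), " genome(s) without cassettes)\n", sep = "")
  invisible(x)
}

#' Flat cassette-gene table for a corpus
#'
#' One row per cassette member across the corpus, joining operon membership
#' with the gene annotation, ordered by genome, cassette and rank. When a
#' catalog is supplied, each row additionally carries the resolved
#' `canonical` gene and its `category` (see [resolve_genes()]).
#'
#' @param corpus A `cassette_corpus`.
#' @param catalog Optional `curated_catalog`.
#' @return A data.frame with columns `genome_id, cassette_id, rank, locus_tag,
#'   gene_name, synonyms, product, cog_ids, start, end, strand, length` and,
#'   with a catalog, `canonical, category`.
#' @export
cassette_gene_table <- function(corpus, catalog = NULL) {
  parts <- lapply(names(corpus$cassettes), function(gid) {
    memb <- corpus$cassettes[[gid]]
    if (!nrow(memb)) return(NULL)
    genes <- corpus$genomes[[gid]]$genes
    idx <- match(memb$locus_tag, genes$locus_tag)
    cbind(data.frame(genome_id = gid, cassette_id = memb$cassette_id,
                     rank = memb$rank, stringsAsFactors = FALSE),
          genes[idx, setdiff(names(genes), c("genome_id")), drop = FALSE])
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) {
    tab <- cbind(data.frame(genome_id = character(0),
                            cassette_id = character(0), rank = integer(0),
                            stringsAsFactors = FALSE),
                 .empty_gene_table()[, -1])
  } else {
    tab <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  }
  if (!is.null(catalog)) {
    res <- resolve_genes(tab, catalog)
    tab$canonical <- res$canonical
    tab$category <- res$category
  }
  tab
}
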