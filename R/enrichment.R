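#' Hypergeometric upper-tail probability
#'
#' Probability of drawing at least `k` annotated genes when sampling `n`
#' genes from a universe of `N` genes of which `K` are annotated:
#' `p = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`, evaluated in
#' log-space for numerical stability.
#'
#' @param k Observed overlap (query genes annotated to the term).
#' @param K Universe genes annotated to the term.
#' @param n Query size.
#' @param N Universe size.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(n, K) || n > N || K > N)
    stop("hypergeom_upper_tail: need 0 <= k <= min(n, K), n <= N, K <= N")
  if (k == 0) return(1)
  i <- k:min(n, K)
  logs <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(logs)
  min(1, exp(mx) * sum(exp(logs - mx)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} (p_(j) * m / j)` capped at 1, returned in the input
#' order.
#'
#' @param pvalues Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("bh_adjust: p-values must lie in (0, 1]")
  m <- length(pvalues)
  ord <- order(pvalues)
  p <- pvalues[ord]
  q <- pmin(1, rev(cummin(rev(p * m / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Read a term-to-gene map
#'
#' TSV columns: `term_id, term_name, gene` (one row per term-gene pair).
#'
#' @param source Path to the TSV.
#' @return Data.frame with those three columns.
#' @export
read_term_map <- function(source) {
  df <- utils::read.delim(source, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("term_id", "term_name", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("term map TSV: missing columns: ", paste(miss, collapse = ", "))
  df[need]
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term of a term-to-gene map for over-representation in a query
#' gene set against a background universe, with Benjamini-Hochberg FDR
#' control. Only terms overlapping the query (`k >= 1`) are reported.
#'
#' @param query_genes Character vector (subset of `universe`).
#' @param term_map Data.frame `term_id, term_name, gene` (genes in
#'   `universe`; rows outside it are dropped).
#' @param universe Character vector: the background gene set.
#' @param alpha Significance level on the adjusted p-value (inclusive;
#'   default 0.05).
#' @return Data.frame `term_id, term_name, k, n, K, N, gene_ratio, p, p_adj,
#'   significant`, sorted by `p` ascending then `term_id`.
#' @export
run_ora <- function(query_genes, term_map, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("run_ora: empty universe")
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe))
    stop("run_ora: query genes outside the universe: ",
         paste(setdiff(query_genes, universe), collapse = ", "))
  term_map <- unique(term_map[term_map$gene %in% universe, , drop = FALSE])
  n <- length(query_genes)
  N <- length(universe)
  terms <- unique(term_map[c("term_id", "term_name")])
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    tg <- unique(term_map$gene[term_map$term_id == terms$term_id[i]])
    k <- length(intersect(query_genes, tg))
    if (k < 1) return(NULL)
    K <- length(tg)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               k = k, n = n, K = K, N = N, gene_ratio = k / n,
               p = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), gene_ratio = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj <= alpha
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
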