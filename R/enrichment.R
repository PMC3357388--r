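# Overrepresentation analysis of change-class gene lists: one-sided
# hypergeometric tail per set, BH across sets.

#' Upper hypergeometric tail probability
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K`
#' are annotated: `p = sum_{j >= k} C(K,j) C(N-K, n-j) / C(N,n)`.
#'
#' @param k Observed overlap.
#' @param K Genes in the set (within the universe).
#' @param n Size of the query list.
#' @param N Universe size.
#' @return The tail probability (1 when `k = 0`).
#' @export
#' @examples
#' hypergeometric_tail(4, 5, 6, 20)  # 540/38760
hypergeometric_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N || k > min(K, n)) {
    stop(sprintf("inconsistent counts: k=%d K=%d n=%d N=%d", k, K, n, N),
         call. = FALSE)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set overrepresentation of a gene list
#'
#' Tests every set of the collection for overrepresentation in `gene_list`
#' relative to `universe` by the one-sided hypergeometric tail. Sets are
#' intersected with the universe first; sets with no universe member are
#' dropped. q-values are BH-adjusted across the tested sets. The odds
#' ratio is taken from the 2x2 overlap table, with a Haldane correction
#' (+0.5 per cell) when any cell is zero.
#'
#' @param gene_list Character vector of query genes (must be a subset of
#'   `universe`).
#' @param universe Character vector, the gene background (all genes on the
#'   matrix).
#' @param collection Gene-set collection from [read_gmt()] or
#'   [generate_gene_sets()].
#' @param alpha Significance level used for the `significant` flag.
#' @return `data.frame`: set_name, overlap_k, set_size_K, list_size_n,
#'   universe_N, odds_ratio, p_value, q_value, significant.
#' @export
enrich_gene_list <- function(gene_list, universe, collection, alpha = 0.05) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (!all(gene_list %in% universe)) {
    stop("gene_list contains genes absent from the universe: ",
         paste(utils::head(setdiff(gene_list, universe), 5), collapse = ", "),
         call. = FALSE)
  }
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, gene_list))
    p <- hypergeometric_tail(k, K, n, N)
    a <- k; b <- n - k; c <- K - k; d <- N - K - n + k
    if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
    data.frame(set_name = nm, overlap_k = k, set_size_K = K,
               list_size_n = n, universe_N = N,
               odds_ratio = (a * d) / (b * c), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set_name = character(0), overlap_k = integer(0),
                      set_size_K = integer(0), list_size_n = integer(0),
                      universe_N = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      significant = logical(0))
    return(out)
  }
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < alpha
  rownames(out) <- NULL
  out
}
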