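## Over-representation analysis of a gene list against GMT collections
## (functional categories or TF -> target sets): upper-tail
## hypergeometric p-values with Benjamini-Hochberg correction. The
## universe defaults to the study platform, not the genome; sets with no
## overlap are omitted from the output and from the BH family.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X` hypergeometric with `K` successes in a universe
#' of `N` and a draw of `n`; evaluated in log space via `phyper` for
#' numerical stability.
#'
#' @param k overlap count.
#' @param K set size in the universe.
#' @param n list size.
#' @param N universe size.
#' @return probability in `[0, 1]`.
#' @export
hypergeometric_upper <- function(k, K, n, N) {
  if (any(K > N | n > N | K < 0 | n < 0 | N < 0))
    stop_stats("inconsistent counts: need 0 <= K, n <= N")
  if (any(k < 0 | k > pmin(K, n)))
    stop_stats("inconsistent counts: need 0 <= k <= min(K, n)")
  ifelse(k == 0, 1,
         exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `p_adj_(i) = min_\{j >= i\} m p_(j) / j`, capped at
#' 1, returned in the original order.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop_stats("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Over-representation of a gene list against a set collection
#'
#' Sets are intersected with the universe; one row is emitted per set
#' overlapping the list (`k >= 1`), with the upper-tail hypergeometric p
#' (`max(k - 1, 0)` instead of `k` under the EASE variant), BH
#' adjustment over the emitted rows, and a significance flag at
#' `p_adj <= 0.05`.
#'
#' @param gene_list character gene labels (subset of `universe`).
#' @param collection a `GeneSetCollection` from [read_gmt()], or a named
#'   list of gene vectors.
#' @param universe character vector of all assayable genes.
#' @param ease logical; use DAVID's conservative EASE variant.
#' @param alpha significance level on the adjusted p.
#' @return data frame (term, description, k, K, n, N, p, p_adj,
#'   significant) sorted by ascending `p_adj`.
#' @export
enrich_collection <- function(gene_list, collection, universe, ease = FALSE,
                              alpha = 0.05) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!length(universe) || !length(gene_list))
    stop_stats("empty universe or gene list")
  outside <- setdiff(gene_list, universe)
  if (length(outside))
    stop_stats("gene list not contained in universe: %s",
               paste(head(outside, 5), collapse = ", "))
  N <- length(universe); n <- length(gene_list)
  rows <- lapply(names(collection), function(nm) {
    el <- collection[[nm]]
    genes <- if (is.list(el)) el$genes else el
    desc <- if (is.list(el)) el$description else ""
    set <- intersect(genes, universe)
    k <- length(intersect(set, gene_list))
    if (k < 1) return(NULL)
    keff <- if (ease) max(k - 1, 0) else k
    data.frame(term = nm, description = desc, k = k, K = length(set),
               n = n, N = N,
               p = hypergeometric_upper(keff, length(set), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj <= alpha
  out <- out[order(out$p_adj, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
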