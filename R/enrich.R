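#' Hypergeometric over-representation analysis of a DAP set
#'
#' For each term annotating at least `min_daps` members of the DAP set,
#' computes the upper-tail hypergeometric probability of drawing at least
#' that many annotated proteins when `n` proteins are sampled without
#' replacement from a universe of `N` proteins of which `K` carry the
#' term: p = P\[X >= k\], X ~ Hypergeometric(N, K, n). p-values are
#' Benjamini-Hochberg adjusted across the reported terms and sorted
#' ascending.
#'
#' The universe defaults in practice to the identified-protein set (not
#' the whole genome), reflecting proteomic detection bias; pass it
#' explicitly.
#'
#' @param dap_set character vector of protein/gene IDs (must be a subset
#'   of `universe`).
#' @param term_map data.frame with columns `term_id`, `gene_id` and
#'   optionally `term_name` (see [read_term_map()]). Annotations outside
#'   the universe are dropped.
#' @param universe character vector of all IDs eligible for the draw.
#' @param min_daps minimum DAP-set members a term needs to be reported
#'   (default 3).
#' @return data.frame with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p_value`, `q_value`, sorted by `p_value`.
#' @examples
#' tm <- data.frame(term_id = "T1", gene_id = paste0("P", 1:5))
#' hypergeom_enrich(paste0("P", 1:5), tm, paste0("P", 1:10), min_daps = 3)
#' @export
hypergeom_enrich <- function(dap_set, term_map, universe, min_daps = 3) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  dap_set <- unique(as.character(dap_set))
  bad <- setdiff(dap_set, universe)
  if (length(bad))
    stop("DAP set members outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  tm <- tm[!duplicated(tm[, c("term_id", "gene_id")]), , drop = FALSE]
  if (is.null(tm$term_name)) tm$term_name <- tm$term_id
  N <- length(universe)
  n <- length(dap_set)
  terms <- unique(tm$term_id)
  rows <- lapply(terms, function(t) {
    g <- tm$gene_id[tm$term_id == t]
    K <- length(g)
    if (K == 0) return(NULL)
    k <- sum(g %in% dap_set)
    if (k < min_daps) return(NULL)
    data.frame(term_id = t,
               term_name = tm$term_name[match(t, tm$term_id)],
               k = k, K = K, n = n, N = N,
               p_value = stats::phyper(k - 1, K, N - K, n,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
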