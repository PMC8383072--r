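#' Window rules for candidate cluster detection
#'
#' A window of `window_len` consecutive genes (within one contig)
#' qualifies as part of a candidate cluster if it contains at least
#' `min_dap` DAP genes. The default rule pair is 3 DAPs in 10 consecutive
#' genes, or 5 in 15.
#'
#' @param rules list of `c(window_len, min_dap)` pairs.
#' @return validated list of integer pairs.
#' @export
window_rules <- function(rules = list(c(10L, 3L), c(15L, 5L))) {
  lapply(rules, function(r) {
    r <- as.integer(r)
    if (length(r) != 2 || r[1] < 1 || r[2] < 1 || r[2] > r[1])
      stop("a window rule is c(window_len, min_dap) with 1 <= min_dap <= window_len")
    r
  })
}

#' Flag DAP genes along the genome
#'
#' Joins ordered gene models to DAP calls through the protein link and
#' returns, per gene, whether its protein is in the screened DAP set and
#' the fold change used for AFCL scoring. For `direction = "up"` the
#' screened set is up + unique_case and the score is the fold change as
#' called (imputed value for unique proteins); for `"down"` it is down +
#' unique_control scored by the reciprocal fold change (induction
#' magnitude in the screened direction); for `"both"` all four classes,
#' scored by `max(fc, 1/fc)`.
#'
#' Genes without a linked quantified protein are never flagged; their
#' count is recorded in the `n_unlinked` attribute.
#'
#' @param genes ordered gene models (see [order_genes()]).
#' @param daps a `dap_calls` object.
#' @param direction `"up"` (default), `"down"` or `"both"`.
#' @return `genes` with added columns `dap` (logical) and `fc` (numeric,
#'   NA when the gene has no DAP protein).
#' @export
flag_dap_genes <- function(genes, daps, direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  if (is.null(genes$ordinal))
    stop("genes must be ordered first (order_genes)")
  records <- daps$records
  idx <- match(genes$protein_id, records$protein_id)
  status <- as.character(records$status[idx])
  fc <- records$fold_change[idx]
  set <- switch(direction,
                up = c("up", "unique_case"),
                down = c("down", "unique_control"),
                both = c("up", "unique_case", "down", "unique_control"))
  flag <- !is.na(status) & status %in% set
  score <- rep(NA_real_, nrow(genes))
  score[flag] <- switch(direction,
                        up = fc[flag],
                        down = 1 / fc[flag],
                        both = pmax(fc[flag], 1 / fc[flag]))
  genes$dap <- flag
  genes$fc <- score
  attr(genes, "n_unlinked") <- sum(is.na(idx) | is.na(genes$protein_id))
  genes
}

# qualifying-window coverage for one contig's flag vector; returns a
# logical coverage vector (TRUE = ordinal covered by >= 1 qualifying
# window under any rule)
window_coverage <- function(flags, rules) {
  n <- length(flags)
  covered <- logical(n)
  cs <- cumsum(c(0L, as.integer(flags)))
  for (r in rules) {
    w <- r[1]; m <- r[2]
    if (n < w) next
    starts <- seq_len(n - w + 1L)
    hits <- starts[cs[starts + w] - cs[starts] >= m]
    for (s in hits) covered[s:(s + w - 1L)] <- TRUE
  }
  covered
}

#' Detect candidate gene clusters by genome-window rules
#'
#' Slides every window of every rule along each contig's gene order; a
#' window qualifies if it holds at least the rule's minimum number of DAP
#' genes. Qualifying windows that overlap or abut are merged into one
#' maximal candidate, and each candidate is trimmed so that its span
#' starts and ends on DAP genes. Candidates never cross contig
#' boundaries, never overlap each other, and none contains another.
#'
#' @param flagged gene models with `dap`/`fc` columns
#'   (see [flag_dap_genes()]).
#' @param rules a [window_rules()] list.
#' @return data.frame of unscored candidates: `contig`, `first_ordinal`,
#'   `last_ordinal`, `n_genes` (trimmed span size), `n_dap`, plus genomic
#'   coordinates `start_bp`, `end_bp` and the member/DAP gene ID lists
#'   (comma-separated).
#' @export
find_candidate_clusters <- function(flagged, rules = window_rules()) {
  out <- list()
  for (ctg in unique(flagged$contig)) {
    g <- flagged[flagged$contig == ctg, , drop = FALSE]
    g <- g[order(g$ordinal), , drop = FALSE]
    covered <- window_coverage(g$dap, rules)
    if (!any(covered)) next
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      span <- starts[k]:ends[k]
      fl <- span[g$dap[span]]
      if (!length(fl)) next  # cannot happen: every window holds >=1 flag
      span <- fl[1]:fl[length(fl)]  # trim to outermost DAP genes
      memb <- g[span, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg,
        first_ordinal = memb$ordinal[1],
        last_ordinal = memb$ordinal[nrow(memb)],
        n_genes = nrow(memb),
        n_dap = sum(memb$dap),
        start_bp = min(memb$start),
        end_bp = max(memb$end),
        gene_ids = paste(memb$gene_id, collapse = ","),
        dap_gene_ids = paste(memb$gene_id[memb$dap], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), first_ordinal = integer(),
                      last_ordinal = integer(), n_genes = integer(),
                      n_dap = integer(), start_bp = integer(),
                      end_bp = integer(), gene_ids = character(),
                      dap_gene_ids = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Average fold-change level (AFCL) of a candidate cluster
#'
#' Arithmetic mean, on the linear fold-change scale, of the fold changes
#' of the candidate's DAP genes (imputed values of unique proteins
#' included). With `all_genes = TRUE` the mean instead runs over every
#' member gene, counting genes without a defined fold change as 1
#' (sensitivity-analysis mode).
#'
#' @param candidate one row of the candidate table.
#' @param flagged the flagged gene models the candidates were derived
#'   from.
#' @param all_genes average over all member genes instead of DAP genes.
#' @return the AFCL (positive real).
#' @export
compute_afcl <- function(candidate, flagged, all_genes = FALSE) {
  g <- flagged[flagged$contig == candidate$contig &
                 flagged$ordinal >= candidate$first_ordinal &
                 flagged$ordinal <= candidate$last_ordinal, , drop = FALSE]
  if (all_genes) {
    fc <- ifelse(is.na(g$fc), 1, g$fc)
    return(mean(fc))
  }
  fc <- g$fc[g$dap & !is.na(g$fc)]
  if (!length(fc))
    stop("candidate has no DAP gene with a defined fold change; cannot score")
  mean(fc)
}

#' Rank scored candidates and apply the selection rule
#'
#' Candidates are ranked by AFCL descending; ties are broken by more DAP
#' genes, then larger span, then lower first ordinal. The selected cluster
#' is the highest-ranked candidate with at least `min_genes` genes (the
#' "highest AFCL with at least five genes" criterion), or none.
#'
#' @param candidates scored candidate table (an `afcl` column present).
#' @param min_genes minimum span size for selection (default 5).
#' @return list with `candidates` (ranked, `rank` column added) and
#'   `selected` (one-row data.frame or NULL).
#' @export
rank_and_select <- function(candidates, min_genes = 5) {
  if (!nrow(candidates))
    return(list(candidates = candidates, selected = NULL))
  o <- order(-candidates$afcl, -candidates$n_dap, -candidates$n_genes,
             candidates$first_ordinal)
  candidates <- candidates[o, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  eligible <- which(candidates$n_genes >= min_genes)
  selected <- if (length(eligible)) candidates[eligible[1], , drop = FALSE]
  else NULL
  list(candidates = candidates, selected = selected)
}

#' Screen a genome for substrate-degradation gene clusters
#'
#' End-to-end screen: call DAPs from the quantification matrix, flag DAP
#' genes along the ordered genome, detect candidate clusters by the
#' window rules, score each candidate by AFCL, rank, and select the
#' highest-AFCL candidate with at least `min_genes` genes.
#'
#' @param quant a [quant_matrix()].
#' @param genes gene models (ordered or not; ordinals are (re)assigned).
#' @param params a [dap_params()].
#' @param rules a [window_rules()] list.
#' @param direction screened DAP direction, see [flag_dap_genes()].
#' @param min_genes selection threshold on span size.
#' @param afcl_all_genes see [compute_afcl()].
#' @param case,control condition labels, see [call_daps()].
#' @param daps optionally, precomputed `dap_calls` (then `quant`,
#'   `params`, `case`, `control` are ignored for the calling step).
#' @return object of class `cluster_screen`: list with `candidates`
#'   (ranked table), `selected`, `daps`, `flagged` (gene table with
#'   dap/fc columns), `rules`, `direction`, `min_genes`, `n_unlinked`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 120, seed = 7))
#' scr <- screen_clusters(sim$quant, sim$genes)
#' scr
#' @export
screen_clusters <- function(quant, genes, params = dap_params(),
                            rules = window_rules(),
                            direction = "up", min_genes = 5,
                            afcl_all_genes = FALSE, case = NULL,
                            control = NULL, daps = NULL) {
  rules <- window_rules(rules)
  if (is.null(daps))
    daps <- call_daps(quant, params = params, case = case, control = control)
  genes <- order_genes(genes)
  flagged <- flag_dap_genes(genes, daps, direction = direction)
  candidates <- find_candidate_clusters(flagged, rules)
  if (nrow(candidates))
    candidates$afcl <- vapply(seq_len(nrow(candidates)), function(i)
      compute_afcl(candidates[i, ], flagged, all_genes = afcl_all_genes),
      numeric(1))
  else candidates$afcl <- numeric(0)
  rs <- rank_and_select(candidates, min_genes = min_genes)
  structure(list(candidates = rs$candidates, selected = rs$selected,
                 daps = daps, flagged = flagged, rules = rules,
                 direction = direction, min_genes = min_genes,
                 n_unlinked = attr(flagged, "n_unlinked")),
            class = "cluster_screen")
}

#' @export
print.cluster_screen <- function(x, ...) {
  cat("Gene-cluster screen (direction: ", x$direction, ", rules: ",
      paste(vapply(x$rules, function(r)
        paste0(r[2], "/", r[1]), ""), collapse = ", "),
      ", selection: >= ", x$min_genes, " genes)\n", sep = "")
  cat(nrow(x$candidates), "candidate cluster(s)\n")
  if (nrow(x$candidates)) {
    show <- utils::head(x$candidates[, c("rank", "contig", "first_ordinal",
                                         "last_ordinal", "n_genes", "n_dap",
                                         "afcl")], 5)
    print(show, row.names = FALSE)
  }
  if (!is.null(x$selected))
    cat(sprintf("selected: %s ordinals %d-%d, %d genes (%d DAP), AFCL %.2f\n",
                x$selected$contig, x$selected$first_ordinal,
                x$selected$last_ordinal, x$selected$n_genes,
                x$selected$n_dap, x$selected$afcl))
  else cat("selected: none\n")
  invisible(x)
}

#' @method summary cluster_screen
#' @export
summary.cluster_screen <- function(object, ...) {
  s <- list(candidates = object$candidates, selected = object$selected,
            dap_summary = dap_partition_summary(object$daps),
            n_unlinked = object$n_unlinked)
  class(s) <- "summary.cluster_screen"
  s
}

#' @export
print.summary.cluster_screen <- function(x, ...) {
  cat("DAP partition:\n")
  print(x$dap_summary$counts)
  cat(x$n_unlinked, "gene(s) without a quantified protein\n")
  cat(nrow(x$candidates), "candidate cluster(s):\n")
  if (nrow(x$candidates))
    print(x$candidates[, c("rank", "contig", "first_ordinal", "last_ordinal",
                           "n_genes", "n_dap", "afcl")], row.names = FALSE)
  invisible(x)
}

#' Plot a cluster screen along the genome
#'
#' Per-gene fold change (log2 scale) against genome ordinal, DAP genes
#' highlighted, candidate spans underlined and the selected cluster
#' marked.
#'
#' @param x a `cluster_screen` object.
#' @param ... passed to [graphics::plot()].
#' @method plot cluster_screen
#' @export
plot.cluster_screen <- function(x, ...) {
  g <- x$flagged
  y <- ifelse(is.na(g$fc), 0, log2(g$fc))
  graphics::plot(g$ordinal, y, type = "h",
                 col = ifelse(g$dap, "firebrick", "grey70"),
                 xlab = "gene ordinal (genome order)",
                 ylab = expression(log[2] ~ "fold change"), ...)
  if (nrow(x$candidates))
    graphics::segments(x$candidates$first_ordinal, 0,
                       x$candidates$last_ordinal, 0,
                       lwd = 4, col = "steelblue")
  if (!is.null(x$selected))
    graphics::segments(x$selected$first_ordinal, 0, x$selected$last_ordinal,
                       0, lwd = 4, col = "darkorange")
  b <- cumsum(table(factor(g$contig, levels = unique(g$contig))))
  if (length(b) > 1)
    graphics::abline(v = g$ordinal[1] + utils::head(b, -1) - 0.5,
                     lty = 3, col = "grey50")
  invisible(x)
}

#' Export candidate cluster spans as BED
#'
#' Writes candidate genomic spans (0-based half-open, from member gene
#' extremes) for genome-browser viewing.
#'
#' @param screen a `cluster_screen` object.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(screen, path) {
  cand <- screen$candidates
  if (!nrow(cand)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(cand$contig, cand$start_bp - 1L, cand$end_bp,
                    paste0("cluster_", cand$rank),
                    round(cand$afcl, 3), ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
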