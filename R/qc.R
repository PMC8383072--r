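#' Run-by-run Pearson correlation of a quantification matrix
#'
#' Pearson correlation between every pair of runs on log2 intensities,
#' pairwise-complete (only proteins present with positive intensity in
#' both runs of a pair enter that pair's correlation). Pairs with fewer
#' than `min_pairs` complete observations are marked undefined (`NA`).
#' The grid is symmetric with unit diagonal.
#'
#' @param quant a [quant_matrix()].
#' @param min_pairs minimum complete observations per pair (default 3).
#' @return run x run correlation matrix.
#' @export
pearson_run_correlation <- function(quant, min_pairs = 3) {
  x <- quant$abundance
  x[!is.na(x) & x <= 0] <- NA  # cannot log; drop from pairwise sets
  lx <- log2(x)
  cc <- suppressWarnings(stats::cor(lx, use = "pairwise.complete.obs",
                                    method = "pearson"))
  npairs <- crossprod(!is.na(lx))
  cc[npairs < min_pairs] <- NA
  diag(cc) <- 1
  cc
}

#' Detection Venn counts between the two conditions
#'
#' Partitions the proteins detected in at least one condition into three
#' classes by per-group detection state: detected in both, case only,
#' control only. Detection follows [detect_state()] (present in >=
#' `min_detect_runs` runs of the group).
#'
#' @param quant a [quant_matrix()].
#' @param params a [dap_params()].
#' @param case,control condition labels; defaults as in [call_daps()].
#' @return named integer vector `c(both, case_only, control_only)`.
#' @export
venn_counts <- function(quant, params = dap_params(), case = NULL,
                        control = NULL) {
  conds <- conditions(quant)
  if (is.null(case)) case <- conds[1]
  if (is.null(control)) control <- setdiff(conds, case)[1]
  ab <- quant$abundance
  cond <- quant$runs$condition
  det_case <- rowSums(!is.na(ab[, cond == case, drop = FALSE])) >=
    params$min_detect_runs
  det_control <- rowSums(!is.na(ab[, cond == control, drop = FALSE])) >=
    params$min_detect_runs
  c(both = sum(det_case & det_control),
    case_only = sum(det_case & !det_control),
    control_only = sum(det_control & !det_case))
}

#' Assemble a dataset-level QC report
#'
#' Bundles the run-correlation grid, the detection Venn counts and the
#' DAP status partition, and can write them as a markdown report.
#'
#' @param quant a [quant_matrix()].
#' @param daps optional precomputed `dap_calls`.
#' @param params a [dap_params()].
#' @param screen optional `cluster_screen` whose top candidates are
#'   included.
#' @return list of class `qc_report` with elements `correlation`, `venn`,
#'   `dap_summary`, `top_clusters`.
#' @export
qc_report <- function(quant, daps = NULL, params = dap_params(),
                      screen = NULL) {
  if (is.null(daps)) daps <- call_daps(quant, params = params)
  structure(list(
    correlation = pearson_run_correlation(quant),
    venn = venn_counts(quant, params = params,
                       case = daps$case, control = daps$control),
    dap_summary = dap_partition_summary(daps),
    top_clusters = if (!is.null(screen))
      utils::head(screen$candidates, 5) else NULL),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Detection Venn counts:\n"); print(x$venn)
  cat("DAP partition:\n"); print(x$dap_summary$counts)
  cat("Run correlation (log2, pairwise-complete):\n")
  print(round(x$correlation, 3))
  if (!is.null(x$top_clusters)) {
    cat("Top candidate clusters:\n")
    print(x$top_clusters[, c("rank", "contig", "first_ordinal",
                             "last_ordinal", "n_genes", "n_dap", "afcl")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a QC report as markdown
#'
#' @param report a [qc_report()] object.
#' @param path output markdown path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  fmt_table <- function(df) {
    df <- as.data.frame(df)
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    c(hdr, sep, rows)
  }
  lines <- c("# Proteome QC report", "",
             "## Detection Venn counts", "",
             fmt_table(as.data.frame(t(report$venn))), "",
             "## DAP status partition", "",
             fmt_table(as.data.frame(t(as.matrix(report$dap_summary$counts)))),
             "",
             sprintf("Up set: %d; down set: %d; total DAPs: %d of %d proteins.",
                     report$dap_summary$n_up_set, report$dap_summary$n_down_set,
                     report$dap_summary$n_daps, report$dap_summary$n_proteins),
             "", "## Run-by-run Pearson correlation (log2)", "",
             fmt_table(cbind(run = rownames(report$correlation),
                             as.data.frame(round(report$correlation, 3)))))
  if (!is.null(report$top_clusters) && nrow(report$top_clusters))
    lines <- c(lines, "", "## Top candidate clusters", "",
               fmt_table(report$top_clusters[, c("rank", "contig",
                                                 "first_ordinal", "last_ordinal",
                                                 "n_genes", "n_dap", "afcl")]))
  writeLines(lines, path)
  invisible(path)
}
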