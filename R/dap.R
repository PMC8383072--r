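#' Parameters for differential-abundance calling
#'
#' Defaults reproduce the standard label-free screening thresholds: a
#' 2.0-fold change cut-off combined with p < 0.05 from a two-sided t-test,
#' detection in at least 2 runs of a group to count as present in that
#' group, and an imputed fold change of 2 for proteins detected in only
#' one group ("unique" proteins).
#'
#' @param fc_cutoff fold-change cut-off (> 1); a protein is up if its
#'   fold change is >= `fc_cutoff`, down if <= `1/fc_cutoff`.
#' @param p_cutoff significance threshold (strict: p must be < this).
#' @param min_detect_runs runs of a group a protein must be present in to
#'   count as detected in that group.
#' @param unique_fc_impute fold change assigned to case-unique proteins
#'   (control-unique proteins get its reciprocal).
#' @param log2_test if TRUE (default) the t-test runs on log2 intensities;
#'   fold changes are always ratios of linear-scale group means.
#' @param average_tech_reps if TRUE, technical replicates are averaged
#'   within each biological replicate before testing (n = number of
#'   biological replicates per group).
#' @param adjust multiple-testing correction applied to the t-test
#'   p-values before thresholding: `"none"` (default) or any method of
#'   [stats::p.adjust()] (e.g. `"BH"`).
#' @return a list of class `dap_params`.
#' @export
dap_params <- function(fc_cutoff = 2, p_cutoff = 0.05, min_detect_runs = 2,
                       unique_fc_impute = 2, log2_test = TRUE,
                       average_tech_reps = FALSE, adjust = "none") {
  stopifnot(fc_cutoff > 1, p_cutoff > 0, p_cutoff < 1, min_detect_runs >= 1)
  structure(list(fc_cutoff = fc_cutoff, p_cutoff = p_cutoff,
                 min_detect_runs = as.integer(min_detect_runs),
                 unique_fc_impute = unique_fc_impute,
                 log2_test = isTRUE(log2_test),
                 average_tech_reps = isTRUE(average_tech_reps),
                 adjust = adjust),
            class = "dap_params")
}

#' Per-group detection state of one protein
#'
#' A protein counts as detected in a group iff it is present (non-missing)
#' in at least `params$min_detect_runs` runs of that group.
#'
#' @param abundances numeric vector of one protein's run values (`NA` =
#'   missing).
#' @param condition condition label per run (same length).
#' @param case,control the two condition labels.
#' @param params a [dap_params()].
#' @return named logical vector `c(case = , control = )`.
#' @export
detect_state <- function(abundances, condition, case, control,
                         params = dap_params()) {
  c(case = sum(!is.na(abundances[condition == case])) >= params$min_detect_runs,
    control = sum(!is.na(abundances[condition == control])) >= params$min_detect_runs)
}

#' Two-sided Welch t-test on (log2) intensities
#'
#' Wraps [stats::t.test()] (Welch, two-sided) with the conventions the
#' abundance data need: intensities are log2-transformed first (zeros
#' cannot be logged and are dropped), fewer than 2 usable values on either
#' side yields `NA`, and the degenerate case of two zero-variance samples
#' is resolved directly (equal means: p = 1; unequal means: p = 0, the t
#' statistic diverging).
#'
#' @param x,y numeric vectors of present intensities for the two groups.
#' @param log2 transform to log2 scale before testing (default TRUE).
#' @return p-value in \[0, 1\], or `NA` if either side has < 2 usable
#'   values.
#' @export
two_sided_t_test <- function(x, y, log2 = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (log2) {
    x <- x[x > 0]; y <- y[y > 0]
    x <- base::log2(x); y <- base::log2(y)
  }
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  degenerate <- function() if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  if (stats::sd(x) == 0 && stats::sd(y) == 0) return(degenerate())
  tryCatch(stats::t.test(x, y, alternative = "two.sided")$p.value,
           error = function(e) degenerate())
}

#' Fold change between group means
#'
#' Ratio of linear-scale group means, case over control. Satisfies
#' `fold_change(a, b) == 1 / fold_change(b, a)`.
#'
#' @param mean_case,mean_control group means (> 0).
#' @return positive real.
#' @export
fold_change <- function(mean_case, mean_control) {
  stopifnot(mean_case > 0, mean_control > 0)
  mean_case / mean_control
}

# status assignment for a both-detected protein; strict inequality on p,
# inclusive on the fold-change cut-offs
classify_dap <- function(fc, p, params) {
  if (is.na(p) || is.na(fc)) return("unchanged")
  if (p < params$p_cutoff) {
    if (fc >= params$fc_cutoff) return("up")
    if (fc <= 1 / params$fc_cutoff) return("down")
  }
  "unchanged"
}

#' Call differentially abundant proteins (DAPs)
#'
#' Classifies every protein of a quantification matrix into exactly one
#' status:
#' \describe{
#'   \item{up / down}{detected in both groups, fold change >= cut-off
#'     (resp. <= 1/cut-off) and t-test p < threshold;}
#'   \item{unique_case / unique_control}{detected in one group only;
#'     fold change imputed to `unique_fc_impute` (resp. its reciprocal),
#'     p undefined;}
#'   \item{unchanged}{detected in both, thresholds not met (including
#'     proteins with too few usable values to test, which are flagged);}
#'   \item{undetected}{detected in neither group.}
#' }
#' The "case-up DAP set" is up + unique_case; the "case-down DAP set" is
#' down + unique_control.
#'
#' @param quant a [quant_matrix()].
#' @param params a [dap_params()].
#' @param case,control condition labels; default: first and second
#'   condition in order of appearance in the run design.
#' @return object of class `dap_calls`: list with `records` (one row per
#'   protein: `protein_id`, `n_case`, `n_control`, `mean_case`,
#'   `mean_control`, `fold_change`, `p_value`, `status`, `flagged`),
#'   `counts` (status counts), `case`, `control`, `params`.
#' @export
call_daps <- function(quant, params = dap_params(), case = NULL,
                      control = NULL) {
  stopifnot(inherits(quant, "quant_matrix"))
  conds <- conditions(quant)
  if (is.null(case)) case <- conds[1]
  if (is.null(control)) control <- setdiff(conds, case)[1]
  if (!all(c(case, control) %in% conds))
    stop("case/control condition not present in run design")
  ab <- quant$abundance
  cond <- quant$runs$condition
  if (params$average_tech_reps) {
    key <- paste(cond, quant$runs$bio_rep, sep = "//")
    groups <- unique(key)
    ab <- do.call(cbind, lapply(groups, function(g)
      rowMeans(ab[, key == g, drop = FALSE], na.rm = TRUE)))
    colnames(ab) <- groups
    ab[is.nan(ab)] <- NA  # all tech reps missing
    cond <- vapply(strsplit(groups, "//", fixed = TRUE), `[`, "", 1)
  }
  if (sum(cond == case) < 2 || sum(cond == control) < 2)
    stop("need at least 2 runs per condition")
  ca <- ab[, cond == case, drop = FALSE]
  co <- ab[, cond == control, drop = FALSE]
  n_case <- rowSums(!is.na(ca))
  n_control <- rowSums(!is.na(co))
  det_case <- n_case >= params$min_detect_runs
  det_control <- n_control >= params$min_detect_runs

  n <- nrow(ab)
  mean_case <- ifelse(n_case > 0, rowMeans(ca, na.rm = TRUE), NA_real_)
  mean_control <- ifelse(n_control > 0, rowMeans(co, na.rm = TRUE), NA_real_)
  fc <- rep(NA_real_, n)
  p <- rep(NA_real_, n)
  status <- rep("undetected", n)
  flagged <- rep(FALSE, n)

  both <- det_case & det_control
  for (i in which(both)) {
    if (mean_control[i] == 0 && mean_case[i] > 0) next  # -> unique_case below
    if (mean_case[i] == 0 && mean_control[i] > 0) next  # -> unique_control
    if (mean_case[i] == 0 && mean_control[i] == 0) {
      status[i] <- "unchanged"; flagged[i] <- TRUE; next
    }
    fc[i] <- fold_change(mean_case[i], mean_control[i])
    p[i] <- two_sided_t_test(ca[i, ], co[i, ], log2 = params$log2_test)
  }
  tested <- both & !is.na(p)
  if (params$adjust != "none")
    p[tested] <- stats::p.adjust(p[tested], method = params$adjust)

  uc <- (det_case & !det_control) |
    (both & !is.na(mean_control) & mean_control == 0 & mean_case > 0)
  uo <- (det_control & !det_case) |
    (both & !is.na(mean_case) & mean_case == 0 & mean_control > 0)
  status[uc] <- "unique_case"
  fc[uc] <- params$unique_fc_impute
  p[uc] <- NA_real_
  status[uo] <- "unique_control"
  fc[uo] <- 1 / params$unique_fc_impute
  p[uo] <- NA_real_

  rest <- both & !uc & !uo & !(mean_case == 0 & mean_control == 0)
  for (i in which(rest)) {
    status[i] <- classify_dap(fc[i], p[i], params)
    if (is.na(p[i])) flagged[i] <- TRUE  # detected both but untestable
  }

  records <- data.frame(
    protein_id = rownames(ab), n_case = n_case, n_control = n_control,
    mean_case = mean_case, mean_control = mean_control,
    fold_change = fc, p_value = p,
    status = factor(status, levels = dap_status_levels()),
    flagged = flagged, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(list(records = records,
                 counts = table(records$status),
                 case = case, control = control, params = params),
            class = "dap_calls")
}

dap_status_levels <- function() {
  c("up", "down", "unchanged", "unique_case", "unique_control", "undetected")
}

#' Status partition summary of a DAP call set
#'
#' Counts per status plus the two directional DAP sets: the case-up set
#' (up + unique_case) and the case-down set (down + unique_control). The
#' status counts always sum to the number of proteins.
#'
#' @param daps a `dap_calls` object (or its `records` data.frame).
#' @return list with `counts` (named integer vector over all statuses),
#'   `n_up_set`, `n_down_set`, `n_daps` (their sum), `n_proteins`.
#' @export
dap_partition_summary <- function(daps) {
  records <- if (inherits(daps, "dap_calls")) daps$records else daps
  st <- factor(as.character(records$status), levels = dap_status_levels())
  counts <- table(st)
  n_up <- sum(counts[c("up", "unique_case")])
  n_down <- sum(counts[c("down", "unique_control")])
  list(counts = c(counts), n_up_set = n_up, n_down_set = n_down,
       n_daps = n_up + n_down, n_proteins = nrow(records))
}

#' @export
print.dap_calls <- function(x, ...) {
  s <- dap_partition_summary(x)
  cat("DAP calls (", x$case, " vs ", x$control, "): ",
      s$n_proteins, " proteins\n", sep = "")
  print(s$counts)
  cat(sprintf("%s-up DAP set: %d   %s-down DAP set: %d\n",
              x$case, s$n_up_set, x$case, s$n_down_set))
  cat(sprintf("thresholds: fold change >= %.3g, p < %.3g (%s)\n",
              x$params$fc_cutoff, x$params$p_cutoff,
              if (x$params$adjust == "none") "unadjusted" else x$params$adjust))
  invisible(x)
}

#' @method summary dap_calls
#' @export
summary.dap_calls <- function(object, ...) {
  s <- dap_partition_summary(object)
  s$case <- object$case
  s$control <- object$control
  s$n_flagged <- sum(object$records$flagged)
  class(s) <- "summary.dap_calls"
  s
}

#' @export
print.summary.dap_calls <- function(x, ...) {
  cat("Status partition (", x$case, " vs ", x$control, "):\n", sep = "")
  print(x$counts)
  cat(sprintf("up set %d, down set %d, total DAPs %d of %d proteins (%d flagged untestable)\n",
              x$n_up_set, x$n_down_set, x$n_daps, x$n_proteins, x$n_flagged))
  invisible(x)
}

#' Volcano plot of DAP calls
#'
#' log2 fold change against -log10 p for tested proteins; threshold lines
#' at the fold-change cut-offs and the p cut-off.
#'
#' @param x a `dap_calls` object.
#' @param ... passed to [graphics::plot()].
#' @method plot dap_calls
#' @export
plot.dap_calls <- function(x, ...) {
  r <- x$records[!is.na(x$records$p_value), ]
  if (!nrow(r)) {
    warning("no tested proteins to plot")
    return(invisible(x))
  }
  col <- ifelse(r$status == "up", "firebrick",
                ifelse(r$status == "down", "steelblue", "grey60"))
  graphics::plot(log2(r$fold_change), -log10(r$p_value), col = col,
                 pch = 16, cex = 0.6,
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ italic(p)), ...)
  graphics::abline(v = c(-1, 1) * log2(x$params$fc_cutoff), lty = 2,
                   col = "grey40")
  graphics::abline(h = -log10(x$params$p_cutoff), lty = 2, col = "grey40")
  invisible(x)
}
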