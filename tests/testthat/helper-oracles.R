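# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Exact two-sided permutation test on the difference of means of the
# pooled log2 values: enumerates every way to relabel the pooled sample
# into groups of the original sizes.
perm_test_p <- function(x, y, log2_scale = TRUE) {
  if (log2_scale) { x <- log2(x); y <- log2(y) }
  pool <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  idx <- utils::combn(length(pool), nx)
  stats <- apply(idx, 2, function(i)
    abs(mean(pool[i]) - mean(pool[-i])))
  mean(stats >= obs - 1e-12)
}

# Welch t-test from the textbook formulae (no call into stats::t.test).
welch_formula_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Naive window-rule candidate detection: enumerate every window of every
# rule, collect qualifying intervals, merge overlapping-or-abutting
# intervals, trim to flagged endpoints. Positions are 1-based within the
# flag vector; returns a data.frame of (first, last) or zero rows.
enum_candidates <- function(flags, rules = list(c(10L, 3L), c(15L, 5L))) {
  n <- length(flags)
  ivs <- list()
  for (r in rules) {
    w <- r[1]; m <- r[2]
    if (n < w) next
    for (s in seq_len(n - w + 1L))
      if (sum(flags[s:(s + w - 1L)]) >= m)
        ivs[[length(ivs) + 1L]] <- c(s, s + w - 1L)
  }
  if (!length(ivs))
    return(data.frame(first = integer(), last = integer()))
  ivs <- ivs[order(vapply(ivs, `[`, 0L, 1))]
  merged <- list(ivs[[1]])
  for (iv in ivs[-1]) {
    cur <- merged[[length(merged)]]
    if (iv[1] <= cur[2] + 1L)
      merged[[length(merged)]] <- c(cur[1], max(cur[2], iv[2]))
    else merged[[length(merged) + 1L]] <- iv
  }
  out <- lapply(merged, function(iv) {
    fl <- which(flags[iv[1]:iv[2]]) + iv[1] - 1L
    c(first = fl[1], last = fl[length(fl)])
  })
  as.data.frame(do.call(rbind, out))
}

# Exact hypergeometric upper tail from binomial coefficients.
hyper_tail <- function(N, K, n, k) {
  ks <- k:min(n, K)
  ks <- ks[n - ks <= N - K]
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Build a gene table on one or more contigs from a logical flag vector,
# suitable for find_candidate_clusters(); fc = fc_value where flagged.
flags_to_genes <- function(flags, contig = "c1", fc_value = 4) {
  n <- length(flags)
  data.frame(gene_id = sprintf("%s_g%03d", contig, seq_len(n)),
             contig = contig,
             start = (seq_len(n) - 1L) * 1100L + 1L,
             end = (seq_len(n) - 1L) * 1100L + 1000L,
             strand = "+",
             protein_id = sprintf("%s_g%03d", contig, seq_len(n)),
             ordinal = seq_len(n) - 1L,
             dap = flags,
             fc = ifelse(flags, fc_value, NA_real_),
             stringsAsFactors = FALSE)
}

# Small quantification matrix from explicit case/control value matrices
# (rows = proteins); NA encodes missingness.
toy_quant <- function(case_vals, control_vals, ids = NULL) {
  stopifnot(nrow(case_vals) == nrow(control_vals))
  n <- nrow(case_vals)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  ab <- cbind(case_vals, control_vals)
  colnames(ab) <- c(paste0("IAA_b", c(1, 1, 2, 2), "_t", c(1, 2, 1, 2))[seq_len(ncol(case_vals))],
                    paste0("IAACon_b", c(1, 1, 2, 2), "_t", c(1, 2, 1, 2))[seq_len(ncol(control_vals))])
  rownames(ab) <- ids
  runs <- data.frame(
    run_id = colnames(ab),
    condition = rep(c("IAA", "IAACon"), c(ncol(case_vals), ncol(control_vals))),
    bio_rep = c(rep(c(1, 1, 2, 2), length.out = ncol(case_vals)),
                rep(c(1, 1, 2, 2), length.out = ncol(control_vals))),
    tech_rep = c(rep(c(1, 2, 1, 2), length.out = ncol(case_vals)),
                 rep(c(1, 2, 1, 2), length.out = ncol(control_vals))))
  quant_matrix(ab, runs)
}
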