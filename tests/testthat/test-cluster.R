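test_that("DAP genes are flagged through the protein link with direction control", {
  genes <- flags_to_genes(rep(FALSE, 10))[, 1:7]  # drop dap/fc columns
  records <- data.frame(
    protein_id = genes$protein_id,
    fold_change = c(1, 1, 6, 8, 2, 1, 1, 1, 1, 1),
    status = c("unchanged", "unchanged", "up", "up", "unique_case",
               rep("unchanged", 5)))
  daps <- structure(list(records = records), class = "dap_calls")
  fl <- flag_dap_genes(genes, daps, direction = "up")
  expect_equal(which(fl$dap) - 1L, c(2L, 3L, 4L))
  expect_equal(fl$fc[5], 2)          # unique protein scores its imputed value
  expect_true(all(is.na(fl$fc[!fl$dap])))
  # down direction on an all-up dataset flags nothing
  expect_equal(sum(flag_dap_genes(genes, daps, direction = "down")$dap), 0)
  # a gene without a linked protein is never flagged
  genes2 <- genes; genes2$protein_id[3] <- NA
  fl2 <- flag_dap_genes(genes2, daps, direction = "up")
  expect_false(fl2$dap[3])
  expect_equal(attr(fl2, "n_unlinked"), 1L)
})

test_that("window rules detect, merge and trim candidates as specified", {
  # flags at ordinals 1, 5, 9 within 10 genes: one candidate spanning 1-9
  f1 <- rep(FALSE, 10); f1[c(2, 6, 10)] <- TRUE
  c1 <- find_candidate_clusters(flags_to_genes(f1))
  expect_equal(nrow(c1), 1L)
  expect_equal(c(c1$first_ordinal, c1$last_ordinal), c(1L, 9L))
  expect_equal(c1$n_dap, 3L)

  # flags at ordinals 1, 11, 21: no rule is satisfied anywhere
  f2 <- rep(FALSE, 25); f2[c(2, 12, 22)] <- TRUE
  expect_equal(nrow(find_candidate_clusters(flags_to_genes(f2))), 0L)

  # flags at 0,3,6,9,12: both rules fire and merge into a single 0-12 span
  f3 <- rep(FALSE, 15); f3[c(1, 4, 7, 10, 13)] <- TRUE
  c3 <- find_candidate_clusters(flags_to_genes(f3))
  expect_equal(nrow(c3), 1L)
  expect_equal(c(c3$first_ordinal, c3$last_ordinal), c(0L, 12L))
})

test_that("candidate detection matches brute-force window enumeration", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(20:120, 1)
    flags <- runif(n) < runif(1, 0, 0.4)
    got <- find_candidate_clusters(flags_to_genes(flags))
    want <- enum_candidates(flags)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$first_ordinal, want$first - 1L)
      expect_equal(got$last_ordinal, want$last - 1L)
    }
  }
})

test_that("candidates respect contig boundaries, flagged endpoints and disjointness", {
  set.seed(123)
  for (i in 1:30) {
    fa <- runif(40) < 0.3; fb <- runif(40) < 0.3
    genes <- rbind(flags_to_genes(fa, "c1"), flags_to_genes(fb, "c2"))
    genes$ordinal <- seq_len(nrow(genes)) - 1L
    cand <- find_candidate_clusters(genes)
    if (!nrow(cand)) next
    # never cross a contig boundary
    expect_true(all(cand$first_ordinal >= 40 | cand$last_ordinal <= 39))
    # endpoints flagged
    flags_all <- genes$dap
    expect_true(all(flags_all[cand$first_ordinal + 1L]))
    expect_true(all(flags_all[cand$last_ordinal + 1L]))
    # no two candidates overlap
    if (nrow(cand) > 1) {
      o <- cand[order(cand$first_ordinal), ]
      expect_true(all(o$first_ordinal[-1] > o$last_ordinal[-nrow(o)]))
    }
  }
})

test_that("a dense flag block split across two contigs yields two candidates", {
  genes <- rbind(flags_to_genes(c(rep(FALSE, 36), rep(TRUE, 4)), "c1"),
                 flags_to_genes(c(rep(TRUE, 4), rep(FALSE, 36)), "c2"))
  genes$ordinal <- seq_len(nrow(genes)) - 1L
  cand <- find_candidate_clusters(genes)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$contig, c("c1", "c2"))
  expect_equal(cand$n_genes, c(4L, 4L))
})

test_that("AFCL is the arithmetic mean of DAP fold changes on the linear scale", {
  flags <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  g <- flags_to_genes(flags)
  g$fc[flags] <- c(10, 20, 30)
  cand <- data.frame(contig = "c1", first_ordinal = 0L, last_ordinal = 4L)
  expect_equal(compute_afcl(cand, g), 20)
  g$fc[flags] <- c(7, 7, 7)
  expect_equal(compute_afcl(cand, g), 7)
  g$fc[flags] <- c(6, 2, NA); g$dap[4] <- FALSE  # one up at 6, one imputed unique at 2
  expect_equal(compute_afcl(cand, g), 4)
  # all-genes mode counts unmeasured members as 1
  g2 <- flags_to_genes(c(TRUE, FALSE, TRUE))
  g2$fc[c(1, 3)] <- c(5, 6)
  cand2 <- data.frame(contig = "c1", first_ordinal = 0L, last_ordinal = 2L)
  expect_equal(compute_afcl(cand2, g2, all_genes = TRUE), mean(c(5, 1, 6)))
})

test_that("ranking is AFCL-descending with documented tie-breaks and selection rule", {
  cand <- data.frame(contig = "c1",
                     first_ordinal = c(0L, 20L), last_ordinal = c(8L, 28L),
                     n_genes = c(9L, 9L), n_dap = c(5L, 4L),
                     afcl = c(40.89, 8.24))
  rs <- rank_and_select(cand)
  expect_equal(rs$candidates$afcl, c(40.89, 8.24))
  expect_equal(rs$selected$afcl, 40.89)

  # the top-AFCL cluster is too small: runner-up selected, rank kept
  small <- data.frame(contig = "c1",
                      first_ordinal = c(0L, 20L), last_ordinal = c(3L, 28L),
                      n_genes = c(4L, 9L), n_dap = c(4L, 5L),
                      afcl = c(50, 12))
  rs2 <- rank_and_select(small, min_genes = 5)
  expect_equal(rs2$candidates$rank[rs2$candidates$afcl == 50], 1L)
  expect_equal(rs2$selected$afcl, 12)

  # identical AFCL: more DAP genes wins
  tie <- data.frame(contig = "c1",
                    first_ordinal = c(0L, 20L), last_ordinal = c(8L, 28L),
                    n_genes = c(9L, 9L), n_dap = c(3L, 5L),
                    afcl = c(10, 10))
  expect_equal(rank_and_select(tie)$candidates$n_dap, c(5L, 3L))

  # nothing eligible -> selected is NULL
  none <- data.frame(contig = "c1", first_ordinal = 0L, last_ordinal = 2L,
                     n_genes = 3L, n_dap = 3L, afcl = 9)
  expect_null(rank_and_select(none, min_genes = 5)$selected)
})

test_that("the end-to-end screen recovers a planted cluster and respects min_genes", {
  sim <- simulate_dataset(sim_config(seed = 31))
  scr <- screen_clusters(sim$quant, sim$genes)
  tr <- sim$truth$clusters
  expect_false(is.null(scr$selected))
  expect_equal(scr$selected$contig, tr$contig)
  expect_lte(scr$selected$first_ordinal, tr$last_ordinal)
  expect_gte(scr$selected$last_ordinal, tr$first_ordinal)

  # a 4-gene planted cluster appears as a candidate but is never selected
  cfg4 <- sim_config(planted_clusters = list(planted_cluster(length = 4)),
                     background_dap_rate = 0, dropout_midpoint = -50, seed = 8)
  sim4 <- simulate_dataset(cfg4)
  scr4 <- screen_clusters(sim4$quant, sim4$genes)
  expect_true(nrow(scr4$candidates) >= 1)
  expect_true(all(scr4$candidates$n_genes < 5))
  expect_null(scr4$selected)

  # no DAPs at all -> empty candidate table, nothing selected
  cfg0 <- sim_config(planted_clusters = list(), background_dap_rate = 0,
                     dropout_midpoint = -50, seed = 4)
  sim0 <- simulate_dataset(cfg0)
  scr0 <- screen_clusters(sim0$quant, sim0$genes)
  expect_equal(nrow(scr0$candidates), 0L)
  expect_null(scr0$selected)
})

test_that("raising the planted fold change never demotes the planted cluster", {
  for (seed in c(3, 14, 27)) {
    rank_of <- function(fc_range) {
      cfg <- sim_config(planted_clusters = list(planted_cluster(fc_range = fc_range)),
                        seed = seed)
      sim <- simulate_dataset(cfg)
      scr <- screen_clusters(sim$quant, sim$genes)
      tr <- sim$truth$clusters
      hit <- scr$candidates$contig == tr$contig &
        scr$candidates$first_ordinal <= tr$last_ordinal &
        scr$candidates$last_ordinal >= tr$first_ordinal
      if (!any(hit)) return(Inf)
      min(scr$candidates$rank[hit])
    }
    expect_lte(rank_of(c(40, 80)), rank_of(c(10, 20)))
  }
})

test_that("permuting gene order destroys planted clustering", {
  sim <- simulate_dataset(sim_config(seed = 55))
  planted_genes <- strsplit(sim$truth$clusters$gene_ids, ",")[[1]]
  daps <- call_daps(sim$quant)
  set.seed(100)
  hits <- 0
  for (i in 1:20) {
    g <- sim$genes
    perm <- sample(nrow(g))
    g[, c("gene_id", "protein_id")] <- g[perm, c("gene_id", "protein_id")]
    scr <- screen_clusters(sim$quant, g, daps = daps)
    if (!is.null(scr$selected)) {
      members <- strsplit(scr$selected$gene_ids, ",")[[1]]
      if (length(intersect(members, planted_genes)) >= 5) hits <- hits + 1
    }
  }
  expect_lte(hits, 2)
})

test_that("BED export writes 0-based half-open candidate spans", {
  sim <- simulate_dataset(sim_config(seed = 31))
  scr <- screen_clusters(sim$quant, sim$genes)
  bed <- tempfile(fileext = ".bed")
  write_cluster_bed(scr, bed)
  b <- utils::read.table(bed, sep = "\t")
  expect_equal(nrow(b), nrow(scr$candidates))
  expect_equal(b$V2, scr$candidates$start_bp - 1L)
  expect_equal(b$V3, scr$candidates$end_bp)
})
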