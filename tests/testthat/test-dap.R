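test_that("detection state follows the min-detect-runs rule", {
  p <- dap_params(min_detect_runs = 2)
  cond <- rep(c("IAA", "IAACon"), each = 4)
  expect_equal(detect_state(c(1, 2, 3, 4, NA, NA, NA, NA), cond,
                            "IAA", "IAACon", p),
               c(case = TRUE, control = FALSE))
  expect_equal(detect_state(c(1, NA, NA, NA, 1, 2, 3, 4), cond,
                            "IAA", "IAACon", p),
               c(case = FALSE, control = TRUE))
  expect_equal(detect_state(c(1, 2, NA, NA, NA, NA, 3, 4), cond,
                            "IAA", "IAACon", p),
               c(case = TRUE, control = TRUE))
})

test_that("the two-sided t-test honours its degenerate and symmetry contracts", {
  expect_equal(two_sided_t_test(c(5, 5, 5, 5), c(5, 5, 5, 5)), 1)
  expect_true(is.na(two_sided_t_test(c(5), c(1, 2, 3))))
  set.seed(1)
  for (i in 1:10) {
    x <- 2^rnorm(4, 20); y <- 2^rnorm(4, 20)
    expect_equal(two_sided_t_test(x, y), two_sided_t_test(y, x))
  }
})

test_that("a strong separation is significant and agrees with independent oracles", {
  x <- c(10, 11, 10, 11); y <- c(80, 82, 81, 79)
  p <- two_sided_t_test(x, y)
  expect_lt(p, 0.001)
  # textbook Welch formula on the log2 values
  expect_equal(p, welch_formula_p(log2(x), log2(y)), tolerance = 1e-12)
  # exact permutation test: the observed split is the most extreme of the
  # 70 relabelings (attained twice, by the split and its complement)
  expect_equal(perm_test_p(x, y), 2 / 70, tolerance = 1e-12)
})

test_that("fold change is a reciprocal ratio of linear means", {
  expect_equal(fold_change(40, 10), 4)
  expect_equal(fold_change(7, 7), 1)
  expect_equal(fold_change(3, 11), 1 / fold_change(11, 3))
})

test_that("call_daps assigns exactly one status per protein with correct classes", {
  case <- rbind(c(50, 52, 51, 49),     # identical distribution both sides
                c(400, 410, 390, 405), # strong up
                c(10, 11, 10, 11),     # strong down
                c(30, 31, 29, 30),     # case only
                c(NA, NA, NA, NA),     # control only
                c(NA, 7, NA, NA))      # detected nowhere (1 run < 2)
  ctrl <- rbind(c(50, 52, 51, 49),
                c(100, 102, 99, 101),
                c(100, 102, 99, 101),
                c(NA, NA, NA, NA),
                c(20, 21, 19, 20),
                c(NA, NA, 8, NA))
  q <- toy_quant(case, ctrl)
  d <- call_daps(q)
  st <- as.character(d$records$status)
  expect_equal(st, c("unchanged", "up", "down", "unique_case",
                     "unique_control", "undetected"))
  expect_equal(sum(dap_partition_summary(d)$counts), 6)
  # unique proteins carry the imputed fold change and no p-value
  expect_equal(d$records$fold_change[4], 2)
  expect_equal(d$records$fold_change[5], 0.5)
  expect_true(all(is.na(d$records$p_value[4:6])))
})

test_that("thresholds are inclusive on fold change and strict on p", {
  classify <- proteoscreen:::classify_dap
  p <- dap_params()
  expect_equal(classify(2.0, 0.049, p), "up")
  expect_equal(classify(1.999, 0.049, p), "unchanged")
  expect_equal(classify(2.5, 0.05, p), "unchanged")
  expect_equal(classify(0.5, 0.049, p), "down")
  expect_equal(classify(0.501, 0.049, p), "unchanged")
  expect_equal(classify(4, NA, p), "unchanged")
})

test_that("swapping condition labels reciprocates fold changes and mirrors statuses", {
  sim <- simulate_dataset(sim_config(n_genes = 120, seed = 21))
  a <- call_daps(sim$quant, case = "IAA", control = "IAACon")
  b <- call_daps(sim$quant, case = "IAACon", control = "IAA")
  expect_equal(a$records$fold_change, 1 / b$records$fold_change,
               tolerance = 1e-12)
  expect_equal(a$records$p_value, b$records$p_value, tolerance = 1e-12)
  map <- c(up = "down", down = "up", unchanged = "unchanged",
           unique_case = "unique_control", unique_control = "unique_case",
           undetected = "undetected")
  expect_identical(unname(map[as.character(a$records$status)]),
                   as.character(b$records$status))
})

test_that("status classes always partition the protein universe", {
  for (seed in 1:5) {
    sim <- simulate_dataset(sim_config(n_genes = 80, planted_clusters = list(planted_cluster(start = 5)), seed = seed))
    d <- call_daps(sim$quant)
    expect_equal(sum(d$counts), nrow(sim$quant$abundance))
  }
})

test_that("planted 8-fold effects are recovered with high power and few false calls", {
  # 20 proteins with a true 8-fold case effect (log2 noise sd 0.2) among
  # 80 nulls, 4 vs 4 runs; power and false-call rate over 200 draws
  set.seed(2024)
  n_eff <- 20; n_null <- 80; reps <- 200
  power <- numeric(reps); false_calls <- numeric(reps)
  for (r in seq_len(reps)) {
    lfc <- c(rep(3, n_eff), rep(0, n_null))
    base <- rnorm(n_eff + n_null, 20, 2)
    ca <- 2^(base + lfc + matrix(rnorm(4 * (n_eff + n_null), 0, 0.2),
                                 ncol = 4))
    co <- 2^(base + matrix(rnorm(4 * (n_eff + n_null), 0, 0.2), ncol = 4))
    d <- call_daps(toy_quant(ca, co))
    st <- as.character(d$records$status)
    power[r] <- sum(st[1:n_eff] == "up")
    false_calls[r] <- sum(st[-(1:n_eff)] %in% c("up", "down"))
  }
  expect_gte(mean(power), 18)
  expect_lte(mean(false_calls), 8)
})

test_that("the DAP caller's significant set matches the permutation oracle on sampled draws", {
  set.seed(77)
  agree <- 0
  for (i in 1:40) {
    shift <- sample(c(0, 0.5, 1.5), 1)
    x <- 2^rnorm(4, 20 + shift, 0.4); y <- 2^rnorm(4, 20, 0.4)
    welch_sig <- two_sided_t_test(x, y) < 0.05
    perm_sig <- perm_test_p(x, y) < 0.05
    agree <- agree + (welch_sig == perm_sig)
  }
  expect_gte(agree, 36)
})

test_that("partition summary separates the directional DAP sets", {
  rec <- data.frame(status = c("up", "up", "unique_case", "down", "unchanged"))
  s <- dap_partition_summary(rec)
  expect_equal(s$n_up_set, 3)
  expect_equal(s$n_down_set, 1)
  expect_equal(s$n_proteins, 5)
  all_un <- dap_partition_summary(data.frame(status = rep("unchanged", 4)))
  expect_equal(all_un$n_up_set, 0)
  expect_equal(all_un$n_down_set, 0)
})

test_that("technical-replicate averaging reduces to a 2-vs-2 comparison", {
  case <- rbind(c(400, 410, 390, 405))
  ctrl <- rbind(c(100, 102, 99, 101))
  q <- toy_quant(case, ctrl)
  d <- call_daps(q, dap_params(average_tech_reps = TRUE))
  expect_equal(as.character(d$records$status), "up")
  m_case <- mean(c(mean(c(400, 410)), mean(c(390, 405))))
  expect_equal(d$records$mean_case, m_case)
})
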