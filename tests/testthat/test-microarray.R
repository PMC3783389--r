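test_that("background subtraction clamps at zero and is vectorized", {
  expect_equal(subtract_background(500, 100), 400)
  expect_equal(subtract_background(50, 100), 0)
  expect_equal(subtract_background(c(500, 50, 120), c(100, 100, 100)),
               c(400, 0, 20))
})

test_that("detectability needs 3x background SD and spot CV below 0.5", {
  expect_false(is_detectable(c(60, 80, 100), bg_sd = 30))   # 80 <= 90
  expect_false(is_detectable(c(40, 100, 160), bg_sd = 30))  # CV = 0.6
  expect_true(is_detectable(c(80, 100, 120), bg_sd = 30))   # CV = 0.2
  expect_false(is_detectable(c(0, 0), bg_sd = 1))           # zero mean
})

test_that("log2 ratios reproduce printed two-channel arithmetic", {
  expect_equal(log2_ratio(101, 1192), 3.56, tolerance = 0.01 / 3.56)
  expect_equal(log2_ratio(250, 250), 0)
  expect_equal(log2_ratio(3, 48), -log2_ratio(48, 3))
  expect_error(log2_ratio(0, 10), "positive")
})

test_that("paired t-test matches the textbook formula and conventions", {
  expect_equal(paired_t_test(c(100, 200, 400), c(100, 200, 400)), 1)
  # d = (1.0, 1.2, 0.8, 1.1) on the log2 scale, n = 4, df = 3
  a <- c(100, 100, 100, 100)
  b <- a * 2^c(1.0, 1.2, 0.8, 1.1)
  expect_equal(paired_t_test(a, b), 0.00124392315, tolerance = 1e-8)
  # two-tailed symmetry under channel swap
  expect_equal(paired_t_test(a, b), paired_t_test(b, a))
  # zero-variance nonzero shift degenerates to p = 0
  expect_equal(paired_t_test(a, a * 2), 0)
  expect_error(paired_t_test(1, 2), ">= 2")
})

test_that("LOWESS removes constant dye offsets in the no-signal limit", {
  sim <- sim_microarray(n_probes = 150, n_diff = 0, noise_sd = 0.05,
                        replicates = 2, seed = 61)
  sig <- sim$signals
  offset <- 2^0.8                    # constant channel-B dye gain
  sig$fg[sig$channel == "B"] <- sig$bg_mean[sig$channel == "B"] +
    (sig$fg[sig$channel == "B"] - sig$bg_mean[sig$channel == "B"]) * offset
  a <- sig[sig$channel == "A", ]
  b <- sig[sig$channel == "B", ]
  spots <- merge(a, b, by = c("probe_id", "mirna", "replicate"),
                 suffixes = c("_A", "_B"))
  spots$A <- subtract_background(spots$fg_A, spots$bg_mean_A)
  spots$B <- subtract_background(spots$fg_B, spots$bg_mean_B)
  norm <- lowess_normalize(spots)
  expect_gt(median(norm$M), 0.7)               # offset present before
  expect_lt(median(abs(norm$M_norm)), 0.05)    # gone after
})

test_that("normalization preserves A-values exactly, bias slope removed", {
  sim <- sim_microarray(n_probes = 300, n_diff = 0, noise_sd = 0.15,
                        dye_bias = 0.3, replicates = 3, seed = 62)
  a <- sim$signals[sim$signals$channel == "A", ]
  b <- sim$signals[sim$signals$channel == "B", ]
  spots <- merge(a, b, by = c("probe_id", "mirna", "replicate"),
                 suffixes = c("_A", "_B"))
  spots$A <- subtract_background(spots$fg_A, spots$bg_mean_A)
  spots$B <- subtract_background(spots$fg_B, spots$bg_mean_B)
  spots <- spots[spots$A > 0 & spots$B > 0, ]
  norm <- lowess_normalize(spots)
  A_after <- 0.5 * (log2(norm$A_norm) + log2(norm$B_norm))
  expect_lt(max(abs(A_after - norm$Avalue)), 1e-9)
  expect_identical(order(A_after), order(norm$Avalue))
  pre <- unname(coef(lm(M ~ Avalue, data = norm))[2])
  post <- unname(coef(lm(M_norm ~ Avalue, data = norm))[2])
  expect_gt(abs(pre), 0.2)
  expect_lt(abs(post), 0.02)
  expect_error(lowess_normalize(spots[1:5, ]), "larger f")
})

test_that("differential calls apply thresholds to rounded ratios", {
  tab <- pinellia_leaf_signals()
  res <- data.frame(mirna = tab$name,
                    log2_ratio = log2_ratio(tab$signal_A, tab$signal_B))
  called <- differential_call(res, log2_threshold = 1, mode = "fold_only")
  s <- attr(called, "summary")
  expect_equal(s$n_up, 14L)
  expect_equal(s$n_down, 7L)
  expect_equal(s$n_families, 12L)
  # log2(19234/9629) = 0.9982 rounds to 1.00 and passes a threshold of 1
  expect_equal(called$call[called$mirna == "aqc-miR535"], "UP")
})

test_that("calls swap UP and DOWN under channel relabeling", {
  sim <- sim_microarray(n_probes = 120, n_diff = 20, seed = 63)
  res <- analyze_microarray(sim$signals, 0.05, 1)
  flipped <- sim$signals
  flipped$channel <- ifelse(flipped$channel == "A", "B", "A")
  res_f <- analyze_microarray(flipped, 0.05, 1)
  m <- merge(res[, c("probe_id", "call")], res_f[, c("probe_id", "call")],
             by = "probe_id")
  swap <- c(UP = "DOWN", DOWN = "UP", NS = "NS")
  expect_equal(unname(swap[m$call.x]), m$call.y)
})

test_that("full-mode analysis recovers planted fold changes", {
  sim <- sim_microarray(n_probes = 250, n_diff = 25, log2fc = 2,
                        noise_sd = 0.15, replicates = 3, seed = 64)
  res <- analyze_microarray(sim$signals, p_threshold = 0.05,
                            log2_threshold = 1)
  called <- res$probe_id[res$call != "NS"]
  truthy <- sim$truth$probe_id[sim$truth$true_log2fc != 0]
  sens <- length(intersect(called, truthy)) / length(truthy)
  fdr <- if (length(called)) {
    length(setdiff(called, truthy)) / length(called)
  } else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})
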