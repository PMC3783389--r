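test_that("transcriptome generation is seed-reproducible with correct GC", {
  a <- gen_transcriptome(3, c(100, 200), 0.5, seed = 7)
  b <- gen_transcriptome(3, c(100, 200), 0.5, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, gen_transcriptome(3, c(100, 200), 0.5, 8)))
  expect_true(all(nchar(a$seq) >= 100 & nchar(a$seq) <= 200))

  big <- gen_transcriptome(10, c(1000, 1000), 0.7, seed = 11)
  gc <- sum(vapply(strsplit(big$seq, ""), function(x) {
    sum(x %in% c("G", "C"))
  }, numeric(1))) / 10000
  expect_equal(gc, 0.7, tolerance = 0.03 / 0.7)
  expect_error(gen_transcriptome(1, c(100, 100), gc = 1.2, seed = 1),
               "gc")
})

test_that("generator seeding does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(1)
  set.seed(123)
  invisible(gen_transcriptome(1, c(50, 50), 0.5, seed = 99))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("implanted sites round trip through the site finder", {
  mir <- "UGACAGAAGAGAGUGAGCAC"
  tx <- gen_transcriptome(1, c(300, 300), 0.5, seed = 17)
  imp <- implant_site(tx, mir, 150)
  expect_equal(imp$score, 0)
  hit <- find_sites(mir, imp$transcript)
  expect_equal(hit$start, 150L)
  expect_equal(hit$end, 169L)

  gu <- implant_site(tx, mir, 150,
                     data.frame(mirna_pos = 14L, type = "GU"))
  expect_equal(gu$score, 0.5)
  expect_equal(find_sites(mir, gu$transcript)$score, 0.5)

  expect_error(implant_site(tx, mir, 150,
                            data.frame(mirna_pos = 10L,
                                       type = "BULGE_MIRNA")),
               "9-12")
  expect_error(implant_site(tx, mir, 295), "fit")
})

test_that("randomized implants are reported exactly when score <= cutoff", {
  mir <- "UGACAGAAGAGAGUGAGCAC"
  gu_positions <- which(strsplit(mir, "")[[1]] %in% c("G", "U"))
  set.seed(811)
  n_reported <- 0L
  n_exact <- 0L
  for (k in 1:12) {
    tx <- gen_transcriptome(1, c(260, 260), 0.5, seed = 2000 + k)
    n_mm <- sample(0:3, 1)
    n_gu <- sample(0:2, 1)
    mm_pos <- sample(setdiff(2:20, 9:12), n_mm)
    gu_pos <- sample(setdiff(gu_positions, c(mm_pos, 9:12)), n_gu)
    edits <- rbind(
      if (n_mm) data.frame(mirna_pos = mm_pos, type = "MISMATCH"),
      if (n_gu) data.frame(mirna_pos = gu_pos, type = "GU"))
    imp <- implant_site(tx, mir, 100, edits)
    hit <- find_sites(mir, imp$transcript)
    row <- hit[hit$start == 100, ]
    if (imp$score <= 4) {
      n_reported <- n_reported + 1L
      expect_equal(nrow(row), 1L)
      # the designed pairing bounds the minimal-penalty alignment from
      # above; the finder may explain the same site more cheaply
      expect_lte(row$score, imp$score)
      if (row$score == imp$score) n_exact <- n_exact + 1L
    } else {
      expect_true(nrow(row) == 0L || row$score < imp$score)
    }
  }
  expect_gt(n_reported, 0L)
  expect_gt(n_exact, n_reported / 2)   # re-alignment gains are rare
})

test_that("degradome simulation respects signal and background settings", {
  set <- make_planted_set(4, seed = 51)
  clean <- sim_degradome(set$transcripts, set$truth, reads_per_site = 5,
                         background_rate = 0, seed = 52)
  prof <- map_tags(clean$tags, set$transcripts)
  expect_setequal(prof$pos, set$truth$cleavage_site)
  expect_true(all(prof$count == 5))

  bg_only <- sim_degradome(set$transcripts, set$truth,
                           reads_per_site = 0, background_rate = 0.05,
                           seed = 53)
  expect_true(all(bg_only$tags$count >= 1))
  expect_gt(nrow(bg_only$tags), 0)

  # total tag count ~ sites x reads + Poisson background, within 3 sigma
  both <- sim_degradome(set$transcripts, set$truth, reads_per_site = 20,
                        background_rate = 0.02, seed = 54)
  lambda <- 0.02 * sum(nchar(set$transcripts$seq))
  total <- sum(both$tags$count)
  signal <- 20 * nrow(set$truth)
  expect_lt(abs(total - signal - lambda), 3 * sqrt(lambda))
})

test_that("noiseless microarray simulation gives exact ratios", {
  null <- sim_microarray(n_probes = 20, n_diff = 0, noise_sd = 0,
                         replicates = 2, seed = 71)
  a <- null$signals[null$signals$channel == "A", ]
  b <- null$signals[null$signals$channel == "B", ]
  sp <- merge(a, b, by = c("probe_id", "replicate"),
              suffixes = c("_A", "_B"))
  r <- log2((sp$fg_B - sp$bg_mean_B) / (sp$fg_A - sp$bg_mean_A))
  expect_equal(r, rep(0, nrow(sp)), tolerance = 1e-12)

  fc <- sim_microarray(n_probes = 20, n_diff = 20, log2fc = 2,
                       noise_sd = 0, replicates = 2, seed = 72)
  a <- fc$signals[fc$signals$channel == "A", ]
  b <- fc$signals[fc$signals$channel == "B", ]
  sp <- merge(a, b, by = c("probe_id", "replicate"),
              suffixes = c("_A", "_B"))
  r <- log2((sp$fg_B - sp$bg_mean_B) / (sp$fg_A - sp$bg_mean_A))
  truth <- fc$truth$true_log2fc[match(sp$probe_id, fc$truth$probe_id)]
  expect_equal(r, truth, tolerance = 1e-12)
})

test_that("noiseless qPCR simulation encodes exact ratios", {
  one <- sim_qpcr(c(x = 1), noise_sd = 0, seed = 81)
  out1 <- summarize_replicates(one$ct, one$design)
  expect_equal(out1$ddct, 0)
  expect_equal(out1$ratio, 1)

  eight <- sim_qpcr(c(x = 8), noise_sd = 0, seed = 82)
  expect_equal(summarize_replicates(eight$ct, eight$design)$ratio, 8)
})
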