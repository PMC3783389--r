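test_that("base-pair classification follows Watson-Crick plus G:U wobble", {
  expect_equal(classify_pair("A", "U"), "MATCH")
  expect_equal(classify_pair("C", "G"), "MATCH")
  expect_equal(classify_pair("G", "U"), "GU")
  expect_equal(classify_pair("U", "G"), "GU")
  expect_equal(classify_pair("A", "G"), "MISMATCH")
  expect_equal(classify_pair("N", "A"), "MISMATCH")
  expect_equal(classify_pair(c("A", "G"), c("U", "U")),
               c("MATCH", "GU"))
})

test_that("pairing scores follow the weighted penalty table", {
  perfect <- pairing_map(rep("MATCH", 21), 1:21, 500:480)
  expect_equal(score_pairing(perfect), 0)

  one_gu <- pairing_map(c(rep("MATCH", 19), "GU", "MATCH"),
                        1:21, 500:480)
  expect_equal(score_pairing(one_gu), 0.5)   # position 20, outside core

  core_mm <- pairing_map(replace(rep("MATCH", 21), 5, "MISMATCH"),
                         1:21, 500:480)
  expect_equal(score_pairing(core_mm), 2)    # position 5, doubled

  core_gu <- pairing_map(replace(rep("MATCH", 21), 13, "GU"),
                         1:21, 500:480)
  expect_equal(score_pairing(core_gu), 1)    # 0.5 doubled at position 13
})

test_that("random pairings score identically to the summation oracle", {
  set.seed(401)
  for (rep in 1:200) {
    pm <- random_pairing(sample(19:24, 1))
    expect_equal(score_pairing(pm), oracle_score(pm$state, pm$mirna_pos))
  }
})

test_that("invalid pairings are rejected", {
  expect_error(pairing_map(rep("MATCH", 3), c(1, 1, 3), c(10, 9, 8)),
               "exactly once")
  expect_error(pairing_map(rep("MATCH", 3), 1:3, c(10, 8, 7)),
               "contiguous")
  expect_error(pairing_map(c("MATCH", "WOBBLE"), 1:2, c(10, 9)),
               "state")
})

test_that("cleavage position is the base paired to miRNA nucleotide 10", {
  ungapped <- function(L, end) {
    pairing_map(rep("MATCH", L), 1:L, seq(end, end - L + 1))
  }
  expect_equal(expected_cleavage_position(ungapped(21, 1011)), 1002L)
  expect_equal(expected_cleavage_position(ungapped(20, 692)), 683L)
  expect_equal(expected_cleavage_position(ungapped(20, 20)), 11L)
})

test_that("find_sites recovers exact and near-exact complements", {
  mir <- "UGACAGAAGAGAGUGAGCAC"
  tx <- gen_transcriptome(1, c(250, 250), 0.5, seed = 31)
  imp <- implant_site(tx, mir, position = 101)
  hit <- find_sites(mir, imp$transcript)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$score, 0)
  expect_equal(hit$start, 101L)
  expect_equal(hit$end, 120L)
  expect_equal(hit$end - hit$start + 1L, nchar(mir))
  expect_equal(hit$cleavage_site, hit$end - 9L)

  # non-wobble substitution opposite miRNA position 15 (outside core)
  imp2 <- implant_site(tx, mir, position = 101,
                       edits = data.frame(mirna_pos = 15L,
                                          type = "MISMATCH"))
  hit2 <- find_sites(mir, imp2$transcript)
  expect_equal(hit2$score, 1)
})

test_that("find_sites equals exhaustive enumeration on random transcripts", {
  mir <- "UGACAGAAGAGAGUGAGCAC"
  edit_pool <- c("MISMATCH", "GU", "BULGE_TARGET", "BULGE_MIRNA")
  set.seed(402)
  for (k in 1:6) {
    tx <- gen_transcriptome(1, c(300, 300), 0.5, seed = 500 + k)
    n_edits <- sample(0:3, 1)
    edits <- NULL
    if (n_edits > 0) {
      pos <- sort(sample(setdiff(2:20, 9:12), n_edits))
      type <- sample(edit_pool, n_edits, replace = TRUE)
      gu_ok <- substring(mir, pos, pos) %in% c("G", "U")
      type[type == "GU" & !gu_ok] <- "MISMATCH"
      bulges <- which(type %in% c("BULGE_TARGET", "BULGE_MIRNA"))
      if (length(bulges) > 1) type[bulges[-1]] <- "MISMATCH"
      edits <- data.frame(mirna_pos = pos, type = type)
    }
    imp <- implant_site(tx, mir, position = 120, edits = edits)
    got <- find_sites(mir, imp$transcript)
    want <- oracle_find_sites(mir, imp$transcript$seq)
    got_cmp <- data.frame(start = got$start, end = got$end,
                          score = got$score, nbulges = got$n_bulges)
    expect_equal(got_cmp, want, ignore_attr = TRUE)
    if (imp$score <= 4) {
      row <- got[got$start == imp$start, ]
      expect_equal(row$score, imp$score)
      expect_equal(row$cleavage_site, imp$cleavage_site)
    }
  }
})

test_that("site scores are context-invariant and ranges span L-1..L+1", {
  mir <- "UGACAGAAGAGAGUGAGCAC"
  edits <- data.frame(mirna_pos = c(3L, 16L),
                      type = c("MISMATCH", "BULGE_TARGET"))
  scores <- vapply(1:4, function(k) {
    tx <- gen_transcriptome(1, c(280, 280), 0.4 + 0.1 * (k %% 2),
                            seed = 700 + k)
    imp <- implant_site(tx, mir, position = 90, edits = edits)
    hit <- find_sites(mir, imp$transcript)
    L <- nchar(mir)
    expect_true(all(hit$end - hit$start + 1L %in% (L - 1L):(L + 1L)))
    hit$score[hit$start == 90]
  }, numeric(1))
  expect_true(all(scores == scores[1]))
})

test_that("adding a mispair never decreases the score", {
  mir <- "UGACAGAAGAGAGUGAGCAC"
  tx <- gen_transcriptome(1, c(260, 260), 0.5, seed = 77)
  base_edits <- data.frame(mirna_pos = 18L, type = "MISMATCH")
  base <- implant_site(tx, mir, 80, base_edits)$score
  for (extra in c(2L, 7L, 15L)) {
    more <- rbind(base_edits,
                  data.frame(mirna_pos = extra, type = "MISMATCH"))
    expect_gte(implant_site(tx, mir, 80, more)$score, base)
  }
})

test_that("predict_targets filters by cutoff and orders deterministically", {
  mir <- seq_records("osa-miR156", "UGACAGAAGAGAGUGAGCAC")
  empty <- predict_targets(mir[0, ], gen_transcriptome(1, c(100, 100),
                                                       0.5, 1))
  expect_equal(nrow(empty), 0L)

  # planted sites of score 0, 2, 3.5, 4.5: cutoff 4 admits the first three
  specs <- list(
    NULL,
    data.frame(mirna_pos = 5L, type = "MISMATCH"),
    data.frame(mirna_pos = c(5L, 6L, 14L),
               type = c("MISMATCH", "GU", "GU")),
    data.frame(mirna_pos = c(5L, 6L, 15L),
               type = c("MISMATCH", "MISMATCH", "GU"))
  )
  tx <- gen_transcriptome(4, c(300, 300), 0.5, seed = 55)
  expected_scores <- numeric(4)
  for (i in 1:4) {
    imp <- implant_site(tx[i, ], mir, 100, specs[[i]])
    tx[i, ] <- imp$transcript
    expected_scores[i] <- imp$score
  }
  expect_equal(expected_scores, c(0, 2, 3.5, 4.5))
  tab <- predict_targets(mir, tx)
  expect_equal(tab$transcript_id, c("tx0001", "tx0002", "tx0003"))
  expect_equal(tab$score, c(0, 2, 3.5))
  expect_equal(tab$mirna_family, rep("miR156", 3))
  expect_true(all(tab$start <= tab$cleavage_site &
                    tab$cleavage_site <= tab$end))

  dup <- rbind(mir, mir)
  expect_error(predict_targets(dup, tx), "duplicate")
})
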