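# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stage-specific streams derived from one pipeline seed; offsets keep the
# derived seeds distinct and below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(transcriptome = 101L, targets = 211L, degradome = 307L,
               microarray = 401L, qpcr = 503L)
  (as.integer(seed) %% 2000000000L) + offsets[[stage]]
}

#' Reverse complement in the RNA alphabet
#'
#' @param seq character vector of residues over `{A,C,G,U,N}`.
#' @return Reverse complement(s), RNA alphabet.
#' @export
revcomp_rna <- function(seq) {
  comp <- chartr("ACGUN", "UGCAN", toupper(seq))
  vapply(strsplit(comp, "", fixed = TRUE), function(x) {
    paste(rev(x), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic transcriptome
#'
#' Seeded i.i.d. sequences with a controlled GC content: lengths uniform
#' in `length_range`, residues drawn with P(G) = P(C) = gc/2. The same
#' seed and parameters reproduce identical records byte for byte.
#'
#' @param n number of transcripts.
#' @param length_range inclusive length bounds, e.g. `c(500, 1500)`.
#' @param gc GC fraction in (0, 1) (default 0.5).
#' @param seed RNG seed.
#' @return A sequence record data frame (ids `tx0001`, ...).
#' @export
gen_transcriptome <- function(n, length_range = c(500L, 1500L), gc = 0.5,
                              seed = 1L) {
  stopifnot(n >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L], length_range[1L] >= 1L)
  if (!(gc > 0 && gc < 1)) stop("gc must be strictly between 0 and 1")
  with_seed(seed, {
    lens <- length_range[1L] +
      sample.int(length_range[2L] - length_range[1L] + 1L, n,
                 replace = TRUE) - 1L
    prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(prob), L, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1))
    seq_records(sprintf("tx%04d", seq_len(n)), seqs,
                desc = "synthetic transcript")
  })
}

edit_types <- c("MISMATCH", "GU", "BULGE_TARGET", "BULGE_MIRNA")

# Deterministic residue choice realizing a requested pair state.
mismatch_residue <- function(mirna_nt) {
  for (nt in c("A", "C", "G", "U")) {
    if (classify_pair(mirna_nt, nt) == "MISMATCH") return(nt)
  }
}

#' Implant a miRNA target site into a transcript
#'
#' Writes the reverse complement of the miRNA into the transcript starting
#' at `position`, then applies edits so the realized pairing has exactly
#' the requested states; the expected penalty score and cleavage position
#' are computed from the realized pairing map, so they are guaranteed
#' consistent with what [find_sites()] will evaluate.
#'
#' @param transcript single sequence record.
#' @param mirna single sequence record or bare string (19-24 nt).
#' @param position transcript start of the site (1-based).
#' @param edits optional data frame with columns `mirna_pos` and `type`
#'   over `MISMATCH`, `GU`, `BULGE_TARGET`, `BULGE_MIRNA`; at most one
#'   bulge, never at miRNA positions 9-12 (the cleavage region must
#'   pair). `GU` requires a G or U miRNA residue.
#' @param scheme [scoring_scheme()] used for the expected score.
#' @return A list: `transcript` (modified record), `score`, `start`,
#'   `end`, `cleavage_site`, `pairing`.
#' @export
implant_site <- function(transcript, mirna, position, edits = NULL,
                         scheme = scoring_scheme()) {
  tr <- as_single_record(transcript, "transcript")
  m <- as_single_record(mirna, "mirna")
  L <- nchar(m$seq)
  mir_res <- res_alphabet[res_index(m$seq)]
  if (is.null(edits)) {
    edits <- data.frame(mirna_pos = integer(), type = character())
  }
  stopifnot(all(edits$type %in% edit_types),
            all(edits$mirna_pos >= 1L), all(edits$mirna_pos <= L),
            !anyDuplicated(edits$mirna_pos))
  is_bulge <- edits$type %in% c("BULGE_TARGET", "BULGE_MIRNA")
  if (sum(is_bulge) > 1L) stop("at most one bulge per implanted site")
  if (any(is_bulge & edits$mirna_pos %in% 9:12)) {
    stop("bulges are disallowed opposite miRNA positions 9-12")
  }

  # build the site along the miRNA (transcript-descending), then reverse
  chars <- character(0)
  for (i in seq_len(L)) {
    ed <- edits$type[edits$mirna_pos == i]
    if (length(ed) && ed == "BULGE_TARGET") {
      chars <- c(chars, mismatch_residue(mir_res[i]))   # inserted nt
      ed <- character(0)
    }
    nt <- if (!length(ed)) {
      chartr("ACGU", "UGCA", mir_res[i])
    } else if (ed == "MISMATCH") {
      mismatch_residue(mir_res[i])
    } else if (ed == "GU") {
      if (mir_res[i] == "G") "U"
      else if (mir_res[i] == "U") "G"
      else stop("GU edit requires a G or U miRNA residue at position ", i)
    } else if (ed == "BULGE_MIRNA") {
      NULL
    }
    chars <- c(chars, nt)
  }
  site <- paste(rev(chars), collapse = "")
  span <- nchar(site)
  end <- position + span - 1L
  if (position < 1L || end > nchar(tr$seq)) {
    stop("site [", position, ", ", end, "] does not fit in transcript ",
         tr$id)
  }
  seq <- tr$seq
  substr(seq, position, end) <- site
  tr$seq <- seq

  bulge <- edits[is_bulge, , drop = FALSE]
  combo <- if (!nrow(bulge)) {
    list(type = "ungapped", b = NA_integer_, off = 0:(L - 1L), span = L,
         nbulges = 0L)
  } else if (bulge$type == "BULGE_MIRNA") {
    off <- ifelse(seq_len(L) < bulge$mirna_pos, seq_len(L) - 1L,
                  seq_len(L) - 2L)
    off[bulge$mirna_pos] <- NA_integer_
    list(type = "bulge_mirna", b = bulge$mirna_pos, off = off,
         span = L - 1L, nbulges = 1L)
  } else {
    off <- ifelse(seq_len(L) < bulge$mirna_pos, seq_len(L) - 1L,
                  seq_len(L))
    list(type = "bulge_target", b = bulge$mirna_pos, off = off,
         span = L + 1L, nbulges = 1L)
  }
  tgt_res <- res_alphabet[res_index(tr$seq)]
  pairing <- build_pairing(combo, end, mir_res, tgt_res)
  list(transcript = tr,
       score = score_pairing(pairing, scheme),
       start = as.integer(position), end = as.integer(end),
       cleavage_site = expected_cleavage_position(pairing),
       pairing = pairing)
}

#' Simulate a degradome tag library
#'
#' For each truth site, emits a signal tag whose 5' end sits exactly at
#' the expected cleavage position with abundance `reads_per_site`;
#' uniform background tags are added per transcript with
#' Poisson(`background_rate` x length) counts of single-copy tags. Tags
#' running past the transcript end are shortened and flagged.
#'
#' @param transcripts sequence record data frame.
#' @param truth_sites data frame with `transcript_id` and
#'   `cleavage_site`.
#' @param reads_per_site signal abundance per planted site (default 20).
#' @param background_rate background tag 5' ends per nucleotide (default
#'   0.01).
#' @param tag_length tag length in nt (default 20).
#' @param seed RNG seed.
#' @return A list: `tags` (data frame `seq`, `count`), `truth` (the truth
#'   sites with the emitted signal count), `truncated` (number of
#'   shortened tags).
#' @export
sim_degradome <- function(transcripts, truth_sites, reads_per_site = 20L,
                          background_rate = 0.01, tag_length = 20L,
                          seed = 1L) {
  stopifnot(reads_per_site >= 0L, background_rate >= 0, tag_length >= 1L)
  with_seed(seed, {
    seqs <- stats::setNames(transcripts$seq, transcripts$id)
    truncated <- 0L
    take_tag <- function(tid, pos) {
      L <- nchar(seqs[[tid]])
      end <- pos + tag_length - 1L
      if (end > L) {
        truncated <<- truncated + 1L
        end <- L
      }
      substr(seqs[[tid]], pos, end)
    }
    rows <- list()
    if (reads_per_site > 0L && nrow(truth_sites)) {
      for (i in seq_len(nrow(truth_sites))) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq = take_tag(truth_sites$transcript_id[i],
                         truth_sites$cleavage_site[i]),
          count = as.integer(reads_per_site), stringsAsFactors = FALSE)
      }
    }
    for (tid in transcripts$id) {
      L <- nchar(seqs[[tid]])
      n_bg <- stats::rpois(1L, background_rate * L)
      if (n_bg == 0L) next
      pos <- sample.int(L, n_bg, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        seq = vapply(pos, function(p) take_tag(tid, p), character(1)),
        count = 1L, stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      long <- do.call(rbind, rows)
      agg <- rowsum(long$count, long$seq)
      tags <- data.frame(seq = rownames(agg),
                         count = as.integer(agg[, 1L]),
                         row.names = NULL, stringsAsFactors = FALSE)
    } else {
      tags <- data.frame(seq = character(), count = integer())
    }
    truth <- truth_sites
    truth$signal_reads <- as.integer(reads_per_site)
    list(tags = tags, truth = truth, truncated = truncated)
  })
}

#' Simulate a two-channel microarray signal table
#'
#' Base probe intensities are log-normal; channel B equals channel A
#' scaled by the planted fold change, an intensity-dependent dye bias
#' (linear in the underlying log2 intensity with slope `dye_bias`), and
#' multiplicative log-normal spot noise. Replicate spots share the truth
#' and differ only by noise; each spot carries its own background mean.
#'
#' @param n_probes number of probes (default 500).
#' @param n_diff number of differential probes (default 50), planted with
#'   alternating +/- `log2fc`.
#' @param log2fc absolute planted log2 fold change (default 2).
#' @param noise_sd spot noise SD on the log2 scale (default 0.15).
#' @param dye_bias slope of the dye bias per log2-intensity unit
#'   (default 0).
#' @param replicates replicate spots per probe (default 3).
#' @param bg_mean,bg_sd background level and its reported SD (defaults
#'   40 and 8).
#' @param seed RNG seed.
#' @return A list: `signals` (spot-level signal table, see
#'   [read_signal_table()]) and `truth` (probe, miRNA name, true log2FC).
#' @export
sim_microarray <- function(n_probes = 500L, n_diff = 50L, log2fc = 2,
                           noise_sd = 0.15, dye_bias = 0,
                           replicates = 3L, bg_mean = 40, bg_sd = 8,
                           seed = 1L) {
  stopifnot(n_diff <= n_probes, replicates >= 2L, noise_sd >= 0,
            bg_mean >= 0, bg_sd >= 0)
  with_seed(seed, {
    probe_id <- sprintf("probe%04d", seq_len(n_probes))
    mirna <- sprintf("syn-miR%04d", seq_len(n_probes))
    base <- stats::rlnorm(n_probes, meanlog = log(800), sdlog = 1)
    fc <- numeric(n_probes)
    if (n_diff > 0L) {
      fc[seq_len(n_diff)] <- rep_len(c(log2fc, -log2fc), n_diff)
    }
    bias <- dye_bias * (log2(base) - mean(log2(base)))
    rows <- list()
    for (r in seq_len(replicates)) {
      noise_a <- 2^stats::rnorm(n_probes, 0, noise_sd)
      noise_b <- 2^stats::rnorm(n_probes, 0, noise_sd)
      bg_a <- pmax(stats::rnorm(n_probes, bg_mean, bg_sd / 4), 0)
      bg_b <- pmax(stats::rnorm(n_probes, bg_mean, bg_sd / 4), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = probe_id, mirna = mirna, channel = "A",
        replicate = r, fg = base * noise_a + bg_a, bg_mean = bg_a,
        bg_sd = bg_sd, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = probe_id, mirna = mirna, channel = "B",
        replicate = r, fg = base * 2^(fc + bias) * noise_b + bg_b,
        bg_mean = bg_b, bg_sd = bg_sd, stringsAsFactors = FALSE)
    }
    signals <- do.call(rbind, rows)
    rownames(signals) <- NULL
    list(signals = signals,
         truth = data.frame(probe_id = probe_id, mirna = mirna,
                            true_log2fc = fc, stringsAsFactors = FALSE))
  })
}

#' Simulate a qPCR Ct table
#'
#' Generates triplicate-style Ct values for a test and a calibrator
#' sample around known expression ratios: the test sample's target Ct is
#' lowered by log2(ratio) cycles relative to the calibrator, both
#' normalized against a shared reference assay.
#'
#' @param true_ratios named numeric vector of true test/calibrator
#'   expression ratios (> 0), names are assay ids.
#' @param ct_ref reference-assay Ct level (default 15).
#' @param dct_calibrator calibrator delta-Ct of every target (default 5).
#' @param noise_sd per-measurement Ct noise SD in cycles (default 0.05).
#' @param replicates independent replicate experiments (default 3).
#' @param reference_assay reference assay id (default `"5.8S"`).
#' @param seed RNG seed.
#' @return A list: `ct` (Ct table, see [read_ct_table()]), `truth`
#'   (assay, true ratio), `design` (ready for
#'   [summarize_replicates()]).
#' @export
sim_qpcr <- function(true_ratios, ct_ref = 15, dct_calibrator = 5,
                     noise_sd = 0.05, replicates = 3L,
                     reference_assay = "5.8S", seed = 1L) {
  stopifnot(all(true_ratios > 0), !is.null(names(true_ratios)),
            replicates >= 1L, noise_sd >= 0)
  with_seed(seed, {
    rows <- list()
    jitter <- function() stats::rnorm(1L, 0, noise_sd)
    for (e in seq_len(replicates)) {
      for (s in c("test", "calibrator")) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, assay = reference_assay, experiment = e,
          ct = ct_ref + jitter(), stringsAsFactors = FALSE)
      }
      for (a in names(true_ratios)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = "calibrator", assay = a, experiment = e,
          ct = ct_ref + dct_calibrator + jitter(),
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = "test", assay = a, experiment = e,
          ct = ct_ref + dct_calibrator - log2(true_ratios[[a]]) +
            jitter(), stringsAsFactors = FALSE)
      }
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
    list(ct = ct,
         truth = data.frame(assay = names(true_ratios),
                            true_ratio = unname(true_ratios),
                            stringsAsFactors = FALSE),
         design = list(test_sample = "test",
                       calibrator_sample = "calibrator",
                       reference_assay = reference_assay))
  })
}
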