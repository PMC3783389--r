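#' Background-correct foreground signals
#'
#' Subtracts the spot background mean from the foreground, clamping at
#' zero so that negative intensities never enter downstream log ratios.
#'
#' @param fg foreground signal(s).
#' @param bg_mean background mean(s).
#' @return Corrected signal(s), elementwise `max(fg - bg_mean, 0)`.
#' @export
subtract_background <- function(fg, bg_mean) {
  stopifnot(all(is.finite(fg)), all(is.finite(bg_mean)))
  pmax(fg - bg_mean, 0)
}

#' Detectability filter for one probe in one channel
#'
#' A signal is accepted as detectable when (1) the mean background-
#' corrected intensity exceeds three times the background standard
#' deviation, and (2) the spot CV (replicate SD / replicate mean) is below
#' `cv_max`. A zero mean (all spots clamped) has an undefined CV and is
#' not detectable.
#'
#' @param corrected background-corrected replicate signals (>= 2 spots).
#' @param bg_sd background standard deviation.
#' @param cv_max CV threshold (default 0.5).
#' @return `TRUE` or `FALSE`.
#' @export
is_detectable <- function(corrected, bg_sd, cv_max = 0.5) {
  stopifnot(length(corrected) >= 2L, is.finite(bg_sd))
  m <- mean(corrected)
  if (m <= 0) return(FALSE)
  m > 3 * bg_sd && stats::sd(corrected) / m < cv_max
}

#' Log2 expression ratio
#'
#' @param signal_A,signal_B positive channel intensities.
#' @return `log2(signal_B / signal_A)`.
#' @export
log2_ratio <- function(signal_A, signal_B) {
  if (any(signal_A <= 0) || any(signal_B <= 0)) {
    stop("log2 ratio requires positive signals")
  }
  log2(signal_B / signal_A)
}

# Round half away from zero to `digits` decimals (printed-table
# semantics; base round() rounds half to even).
round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Paired two-tailed t-test on spotwise log ratios
#'
#' Computes `d = log2(B) - log2(A)` per replicate spot pair and tests
#' `mean(d) = 0` against the t distribution with `n - 1` degrees of
#' freedom. When the differences have zero variance the test degenerates:
#' p = 1 if the mean difference is zero, else p = 0.
#'
#' @param channel_A,channel_B positive replicate intensities, paired by
#'   spot, `n >= 2`.
#' @return Two-tailed p-value.
#' @export
paired_t_test <- function(channel_A, channel_B) {
  n <- length(channel_A)
  if (n < 2L || length(channel_B) != n) {
    stop("paired t-test needs >= 2 paired replicates")
  }
  if (any(channel_A <= 0) || any(channel_B <= 0)) {
    stop("paired t-test requires positive signals")
  }
  d <- log2(channel_B) - log2(channel_A)
  s <- stats::sd(d)
  if (s == 0) return(if (mean(d) == 0) 1 else 0)
  t <- mean(d) / (s / sqrt(n))
  2 * stats::pt(-abs(t), df = n - 1L)
}

#' LOWESS dye-bias normalization in MA space
#'
#' Computes `M = log2(B/A)` and `A-value = (log2(A) + log2(B)) / 2` per
#' spot, fits the intensity-dependent dye bias by locally weighted
#' regression of M on the A-value (tricube weights with bisquare
#' robustifying iterations), and subtracts the fitted curve. Channel
#' intensities are rescaled so each spot keeps its A-value exactly while
#' realizing the normalized ratio.
#'
#' @param spots data frame with positive columns `A` and `B`
#'   (background-corrected spot intensities).
#' @param span LOWESS span f (default 0.4).
#' @param iter robustifying iterations (default 3).
#' @return `spots` with added columns `M`, `Avalue`, `bias`, `M_norm`,
#'   `A_norm`, `B_norm`; the lowess fit is attached as attribute `fit`.
#' @export
lowess_normalize <- function(spots, span = 0.4, iter = 3L) {
  stopifnot(is.data.frame(spots), all(c("A", "B") %in% names(spots)))
  if (any(spots$A <= 0) || any(spots$B <= 0)) {
    stop("normalization requires positive corrected intensities")
  }
  n <- nrow(spots)
  if (n < 10L || floor(span * n) < 3L) {
    stop("too few spots (", n, ") for LOWESS span f = ", span,
         "; use a larger f")
  }
  M <- log2(spots$B / spots$A)
  Avalue <- 0.5 * (log2(spots$A) + log2(spots$B))
  fit <- stats::lowess(Avalue, M, f = span, iter = iter)
  bias <- stats::approx(fit$x, fit$y, xout = Avalue, rule = 2,
                        ties = mean)$y
  spots$M <- M
  spots$Avalue <- Avalue
  spots$bias <- bias
  spots$M_norm <- M - bias
  spots$A_norm <- 2^(Avalue - spots$M_norm / 2)
  spots$B_norm <- 2^(Avalue + spots$M_norm / 2)
  attr(spots, "fit") <- fit
  spots
}

#' Named microarray threshold presets
#'
#' `"strict_fold"`: p < 0.05 with a threefold change (log2 threshold
#' log2(3)). `"unit_log2"`: p < 0.01 with |log2 ratio| >= 1.
#'
#' @param name preset name.
#' @return List with `p_threshold` and `log2_threshold`.
#' @export
threshold_preset <- function(name = c("strict_fold", "unit_log2")) {
  switch(match.arg(name),
         strict_fold = list(p_threshold = 0.05, log2_threshold = log2(3)),
         unit_log2 = list(p_threshold = 0.01, log2_threshold = 1))
}

#' Differential expression calls
#'
#' Calls `UP` when the 2-decimal rounded log2 ratio meets
#' `+log2_threshold` (and, in `full` mode, p is below `p_threshold`),
#' `DOWN` symmetrically, `NS` otherwise. Thresholds are applied to
#' rounded ratios so printed-table semantics are reproducible (a printed
#' 1.00 passes a threshold of 1). `fold_only` mode ignores p-values, for
#' summary tables carrying no replicate detail.
#'
#' @param results data frame with columns `mirna`, `log2_ratio` and (for
#'   `full` mode) `p_value`.
#' @param p_threshold,log2_threshold call thresholds.
#' @param mode `"full"` or `"fold_only"`.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching raw-p practice; e.g. `"BH"`).
#' @return `results` with added `call` column; summary counts (`n_up`,
#'   `n_down`, `n_families`) as attribute `summary`.
#' @export
differential_call <- function(results, p_threshold = 0.05,
                              log2_threshold = log2(3),
                              mode = c("full", "fold_only"),
                              adjust = "none") {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(results),
            all(c("mirna", "log2_ratio") %in% names(results)))
  r <- round_half_away(results$log2_ratio, 2L)
  if (mode == "full") {
    p <- stats::p.adjust(results$p_value, method = adjust)
    sig <- is.finite(p) & p < p_threshold
  } else {
    sig <- TRUE
  }
  call <- ifelse(sig & r >= log2_threshold, "UP",
                 ifelse(sig & r <= -log2_threshold, "DOWN", "NS"))
  results$call <- call
  de <- call != "NS"
  attr(results, "summary") <- list(
    n_up = sum(call == "UP"),
    n_down = sum(call == "DOWN"),
    n_families = length(unique(mirna_family(results$mirna[de]))))
  results
}

#' Full two-channel differential expression analysis
#'
#' Pipeline over a spot-level signal table: background subtraction,
#' per-channel detectability filtering, LOWESS dye-bias normalization in
#' MA space, probe-level log2 ratios, paired two-tailed t-tests across
#' replicate spots, and differential calls.
#'
#' @param signals signal table (see [read_signal_table()]).
#' @param p_threshold,log2_threshold call thresholds; see
#'   [threshold_preset()] for the named pairs.
#' @param mode `"full"` (p-value and fold) or `"fold_only"`.
#' @param span,iter LOWESS parameters (see [lowess_normalize()]).
#' @param normalize set `FALSE` to skip dye-bias normalization.
#' @param adjust p-value adjustment method (default `"none"`).
#' @return A data frame of differential results: `mirna`, `probe_id`,
#'   `signal_A`, `signal_B`, `log2_ratio`, `p_value`, `call`; summary
#'   counts as attribute `summary`.
#' @export
analyze_microarray <- function(signals, p_threshold = 0.05,
                               log2_threshold = log2(3),
                               mode = c("full", "fold_only"),
                               span = 0.4, iter = 3L, normalize = TRUE,
                               adjust = "none") {
  mode <- match.arg(mode)
  a <- signals[signals$channel == "A", ]
  b <- signals[signals$channel == "B", ]
  spots <- merge(a, b, by = c("probe_id", "mirna", "replicate"),
                 suffixes = c("_A", "_B"))
  spots$A <- subtract_background(spots$fg_A, spots$bg_mean_A)
  spots$B <- subtract_background(spots$fg_B, spots$bg_mean_B)
  spots <- spots[order(spots$probe_id, spots$replicate), ]

  # probe-level filter: detectable in both channels, all spots positive
  keep <- vapply(split(seq_len(nrow(spots)), spots$probe_id), function(i) {
    is_detectable(spots$A[i], mean(spots$bg_sd_A[i])) &&
      is_detectable(spots$B[i], mean(spots$bg_sd_B[i])) &&
      all(spots$A[i] > 0) && all(spots$B[i] > 0)
  }, logical(1))
  spots <- spots[spots$probe_id %in% names(keep)[keep], ]
  if (!nrow(spots)) stop("no detectable probes")

  if (normalize) {
    spots <- lowess_normalize(spots, span = span, iter = iter)
  } else {
    spots$A_norm <- spots$A
    spots$B_norm <- spots$B
  }

  per_probe <- split(seq_len(nrow(spots)), spots$probe_id)
  res <- do.call(rbind, lapply(per_probe, function(i) {
    sa <- mean(spots$A_norm[i])
    sb <- mean(spots$B_norm[i])
    data.frame(mirna = spots$mirna[i][1L],
               probe_id = spots$probe_id[i][1L],
               signal_A = sa, signal_B = sb,
               log2_ratio = log2_ratio(sa, sb),
               p_value = if (length(i) >= 2L) {
                 paired_t_test(spots$A_norm[i], spots$B_norm[i])
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  out <- differential_call(res, p_threshold, log2_threshold, mode, adjust)
  attr(out, "normalization") <- attr(spots, "fit")
  out
}
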