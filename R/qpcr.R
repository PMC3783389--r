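#' Delta-Ct normalization against a reference assay
#'
#' @param target_ct mean threshold cycle of the target assay.
#' @param reference_ct mean threshold cycle of the reference assay (e.g.
#'   5.8S rRNA) in the same sample.
#' @return `target_ct - reference_ct`.
#' @export
delta_ct <- function(target_ct, reference_ct) {
  stopifnot(all(is.finite(target_ct)), all(is.finite(reference_ct)))
  target_ct - reference_ct
}

#' Relative expression by the 2^-ddCt method
#'
#' Expression of the test sample relative to the calibrator sample,
#' assuming a doubling per cycle (amplification efficiency 2).
#'
#' @param dct_test delta-Ct of the test sample.
#' @param dct_calibrator delta-Ct of the calibrator sample.
#' @return `2^-(dct_test - dct_calibrator)`; 1 means no change, 2 means
#'   twofold higher in the test sample.
#' @export
ddct_ratio <- function(dct_test, dct_calibrator) {
  stopifnot(all(is.finite(dct_test)), all(is.finite(dct_calibrator)))
  2^(-(dct_test - dct_calibrator))
}

#' Summarize replicate qPCR experiments into relative expression
#'
#' Point estimates use mean Ct per (sample, assay) pooled over all
#' replicates, then delta-delta-Ct; the spread is the standard deviation
#' of per-experiment ratios across independent replicate experiments
#' (error bars of the usual three-experiment design).
#'
#' @param records Ct table (see [read_ct_table()]): columns `sample`,
#'   `assay`, `experiment`, `ct`.
#' @param design list with `test_sample`, `calibrator_sample` and
#'   `reference_assay`.
#' @return A data frame, one row per target assay in sorted order:
#'   `target`, `test_sample`, `calibrator_sample`, `delta_ct_test`,
#'   `delta_ct_calibrator`, `ddct`, `ratio`, `ratio_sd`,
#'   `n_experiments`.
#' @export
summarize_replicates <- function(records, design) {
  stopifnot(is.data.frame(records),
            all(c("sample", "assay", "experiment", "ct") %in%
                  names(records)),
            all(c("test_sample", "calibrator_sample", "reference_assay")
                %in% names(design)))
  ref <- design$reference_assay
  for (s in c(design$test_sample, design$calibrator_sample)) {
    if (!any(records$sample == s & records$assay == ref)) {
      stop("missing reference assay '", ref, "' for sample '", s, "'")
    }
  }
  targets <- sort(setdiff(unique(records$assay), ref))
  mean_ct <- function(df, sample, assay) {
    ct <- df$ct[df$sample == sample & df$assay == assay]
    if (!length(ct)) return(NA_real_)
    mean(ct)
  }
  out <- lapply(targets, function(tg) {
    dct_t <- delta_ct(mean_ct(records, design$test_sample, tg),
                      mean_ct(records, design$test_sample, ref))
    dct_c <- delta_ct(mean_ct(records, design$calibrator_sample, tg),
                      mean_ct(records, design$calibrator_sample, ref))
    if (!is.finite(dct_t) || !is.finite(dct_c)) {
      stop("assay '", tg, "' missing Ct values for a design sample")
    }
    per_exp <- vapply(sort(unique(records$experiment)), function(e) {
      df <- records[records$experiment == e, ]
      dt <- delta_ct(mean_ct(df, design$test_sample, tg),
                     mean_ct(df, design$test_sample, ref))
      dc <- delta_ct(mean_ct(df, design$calibrator_sample, tg),
                     mean_ct(df, design$calibrator_sample, ref))
      ddct_ratio(dt, dc)
    }, numeric(1))
    per_exp <- per_exp[is.finite(per_exp)]
    data.frame(target = tg,
               test_sample = design$test_sample,
               calibrator_sample = design$calibrator_sample,
               delta_ct_test = dct_t,
               delta_ct_calibrator = dct_c,
               ddct = dct_t - dct_c,
               ratio = ddct_ratio(dct_t, dct_c),
               ratio_sd = if (length(per_exp) >= 2L) stats::sd(per_exp)
                          else NA_real_,
               n_experiments = length(per_exp),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
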