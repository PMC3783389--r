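#' Published leaf miRNA microarray comparison table
#'
#' Mean two-channel hybridization signals of the 21 miRNAs reported as
#' differentially expressed between *Pinellia ternata* (channel A) and
#' *Pinellia pedatisecta* (channel B) leaves, with the published rounded
#' log2(B/A) column. Shipped as a plain-text fixture; useful for
#' exercising [log2_ratio()] and [differential_call()] in `fold_only`
#' mode (the printed table carries no replicate detail).
#'
#' @return A data frame with columns `family`, `name`, `sequence`,
#'   `signal_A`, `signal_B`, `printed_log2`.
#' @examples
#' tab <- pinellia_leaf_signals()
#' summary(log2_ratio(tab$signal_A, tab$signal_B) - tab$printed_log2)
#' @export
pinellia_leaf_signals <- function() {
  path <- system.file("extdata", "pinellia_leaf_microarray.tsv",
                      package = "mircleave", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
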