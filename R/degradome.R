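#' Map degradome tags onto transcripts
#'
#' Each tag is matched exactly and full-length against the sense strand of
#' every transcript (degradome tags derive from mRNA 5' fragments); every
#' occurrence contributes the tag's full abundance at the occurrence's 5'
#' position. Transcripts with no hits are absent from the result.
#'
#' @param tags data frame with columns `seq`, `count` (see [read_tags()]).
#' @param transcripts sequence record data frame.
#' @param multi_map `"full"` (default) credits full abundance at each
#'   occurrence of a multi-mapping tag; `"split"` divides the count evenly
#'   across occurrences.
#' @return A tag-profile data frame: `transcript_id`, `pos` (1-based
#'   position of a tag 5' end), `count` (summed abundance).
#' @export
map_tags <- function(tags, transcripts, multi_map = c("full", "split")) {
  multi_map <- match.arg(multi_map)
  stopifnot(is.data.frame(tags), nrow(transcripts) >= 1L)
  # one subject: transcripts joined by N runs longer than any tag, so no
  # tag (N-free after canonicalization) can match across a boundary
  seqs_dna <- chartr("U", "T", transcripts$seq)
  maxw <- max(nchar(tags$seq))
  subject <- Biostrings::DNAString(
    paste(seqs_dna, collapse = strrep("N", maxw)))
  lens <- nchar(seqs_dna)
  offs <- cumsum(c(0L, utils::head(lens + maxw, -1L)))  # 0-based starts
  has_n <- grepl("N", tags$seq, fixed = TRUE)
  occ <- list()          # one row per (tag occurrence, transcript, pos)
  for (w in unique(nchar(tags$seq[!has_n]))) {
    tag_rows <- which(!has_n & nchar(tags$seq) == w)
    pd <- Biostrings::PDict(
      Biostrings::DNAStringSet(chartr("U", "T", tags$seq[tag_rows])))
    m <- Biostrings::matchPDict(pd, subject)
    nh <- S4Vectors::elementNROWS(m)
    hit <- which(nh > 0L)
    if (!length(hit)) next
    g <- unlist(lapply(hit, function(i) BiocGenerics::start(m[[i]])))
    idx <- findInterval(g, offs + 1L)
    occ[[length(occ) + 1L]] <- data.frame(
      tag = tag_rows[rep(hit, nh[hit])],
      transcript_id = transcripts$id[idx],
      pos = as.integer(g - offs[idx]),
      stringsAsFactors = FALSE)
  }
  # tags containing N (rare; N matches only N) fall back to per-transcript
  # exact matching
  for (i in which(has_n)) {
    pat <- chartr("U", "T", tags$seq[i])
    for (j in seq_along(seqs_dna)) {
      m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seqs_dna[j]),
                                    fixed = TRUE)
      if (!length(m)) next
      occ[[length(occ) + 1L]] <- data.frame(
        tag = i, transcript_id = transcripts$id[j],
        pos = BiocGenerics::start(m), stringsAsFactors = FALSE)
    }
  }
  if (!length(occ)) {
    return(data.frame(transcript_id = character(), pos = integer(),
                      count = numeric(), stringsAsFactors = FALSE))
  }
  long <- do.call(rbind, occ)
  long$count <- tags$count[long$tag]
  if (multi_map == "split") {
    n_occ <- table(long$tag)
    long$count <- long$count / as.numeric(n_occ[as.character(long$tag)])
  }
  key <- paste(long$transcript_id, long$pos)
  agg <- rowsum(long$count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(transcript_id = long$transcript_id[first],
                    pos = long$pos[first], count = agg[, 1L],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$transcript_id, out$pos), , drop = FALSE]
}

#' Extract the t-signature around a degradome position
#'
#' The t-signature is the transcript window spanning `flank` nucleotides
#' upstream of the focal position through `flank - 1` downstream (30 nt at
#' the default flank of 15, with the focal position as its 16th
#' nucleotide); windows running off either transcript end are truncated
#' and flagged.
#'
#' @param transcript single sequence record (or bare string).
#' @param position focal transcript position (tag 5' end), 1-based.
#' @param flank nucleotides of upstream context (default 15).
#' @return A list: `transcript_id`, `position`, `seq`, `start`, `end`,
#'   `left_truncated`, `right_truncated`.
#' @export
extract_t_signature <- function(transcript, position, flank = 15L) {
  tr <- as_single_record(transcript, "transcript")
  L <- nchar(tr$seq)
  if (position < 1L || position > L) {
    stop("position ", position, " outside transcript 1..", L)
  }
  start <- max(1L, position - flank)
  end <- min(L, position + flank - 1L)
  list(transcript_id = tr$id, position = as.integer(position),
       seq = substr(tr$seq, start, end),
       start = start, end = end,
       left_truncated = start > position - flank,
       right_truncated = end < position + flank - 1L)
}

#' Classify a cleavage site's abundance tier
#'
#' Ranks the degradome support at a candidate site against the whole
#' transcript profile: category I when the site count equals the
#' transcript maximum; category II when it lies strictly between the
#' median count over occupied positions and the maximum; category III
#' otherwise (at or below the median).
#'
#' @param site_count summed tag count whose 5' ends fall exactly at the
#'   expected cleavage position.
#' @param profile_counts counts at all occupied positions of the
#'   transcript's tag profile.
#' @return `"I"`, `"II"` or `"III"`.
#' @export
categorize <- function(site_count, profile_counts) {
  if (!length(profile_counts)) stop("empty tag profile")
  stopifnot(site_count >= 1)
  mx <- max(profile_counts)
  md <- stats::median(profile_counts)
  if (site_count == mx) "I"
  else if (site_count > md && site_count < mx) "II"
  else "III"
}

#' Validate predicted target sites against a degradome profile
#'
#' A predicted site is supported when at least `min_reads` tag 5' ends
#' fall exactly at its expected cleavage position; supported sites become
#' cleavage events carrying the site abundance, the transcript profile
#' maximum and median, and the category I/II/III tier.
#'
#' @param sites target-table data frame (from [predict_targets()] or
#'   [read_target_table()]); must carry `transcript_id` and
#'   `cleavage_site`.
#' @param profiles tag-profile data frame from [map_tags()].
#' @param min_reads minimum site abundance (default 1).
#' @return The supported subset of `sites` with added columns
#'   `site_count`, `transcript_max`, `transcript_median` and `category`,
#'   in the input row order.
#' @export
validate_targets <- function(sites, profiles, min_reads = 1) {
  stopifnot(is.data.frame(sites), is.data.frame(profiles))
  if (!nrow(sites)) {
    sites$site_count <- numeric()
    sites$transcript_max <- numeric()
    sites$transcript_median <- numeric()
    return(sites)
  }
  n <- nrow(sites)
  site_count <- numeric(n)
  tr_max <- rep(NA_real_, n)
  tr_med <- rep(NA_real_, n)
  cat <- character(n)
  for (i in seq_len(n)) {
    prof <- profiles[profiles$transcript_id == sites$transcript_id[i], ]
    if (!nrow(prof)) next
    hit <- prof$count[prof$pos == sites$cleavage_site[i]]
    site_count[i] <- if (length(hit)) hit else 0
    tr_max[i] <- max(prof$count)
    tr_med[i] <- stats::median(prof$count)
    if (site_count[i] >= min_reads) {
      cat[i] <- categorize(site_count[i], prof$count)
    }
  }
  keep <- site_count >= min_reads & nzchar(cat)
  out <- sites[keep, , drop = FALSE]
  out$site_count <- site_count[keep]
  out$transcript_max <- tr_max[keep]
  out$transcript_median <- tr_med[keep]
  out$category <- cat[keep]
  rownames(out) <- NULL
  out
}

#' Tabulate a t-plot
#'
#' One row per occupied profile position (ascending), with the tag count
#' and a flag marking candidate cleavage sites; ready for TSV export or
#' plotting (cleavage-signal intensity against transcript position).
#'
#' @param profiles tag-profile data frame from [map_tags()].
#' @param transcript_id transcript to tabulate.
#' @param marked_positions positions to flag (e.g. expected cleavage
#'   sites).
#' @return A data frame with columns `pos`, `count`, `marked`.
#' @export
t_plot_table <- function(profiles, transcript_id,
                         marked_positions = integer()) {
  prof <- profiles[profiles$transcript_id == transcript_id, ]
  if (!nrow(prof)) stop("no tag profile for transcript ", transcript_id)
  out <- data.frame(pos = prof$pos, count = prof$count,
                    marked = prof$pos %in% marked_positions)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
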