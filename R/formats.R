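#' Sequence records
#'
#' A set of identified nucleotide sequences (miRNAs or transcripts) is
#' represented as a plain data frame with columns `id`, `desc` and `seq`.
#' Residues are held in the RNA alphabet `{A,C,G,U,N}`, uppercase; `T` in
#' input is canonicalized to `U` on construction.
#'
#' @param id character vector of identifiers (no whitespace, nonempty).
#' @param seq character vector of residues.
#' @param desc optional character vector of free-text descriptions.
#' @return A data frame with columns `id`, `desc`, `seq`.
#' @examples
#' seq_records("m1", "ugacagaagagagtgagcac")
#' @export
seq_records <- function(id, seq, desc = "") {
  id <- as.character(id)
  seq <- canonicalize_residues(as.character(seq), id)
  if (length(desc) == 1L) desc <- rep(desc, length(id))
  stopifnot(length(id) == length(seq), length(desc) == length(id))
  if (any(!nzchar(id)) || any(grepl("[[:space:]]", id))) {
    stop("sequence ids must be nonempty and contain no whitespace")
  }
  data.frame(id = id, desc = as.character(desc), seq = seq,
             stringsAsFactors = FALSE)
}

# Uppercase, T->U, and reject anything outside {A,C,G,U,N}, naming the
# offending record and position.
canonicalize_residues <- function(seq, id = seq_along(seq)) {
  seq <- chartr("t", "T", toupper(seq))
  seq <- chartr("T", "U", seq)
  if (any(!nzchar(seq))) {
    stop("record '", id[!nzchar(seq)][1L], "' has empty residues")
  }
  bad <- regexpr("[^ACGUN]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in record '%s' at position %d",
                 substr(seq[i], bad[i], bad[i]), id[i], bad[i]))
  }
  seq
}

#' Read a FASTA file of nucleotide sequences
#'
#' Records are returned in file order with line-wrapped residues joined.
#' `T` is converted to `U` so that DNA- and RNA-alphabet inputs unify;
#' characters outside `{A,C,G,U,N}` are an error naming the position.
#'
#' @param path path to a FASTA file.
#' @return A data frame of sequence records (see [seq_records()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- names(set)
  id <- sub("[[:space:]].*$", "", nm)
  desc <- ifelse(grepl("[[:space:]]", nm),
                 sub("^[^[:space:]]+[[:space:]]+", "", nm), "")
  seq_records(id, as.character(set), desc)
}

#' Write sequence records as FASTA
#'
#' Output is deterministic for fixed inputs: header line (id, plus
#' description when present), then residues wrapped at `wrap_width`.
#'
#' @param records data frame of sequence records.
#' @param path output path.
#' @param wrap_width residues per line (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, wrap_width = 60L) {
  stopifnot(is.data.frame(records), wrap_width >= 1L)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(set, path, width = wrap_width)
  invisible(path)
}

#' Read degradome tags
#'
#' Two dialects are accepted: a two-column TSV `sequence<TAB>count`
#' (canonical), or FASTA whose headers end in `-<count>`. Duplicate
#' sequences are merged by summing counts.
#'
#' @param path input path.
#' @param length_bounds allowed tag lengths, inclusive; tags outside the
#'   bounds are an error. Degradome tags are short 5'-fragment reads, so the
#'   default is 15-30 nt.
#' @return A data frame with columns `seq` and `count`.
#' @export
read_tags <- function(path, length_bounds = c(15L, 30L)) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty tag file: ", path)
  if (startsWith(first, ">")) {
    fa <- read_fasta(path)
    counts <- suppressWarnings(as.integer(sub("^.*-", "", fa$id)))
    if (anyNA(counts)) {
      stop("FASTA tag header without trailing -<count>: ",
           fa$id[is.na(counts)][1L])
    }
    seqs <- fa$seq
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) stop("malformed tag line ", bad[1L],
                          " (expected sequence<TAB>count)")
    seqs <- canonicalize_residues(vapply(parts, `[`, "", 1L))
    counts <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    if (anyNA(counts)) stop("non-integer tag count at line ",
                            which(is.na(counts))[1L])
  }
  if (any(counts <= 0L)) stop("tag count must be >= 1 (line ",
                              which(counts <= 0L)[1L], ")")
  len <- nchar(seqs)
  if (any(len < length_bounds[1L] | len > length_bounds[2L])) {
    i <- which(len < length_bounds[1L] | len > length_bounds[2L])[1L]
    stop(sprintf("tag length %d outside bounds [%d, %d]: %s",
                 len[i], length_bounds[1L], length_bounds[2L], seqs[i]))
  }
  agg <- rowsum(counts, seqs)
  data.frame(seq = rownames(agg), count = as.integer(agg[, 1L]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write degradome tags as TSV
#'
#' @param tags data frame with columns `seq`, `count`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tags <- function(tags, path) {
  utils::write.table(tags[, c("seq", "count")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

signal_columns <- c("probe_id", "mirna", "channel", "replicate",
                    "fg", "bg_mean", "bg_sd")

#' Read a two-channel probe signal table
#'
#' CSV with header columns `probe_id, mirna, channel, replicate, fg,
#' bg_mean, bg_sd`; one row per spot per channel. Channel labels are `A`
#' and `B`. Thousands separators in numeric cells ("1,192" style, as in
#' published signal tables) are stripped.
#'
#' @param path input CSV path.
#' @return A data frame with the columns above, numerics parsed.
#' @export
read_signal_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(signal_columns, names(df))
  if (length(missing)) stop("signal table missing required column: ",
                            missing[1L])
  df <- df[signal_columns]
  for (col in c("replicate", "fg", "bg_mean", "bg_sd")) {
    raw <- gsub(",", "", df[[col]], fixed = TRUE)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) stop(sprintf("non-numeric value '%s' in column '%s'",
                                 raw[is.na(val)][1L], col))
    df[[col]] <- val
  }
  df$replicate <- as.integer(df$replicate)
  if (any(df$replicate < 1L)) stop("replicate index must be >= 1")
  if (any(!is.finite(df$fg)) || any(df$fg < 0) ||
      any(!is.finite(df$bg_mean)) || any(df$bg_mean < 0)) {
    stop("signals must be finite and non-negative")
  }
  if (!all(df$channel %in% c("A", "B"))) {
    stop("channel labels must be 'A' or 'B'")
  }
  df
}

#' Write a signal table
#' @param signals data frame as returned by [read_signal_table()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_signal_table <- function(signals, path) {
  utils::write.csv(signals[signal_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

target_table_columns <- c("mirna_family", "mirna_name", "annotation",
                          "transcript_id", "score", "range",
                          "cleavage_site", "category")

#' Write a target table
#'
#' Serializes predicted (or degradome-validated) target sites as TSV in the
#' standard column order: miRNA family, miRNA name, annotation, transcript
#' id, alignment score, alignment range (rendered `start-end`, 1-based
#' inclusive), cleavage site, category (empty when unvalidated).
#'
#' @param rows data frame with columns `mirna_family`, `mirna_name`,
#'   `annotation`, `transcript_id`, `score`, `start`, `end`,
#'   `cleavage_site`, `category`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_target_table <- function(rows, path) {
  need <- c("mirna_family", "mirna_name", "annotation", "transcript_id",
            "score", "start", "end", "cleavage_site", "category")
  missing <- setdiff(need, names(rows))
  if (length(missing)) stop("target table missing required column: ",
                            missing[1L])
  stopifnot(all(rows$start <= rows$cleavage_site),
            all(rows$cleavage_site <= rows$end))
  out <- data.frame(
    mirna_family = rows$mirna_family,
    mirna_name = rows$mirna_name,
    annotation = rows$annotation,
    transcript_id = rows$transcript_id,
    score = rows$score,
    range = paste0(rows$start, "-", rows$end),
    cleavage_site = rows$cleavage_site,
    category = rows$category,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a target table written by [write_target_table()]
#' @param path TSV path.
#' @return A data frame with `start`/`end` split out of the range column.
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  missing <- setdiff(target_table_columns, names(df))
  if (length(missing)) stop("target table missing required column: ",
                            missing[1L])
  rng <- strsplit(df$range, "-", fixed = TRUE)
  df$start <- as.integer(vapply(rng, `[`, "", 1L))
  df$end <- as.integer(vapply(rng, `[`, "", 2L))
  df$score <- as.numeric(df$score)
  df$cleavage_site <- as.integer(df$cleavage_site)
  df
}

#' Read a qPCR Ct table
#'
#' CSV with header columns `sample, assay, experiment, ct`: one row per
#' replicate Ct measurement, `experiment` indexing independent biological
#' replicate experiments.
#'
#' @param path input CSV path.
#' @return A data frame with those columns, `ct` numeric.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(c("sample", "assay", "experiment", "ct"), names(df))
  if (length(missing)) stop("Ct table missing required column: ",
                            missing[1L])
  df$ct <- as.numeric(df$ct)
  df$experiment <- as.integer(df$experiment)
  if (any(!is.finite(df$ct))) stop("Ct values must be finite")
  df
}
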