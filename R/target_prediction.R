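#' Penalty scheme for weighted-complementarity target scoring
#'
#' Plant miRNA targets are scored by summing penalties over an
#' antiparallel miRNA:mRNA alignment: Watson-Crick pairs are free, G:U
#' wobbles cost `gu_penalty`, mismatches and single-nucleotide bulges cost
#' `mismatch_penalty`/`bulge_penalty`. Mismatch and G:U penalties are
#' multiplied by `core_multiplier` when the miRNA position falls in the
#' 5'-proximal core segment, reflecting the importance of 5'
#' complementarity for target-site function. Sites scoring at most
#' `cutoff` are reported.
#'
#' @param mismatch_penalty penalty per mismatched pair (default 1).
#' @param gu_penalty penalty per G:U wobble (default 0.5).
#' @param bulge_penalty penalty per single-nucleotide bulge (default 1).
#' @param core_range miRNA positions (1-based from the 5' end) of the core
#'   segment (default 2-13, the Jones-Rhoades & Bartel convention).
#' @param core_multiplier factor applied to mismatch and G:U penalties in
#'   the core (default 2).
#' @param double_core_bulges if `TRUE`, bulge penalties are also doubled in
#'   the core; the default `FALSE` doubles mismatches and wobbles only.
#' @param max_bulges maximum bulges per site (default 1).
#' @param cutoff maximum reported penalty score (default 4).
#' @return A list with class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' scoring_scheme(cutoff = 3, core_range = c(2, 12))
#' @export
scoring_scheme <- function(mismatch_penalty = 1, gu_penalty = 0.5,
                           bulge_penalty = 1, core_range = c(2L, 13L),
                           core_multiplier = 2, double_core_bulges = FALSE,
                           max_bulges = 1L, cutoff = 4) {
  stopifnot(mismatch_penalty >= 0, gu_penalty >= 0, bulge_penalty >= 0,
            core_multiplier >= 0, cutoff >= 0, max_bulges %in% 0:1,
            length(core_range) == 2L, core_range[1L] >= 1L,
            core_range[1L] <= core_range[2L])
  structure(list(mismatch_penalty = mismatch_penalty,
                 gu_penalty = gu_penalty,
                 bulge_penalty = bulge_penalty,
                 core_range = as.integer(core_range),
                 core_multiplier = core_multiplier,
                 double_core_bulges = double_core_bulges,
                 max_bulges = as.integer(max_bulges),
                 cutoff = cutoff),
            class = "scoring_scheme")
}

pair_states <- c("MATCH", "GU", "MISMATCH", "BULGE_MIRNA", "BULGE_TARGET")

#' Classify one miRNA:target base pair
#'
#' `MATCH` for Watson-Crick complements (A:U, G:C), `GU` for the wobble
#' pair (miRNA G opposite target U or miRNA U opposite target G),
#' `MISMATCH` otherwise. `N` (or any non-standard symbol) never pairs and
#' classifies as `MISMATCH`.
#'
#' @param mirna_nt,target_nt vectors of single residues in `{A,C,G,U,N}`.
#' @return Character vector over `{"MATCH","GU","MISMATCH"}`.
#' @examples
#' classify_pair(c("A", "G", "A"), c("U", "U", "G"))
#' @export
classify_pair <- function(mirna_nt, target_nt) {
  m <- toupper(mirna_nt)
  t <- toupper(target_nt)
  wc <- (m == "A" & t == "U") | (m == "U" & t == "A") |
        (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "U") | (m == "U" & t == "G")
  ifelse(wc, "MATCH", ifelse(gu, "GU", "MISMATCH"))
}

#' Construct a pairing map
#'
#' A pairing map records one miRNA:transcript alignment as ordered rows
#' along the miRNA (5' to 3'): `state` is one of `MATCH`, `GU`,
#' `MISMATCH`, `BULGE_MIRNA` (miRNA nucleotide unpaired, `target_pos` NA)
#' or `BULGE_TARGET` (transcript nucleotide unpaired; its `mirna_pos`
#' carries the position of the next paired miRNA nucleotide for core
#' bookkeeping). Because the duplex is antiparallel, transcript positions
#' decrease down the rows.
#'
#' @param state character vector of pair states.
#' @param mirna_pos integer vector of miRNA positions (1-based, 5' end = 1).
#' @param target_pos integer vector of transcript positions (1-based), NA
#'   for `BULGE_MIRNA` rows.
#' @return A data frame with class `pairing_map`.
#' @export
pairing_map <- function(state, mirna_pos, target_pos) {
  pm <- data.frame(state = as.character(state),
                   mirna_pos = as.integer(mirna_pos),
                   target_pos = as.integer(target_pos),
                   stringsAsFactors = FALSE)
  class(pm) <- c("pairing_map", "data.frame")
  validate_pairing(pm)
  pm
}

validate_pairing <- function(pm) {
  if (!all(pm$state %in% pair_states)) {
    stop("unknown pair state: ",
         pm$state[!pm$state %in% pair_states][1L])
  }
  mp <- as.integer(pm$mirna_pos[pm$state != "BULGE_TARGET"])
  L <- max(mp)
  if (!identical(sort(mp), seq_len(L))) {
    stop("pairing must consume every miRNA position 1..L exactly once")
  }
  tp <- as.integer(pm$target_pos[pm$state != "BULGE_MIRNA"])
  if (anyNA(tp) || !identical(sort(tp), seq.int(min(tp), max(tp)))) {
    stop("transcript positions consumed must form a contiguous range")
  }
  invisible(pm)
}

#' Score a pairing map under a penalty scheme
#'
#' Sums per-position penalties: `MATCH` adds 0; `GU` adds the wobble
#' penalty (multiplied in the core); `MISMATCH` adds the mismatch penalty
#' (multiplied in the core); bulges add the bulge penalty (not multiplied
#' unless `double_core_bulges`). A perfect-complement pairing scores 0.
#'
#' @param pairing a [pairing_map()].
#' @param scheme a [scoring_scheme()].
#' @return Numeric penalty score.
#' @export
score_pairing <- function(pairing, scheme = scoring_scheme()) {
  validate_pairing(pairing)
  in_core <- pairing$mirna_pos >= scheme$core_range[1L] &
             pairing$mirna_pos <= scheme$core_range[2L]
  mult <- ifelse(in_core, scheme$core_multiplier, 1)
  base <- c(MATCH = 0, GU = scheme$gu_penalty,
            MISMATCH = scheme$mismatch_penalty,
            BULGE_MIRNA = scheme$bulge_penalty,
            BULGE_TARGET = scheme$bulge_penalty)[pairing$state]
  is_bulge <- pairing$state %in% c("BULGE_MIRNA", "BULGE_TARGET")
  if (!scheme$double_core_bulges) mult[is_bulge] <- 1
  sum(base * mult)
}

#' Expected cleavage position of a target site
#'
#' miRNA-guided cleavage occurs between the transcript bases paired to
#' miRNA nucleotides 10 and 11 (counted from the miRNA 5' end); the site
#' is reported as the transcript base paired to nucleotide 10. For an
#' ungapped site whose alignment range ends at `E` (the miRNA 5' end is
#' opposite the range end), this is `E - 9`.
#'
#' @param pairing a [pairing_map()].
#' @return Transcript position (1-based) paired to miRNA nucleotide 10.
#' @export
expected_cleavage_position <- function(pairing) {
  paired <- pairing$state %in% c("MATCH", "GU", "MISMATCH")
  i <- which(paired & pairing$mirna_pos == 10L)
  if (length(i) != 1L) stop("miRNA position 10 is not paired; ",
                            "cleavage position undefined")
  pairing$target_pos[i]
}

res_alphabet <- c("A", "C", "G", "U", "N")

res_index <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], res_alphabet)
}

# Per-miRNA-position penalty rows over the 5 target symbols, core
# multiplier applied. PENM[i, j] = penalty of pairing miRNA nt i with
# target symbol j.
penalty_profile <- function(mir_idx, scheme) {
  L <- length(mir_idx)
  cls <- outer(res_alphabet[mir_idx], res_alphabet, classify_pair)
  base <- matrix(c(MATCH = 0, GU = scheme$gu_penalty,
                   MISMATCH = scheme$mismatch_penalty)[cls], nrow = L)
  mult <- ifelse(seq_len(L) >= scheme$core_range[1L] &
                 seq_len(L) <= scheme$core_range[2L],
                 scheme$core_multiplier, 1)
  base * mult
}

# Band-1 placement shapes. Each combo fixes, for miRNA position i, the
# offset of its paired transcript base from the alignment end e
# (target_pos = e - off[i]); bulges shift the tail by one.
placement_combos <- function(L, scheme) {
  combos <- list(list(type = "ungapped", b = NA_integer_,
                      off = 0:(L - 1L), span = L, nbulges = 0L))
  if (scheme$max_bulges >= 1L) {
    allowed <- setdiff(seq_len(L), 9:12)
    for (b in allowed) {                       # miRNA nt b unpaired
      off <- ifelse(seq_len(L) < b, seq_len(L) - 1L, seq_len(L) - 2L)
      off[b] <- NA_integer_
      combos[[length(combos) + 1L]] <-
        list(type = "bulge_mirna", b = b, off = off, span = L - 1L,
             nbulges = 1L)
    }
    for (b in setdiff(allowed, 1L)) {          # extra transcript nt before
      off <- ifelse(seq_len(L) < b, seq_len(L) - 1L, seq_len(L))
      combos[[length(combos) + 1L]] <-
        list(type = "bulge_target", b = b, off = off, span = L + 1L,
             nbulges = 1L)
    }
  }
  combos
}

bulge_penalty_of <- function(combo, scheme) {
  if (combo$nbulges == 0L) return(0)
  mult <- if (scheme$double_core_bulges &&
              combo$b >= scheme$core_range[1L] &&
              combo$b <= scheme$core_range[2L]) scheme$core_multiplier else 1
  scheme$bulge_penalty * mult
}

# Reconstruct the full pairing map of one placement.
build_pairing <- function(combo, e, mir_res, tgt_res) {
  L <- length(mir_res)
  rows <- list()
  for (i in seq_len(L)) {
    if (combo$type == "bulge_target" && i == combo$b) {
      # unpaired transcript nt sits between the pairs of miRNA b-1 and b
      rows[[length(rows) + 1L]] <-
        data.frame(state = "BULGE_TARGET", mirna_pos = i,
                   target_pos = e - combo$off[i] + 1L,
                   stringsAsFactors = FALSE)
    }
    if (combo$type == "bulge_mirna" && i == combo$b) {
      rows[[length(rows) + 1L]] <-
        data.frame(state = "BULGE_MIRNA", mirna_pos = i,
                   target_pos = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    tp <- e - combo$off[i]
    rows[[length(rows) + 1L]] <-
      data.frame(state = classify_pair(mir_res[i], tgt_res[tp]),
                 mirna_pos = i, target_pos = tp, stringsAsFactors = FALSE)
  }
  pm <- do.call(rbind, rows)
  class(pm) <- c("pairing_map", "data.frame")
  pm
}

as_single_record <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    return(seq_records(what, x))
  }
  stopifnot(is.data.frame(x), nrow(x) == 1L)
  x
}

#' Find miRNA target sites on one transcript
#'
#' Scans every local placement of the full miRNA (reverse-complement
#' matching, antiparallel) against the transcript: ungapped and, when the
#' scheme allows, with one single-nucleotide bulge on either strand
#' (bulges are forbidden opposite miRNA positions 9-12 so the cleavage
#' position is always defined). Each placement is scored with
#' [score_pairing()]; placements scoring at most the scheme cutoff are
#' kept, and overlapping placements are collapsed to the best-scoring one
#' (ties: fewest bulges, then leftmost start).
#'
#' @param mirna single sequence record (or bare string), length 19-24 nt,
#'   no `N`.
#' @param transcript single sequence record (or bare string), at least as
#'   long as the miRNA.
#' @param scheme a [scoring_scheme()].
#' @return A data frame of sites sorted by transcript start: columns
#'   `mirna_id`, `transcript_id`, `score`, `start`, `end`, `n_bulges`,
#'   `cleavage_site`, and a list column `pairing` of [pairing_map()]s.
#' @examples
#' ts <- gen_transcriptome(1, c(200, 200), gc = 0.5, seed = 1)
#' mir <- "UGACAGAAGAGAGUGAGCAC"
#' imp <- implant_site(ts[1, ], mir, position = 100)
#' find_sites(mir, imp$transcript)
#' @export
find_sites <- function(mirna, transcript, scheme = scoring_scheme()) {
  m <- as_single_record(mirna, "mirna")
  tr <- as_single_record(transcript, "transcript")
  L <- nchar(m$seq)
  if (L < 19L || L > 24L) stop("miRNA length must be 19-24 nt, got ", L)
  if (grepl("N", m$seq, fixed = TRUE)) stop("miRNA contains N: ", m$id)
  N <- nchar(tr$seq)
  empty <- data.frame(mirna_id = character(), transcript_id = character(),
                      score = numeric(), start = integer(), end = integer(),
                      n_bulges = integer(), cleavage_site = integer())
  empty$pairing <- list()
  if (N < L) return(empty)
  if (scheme$core_range[2L] > L) stop("core range exceeds miRNA length")

  mir_idx <- res_index(m$seq)
  tgt_idx <- res_index(tr$seq)
  mir_res <- res_alphabet[mir_idx]
  tgt_res <- res_alphabet[tgt_idx]
  penm <- penalty_profile(mir_idx, scheme)
  combos <- placement_combos(L, scheme)

  cand <- list()
  for (k in seq_along(combos)) {
    cb <- combos[[k]]
    max_off <- max(cb$off, na.rm = TRUE)
    if (N < max_off + 1L) next
    e <- seq.int(max_off + 1L, N)
    keep <- !is.na(cb$off)
    score <- rowSums(vapply(which(keep), function(i) {
      penm[i, tgt_idx[e - cb$off[i]]]
    }, numeric(length(e)))) + bulge_penalty_of(cb, scheme)
    ok <- which(score <= scheme$cutoff)
    if (!length(ok)) next
    cand[[length(cand) + 1L]] <-
      data.frame(combo = k, e = e[ok], score = score[ok],
                 start = e[ok] - cb$span + 1L, nbulges = cb$nbulges)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)

  # collapse overlapping placements: best score, then fewest bulges,
  # then leftmost
  cand <- cand[order(cand$score, cand$nbulges, cand$start, cand$combo), ]
  chosen <- cand[0, ]
  while (nrow(cand)) {
    top <- cand[1L, ]
    chosen <- rbind(chosen, top)
    cand <- cand[!(cand$start <= top$e & cand$e >= top$start), ]
  }
  chosen <- chosen[order(chosen$start), ]

  pairings <- lapply(seq_len(nrow(chosen)), function(r) {
    build_pairing(combos[[chosen$combo[r]]], chosen$e[r], mir_res, tgt_res)
  })
  out <- data.frame(
    mirna_id = m$id, transcript_id = tr$id,
    score = chosen$score, start = chosen$start, end = chosen$e,
    n_bulges = chosen$nbulges,
    cleavage_site = vapply(pairings, expected_cleavage_position,
                           integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out$pairing <- pairings
  out
}

# "ghr-miR156c" -> "miR156"; names without a miR number are their own family
mirna_family <- function(name) {
  vapply(name, function(n) {
    hit <- regmatches(n, regexpr("miR[0-9]+", n))
    if (length(hit)) hit else n
  }, character(1), USE.NAMES = FALSE)
}

#' Predict target sites over all miRNA x transcript combinations
#'
#' Runs [find_sites()] over the cross product and returns one row per
#' reported site in deterministic order (miRNA input order, then
#' transcript input order, then transcript start).
#'
#' @param mirnas,transcripts sequence record data frames; ids must be
#'   unique within each.
#' @param scheme a [scoring_scheme()].
#' @return A target-table data frame (see [write_target_table()]) with
#'   empty `category`, plus `end`/`start` columns and `n_bulges`.
#' @export
predict_targets <- function(mirnas, transcripts,
                            scheme = scoring_scheme()) {
  stopifnot(is.data.frame(mirnas), is.data.frame(transcripts))
  if (anyDuplicated(mirnas$id)) {
    stop("duplicate miRNA id: ", mirnas$id[duplicated(mirnas$id)][1L])
  }
  if (anyDuplicated(transcripts$id)) {
    stop("duplicate transcript id: ",
         transcripts$id[duplicated(transcripts$id)][1L])
  }
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (j in seq_len(nrow(transcripts))) {
      s <- find_sites(mirnas[i, ], transcripts[j, ], scheme)
      if (nrow(s)) rows[[length(rows) + 1L]] <- s
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_family = character(), mirna_name = character(),
                      annotation = character(), transcript_id = character(),
                      score = numeric(), start = integer(), end = integer(),
                      cleavage_site = integer(), n_bulges = integer(),
                      category = character(), stringsAsFactors = FALSE))
  }
  sites <- do.call(rbind, lapply(rows, function(s) {
    s[setdiff(names(s), "pairing")]
  }))
  ann <- transcripts$desc[match(sites$transcript_id, transcripts$id)]
  data.frame(mirna_family = mirna_family(sites$mirna_id),
             mirna_name = sites$mirna_id,
             annotation = ifelse(is.na(ann), "", ann),
             transcript_id = sites$transcript_id,
             score = sites$score, start = sites$start, end = sites$end,
             cleavage_site = sites$cleavage_site,
             n_bulges = sites$n_bulges,
             category = "", row.names = NULL, stringsAsFactors = FALSE)
}
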