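# Independent re-implementations used as test oracles. These are written
# as plain loops with their own rule tables, deliberately sharing no code
# with the package internals they check.

oracle_pair_class <- function(m, t) {
  pair <- paste0(m, t)
  if (pair %in% c("AU", "UA", "GC", "CG")) "MATCH"
  else if (pair %in% c("GU", "UG")) "GU"
  else "MISMATCH"
}

# Position-by-position penalty summation from the rule table:
# mismatch 1, G:U 0.5, bulge 1; mismatch and G:U doubled at miRNA
# positions 2-13; bulges never doubled.
oracle_score <- function(states, mirna_pos) {
  total <- 0
  for (k in seq_along(states)) {
    core <- mirna_pos[k] >= 2 && mirna_pos[k] <= 13
    total <- total + switch(states[k],
      MATCH = 0,
      GU = if (core) 1.0 else 0.5,
      MISMATCH = if (core) 2 else 1,
      BULGE_MIRNA = 1,
      BULGE_TARGET = 1)
  }
  total
}

# Exhaustive enumeration of every <=1-bulge placement of the full miRNA
# on the transcript, scored with oracle_score; overlapping placements
# collapsed to the best (score, then fewest bulges, then leftmost start,
# then miRNA-bulge shape before transcript-bulge shape).
oracle_find_sites <- function(mirna_seq, transcript_seq, cutoff = 4) {
  mir <- strsplit(mirna_seq, "")[[1]]
  tx <- strsplit(transcript_seq, "")[[1]]
  L <- length(mir)
  N <- length(tx)
  cand <- list()
  push <- function(start, end, score, nb, shape) {
    cand[[length(cand) + 1L]] <<- data.frame(
      start = start, end = end, score = score, nbulges = nb,
      shape = shape)
  }
  # ungapped
  for (s in seq_len(max(0, N - L + 1))) {
    e <- s + L - 1
    states <- character(L)
    for (i in 1:L) states[i] <- oracle_pair_class(mir[i], tx[e - i + 1])
    sc <- oracle_score(states, 1:L)
    if (sc <= cutoff) push(s, e, sc, 0L, 0L)
  }
  # one unpaired miRNA nt at b (site spans L-1)
  for (s in seq_len(max(0, N - (L - 1) + 1))) {
    e <- s + L - 2
    for (b in setdiff(1:L, 9:12)) {
      states <- character(0)
      mpos <- integer(0)
      for (i in 1:L) {
        if (i == b) {
          states <- c(states, "BULGE_MIRNA")
          mpos <- c(mpos, i)
        } else {
          t <- if (i < b) e - i + 1 else e - i + 2
          states <- c(states, oracle_pair_class(mir[i], tx[t]))
          mpos <- c(mpos, i)
        }
      }
      sc <- oracle_score(states, mpos)
      if (sc <= cutoff) push(s, e, sc, 1L, 1L)
    }
  }
  # one unpaired transcript nt before the pair of miRNA b (spans L+1)
  for (s in seq_len(max(0, N - (L + 1) + 1))) {
    e <- s + L
    for (b in setdiff(2:L, 9:12)) {
      states <- "BULGE_TARGET"
      mpos <- b
      for (i in 1:L) {
        t <- if (i < b) e - i + 1 else e - i
        states <- c(states, oracle_pair_class(mir[i], tx[t]))
        mpos <- c(mpos, i)
      }
      sc <- oracle_score(states, mpos)
      if (sc <= cutoff) push(s, e, sc, 1L, 2L)
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(),
                      score = numeric(), nbulges = integer()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$score, cand$nbulges, cand$start, cand$shape), ]
  chosen <- cand[0, ]
  while (nrow(cand)) {
    top <- cand[1, ]
    chosen <- rbind(chosen, top)
    cand <- cand[!(cand$start <= top$end & cand$end >= top$start), ]
  }
  chosen <- chosen[order(chosen$start), c("start", "end", "score",
                                          "nbulges")]
  rownames(chosen) <- NULL
  chosen
}

# Random pairing-map generator for the scoring oracle: a ladder over
# miRNA length L with random states and consistent coordinates.
random_pairing <- function(L = 21L, bulge_prob = 0.3) {
  bulge_pos <- if (stats::runif(1) < bulge_prob) {
    sample(setdiff(2:(L - 1), 9:12), 1)
  } else NA_integer_
  bulge_kind <- if (!is.na(bulge_pos)) sample(c("BULGE_MIRNA",
                                                "BULGE_TARGET"), 1)
  states <- sample(c("MATCH", "GU", "MISMATCH"), L, replace = TRUE,
                   prob = c(0.7, 0.15, 0.15))
  st <- character(0); mp <- integer(0); tp <- integer(0)
  e <- 500L
  t <- e
  for (i in seq_len(L)) {
    if (!is.na(bulge_pos) && i == bulge_pos) {
      if (bulge_kind == "BULGE_TARGET") {
        st <- c(st, "BULGE_TARGET"); mp <- c(mp, i); tp <- c(tp, t)
        t <- t - 1L
      } else {
        st <- c(st, "BULGE_MIRNA"); mp <- c(mp, i); tp <- c(tp, NA)
        next
      }
    }
    st <- c(st, states[i]); mp <- c(mp, i); tp <- c(tp, t)
    t <- t - 1L
  }
  pairing_map(st, mp, tp)
}

# Independent exact substring occurrence count (tag-conservation oracle).
oracle_occurrences <- function(tag, transcripts) {
  total <- 0L
  for (seq in transcripts$seq) {
    hits <- gregexpr(tag, seq, fixed = TRUE)[[1]]
    if (hits[1] != -1L) total <- total + length(hits)
  }
  total
}

# Shared fixture: a miRNA with a planted perfect site in each transcript.
make_planted_set <- function(n_transcripts, seed,
                             mirna = "UGACAGAAGAGAGUGAGCAC",
                             length_range = c(400L, 900L),
                             position = 150L) {
  tx <- gen_transcriptome(n_transcripts, length_range, gc = 0.5,
                          seed = seed)
  mir <- seq_records("mir-test", mirna)
  planted <- lapply(seq_len(n_transcripts), function(i) {
    implant_site(tx[i, ], mir, position = position)
  })
  for (i in seq_len(n_transcripts)) tx[i, ] <- planted[[i]]$transcript
  list(mirna = mir, transcripts = tx,
       truth = data.frame(
         transcript_id = tx$id,
         cleavage_site = vapply(planted, `[[`, integer(1),
                                "cleavage_site"),
         score = vapply(planted, `[[`, numeric(1), "score")))
}
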