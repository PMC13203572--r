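# Construct a compact two-or-three speaker session: one utterance per code,
# sequential non-overlapping times (1000 ms utterances, 100 ms gaps).
# Codes: "A" = LANG_A, "B" = LANG_B, "M" = mixed half/half, "U" = unknown.
quick_session <- function(codes, speakers,
                          roster = c(CG1 = "PRIMARY_CAREGIVER",
                                     CHI = "TARGET_CHILD",
                                     OTH = "OTHER_HOUSEHOLD"),
                          session_id = "s1", family_id = "f1",
                          community = "FRENCH_ENGLISH", session_type = "A",
                          dur_ms = 1000L, gap_ms = 100L) {
  stopifnot(length(codes) == length(speakers))
  n <- length(codes)
  onset <- (0:(n - 1L)) * (dur_ms + gap_ms)
  offset <- onset + dur_ms
  ids <- sprintf("u%03d", seq_len(n))
  utterances <- data.frame(utterance_id = ids, speaker_id = speakers,
                           onset_ms = onset, offset_ms = offset,
                           transcript = NA_character_,
                           stringsAsFactors = FALSE)
  seg <- lapply(seq_len(n), function(i) {
    switch(codes[i],
      A = data.frame(utterance_id = ids[i], language = "LANG_A",
                     onset_ms = onset[i], offset_ms = offset[i]),
      B = data.frame(utterance_id = ids[i], language = "LANG_B",
                     onset_ms = onset[i], offset_ms = offset[i]),
      M = data.frame(utterance_id = ids[c(i, i)],
                     language = c("LANG_A", "LANG_B"),
                     onset_ms = c(onset[i], onset[i] + dur_ms %/% 2L),
                     offset_ms = c(onset[i] + dur_ms %/% 2L, offset[i])),
      U = NULL)
  })
  segments <- do.call(rbind, Filter(Negate(is.null), seg))
  if (is.null(segments)) {
    segments <- data.frame(utterance_id = character(),
                           language = character(), onset_ms = integer(),
                           offset_ms = integer(), stringsAsFactors = FALSE)
  }
  roster <- roster[unique(c(speakers, names(roster)[1:2]))]
  session_record(session_id = session_id, family_id = family_id,
                 community = community, session_type = session_type,
                 utterances = utterances, segments = segments,
                 roster = roster)
}

# Swap LANG_A and LANG_B everywhere in a session (relabel symmetry checks)
swap_languages <- function(session) {
  s <- session$segments
  s$language <- ifelse(s$language == "LANG_A", "LANG_B",
                       ifelse(s$language == "LANG_B", "LANG_A",
                              s$language))
  session$segments <- s
  session
}

swap_series <- function(series) {
  sw <- function(x) ifelse(x == "LANG_A", "LANG_B", "LANG_A")
  turn_series(sw(series$turns$prev_language),
              sw(series$turns$response_language),
              session_id = series$session_id, dyad = series$dyad,
              direction = series$direction)
}

# random turn series with given marginals drawn iid
rand_series <- function(n, p_prev = 0.5, p_resp = 0.5) {
  turn_series(
    ifelse(runif(n) < p_prev, "LANG_A", "LANG_B"),
    ifelse(runif(n) < p_resp, "LANG_A", "LANG_B"))
}

# all permutations of seq_len(n), one per row (brute-force null oracle)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# exact permutation-null distribution of match rates by enumeration
exact_null_dist <- function(series) {
  prev <- series$turns$prev_language
  resp <- series$turns$response_language
  n <- length(prev)
  pm <- all_perms(n)
  rates <- vapply(seq_len(nrow(pm)),
                  function(i) mean(prev == resp[pm[i, ]]), numeric(1L))
  tab <- table(factor(round(rates * n), levels = 0:n))
  as.numeric(tab) / nrow(pm)
}

# empirical distribution of MC rates on the same match-count support
mc_dist <- function(rates, n) {
  tab <- table(factor(round(rates * n), levels = 0:n))
  as.numeric(tab) / length(rates)
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# exact null via the hypergeometric closed form: matches = (n-a-b) + 2X,
# X ~ Hypergeometric(a, n-a, b) with a = prev A-count, b = resp A-count
hyper_null_dist <- function(series) {
  s <- summarize_turns(series)
  n <- s$n_turns
  a <- s$prev_counts[["LANG_A"]]
  b <- s$resp_counts[["LANG_A"]]
  x <- max(0L, a + b - n):min(a, b)
  m <- (n - a - b) + 2L * x
  out <- numeric(n + 1L)
  out[m + 1L] <- stats::dhyper(x, a, n - a, b)
  out
}
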