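#' Synthetic speaker configuration
#'
#' Generative parameters for one simulated speaker. A speaker's utterance
#' language is the most recent identifiable language used by any *other*
#' speaker with probability `coupling` (the alignment strength
#' \eqn{\lambda}), and otherwise a fresh draw with
#' `P(LANG_A) = base_rate_A`. The utterance is then relabelled wholly
#' `UNKNOWN` with probability `unknown_rate` or `MIXED` (half the span in
#' each language) with probability `mixed_rate`; because coupling copies
#' only identifiable single-language speech, these injections act as
#' ignorable missingness, mirroring the analysis's exclusion rules.
#' \eqn{\lambda = 0} realises the alignment test's null of independent
#' language selection.
#'
#' @param speaker_id,speaker_role identity and role
#'   (`TARGET_CHILD`/`PRIMARY_CAREGIVER`/`OTHER_HOUSEHOLD`).
#' @param base_rate_A probability of `LANG_A` when not coupling.
#' @param coupling copy probability \eqn{\lambda} in `[0, 1]`.
#' @param unknown_rate,mixed_rate relabelling probabilities; their sum
#'   must not exceed 1. Children's speech is far less identifiable than
#'   adults' in home recordings of this age range, so child configs
#'   typically use a much higher `unknown_rate` (see
#'   [synthetic_dyad_config()] defaults).
#' @param duration_ms_range integer range for uniform utterance durations.
#' @return object of class `speaker_config`.
#' @export
speaker_config <- function(speaker_id, speaker_role = "PRIMARY_CAREGIVER",
                           base_rate_A = 0.5, coupling = 0,
                           unknown_rate = 0, mixed_rate = 0,
                           duration_ms_range = c(500, 3000)) {
  stopifnot(speaker_role %in% ROLES)
  probs <- c(base_rate_A, coupling, unknown_rate, mixed_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (unknown_rate + mixed_rate > 1) {
    stop("unknown_rate + mixed_rate must not exceed 1", call. = FALSE)
  }
  if (length(duration_ms_range) != 2L ||
      any(duration_ms_range <= 0) ||
      duration_ms_range[2L] < duration_ms_range[1L]) {
    stop("duration_ms_range must be a positive (min, max) pair",
         call. = FALSE)
  }
  structure(list(speaker_id = speaker_id, speaker_role = speaker_role,
                 base_rate_A = base_rate_A, coupling = coupling,
                 unknown_rate = unknown_rate, mixed_rate = mixed_rate,
                 duration_ms_range = as.integer(duration_ms_range)),
            class = "speaker_config")
}

#' Synthetic session configuration
#'
#' Bundles the speakers and sequencing model of one simulated play
#' session. With `speaker_sequence = "ALTERNATING"` (exactly 2 speakers)
#' the two speakers strictly alternate; with `"MARKOV"` the next speaker
#' is drawn from `transition` (rows summing to 1, uniform start).
#'
#' @param n_utterances number of utterances to generate (default 200, on
#'   the order of a talkative 20-minute free-play session).
#' @param speakers list of [speaker_config()] objects.
#' @param speaker_sequence `"ALTERNATING"` or `"MARKOV"`.
#' @param transition square transition matrix over speakers (MARKOV only).
#' @param gap_ms_range integer range for uniform inter-utterance gaps.
#' @param seed optional integer seed for [generate_session()].
#' @param session_id,family_id,community,session_type,child_age_months
#'   metadata for the generated [session_record()].
#' @return object of class `session_config`.
#' @export
session_config <- function(n_utterances = 200, speakers,
                           speaker_sequence = c("ALTERNATING", "MARKOV"),
                           transition = NULL, gap_ms_range = c(200, 1500),
                           seed = NULL, session_id = "synthetic",
                           family_id = "fam01",
                           community = "FRENCH_ENGLISH", session_type = "A",
                           child_age_months = 24) {
  speaker_sequence <- match.arg(speaker_sequence)
  stopifnot(n_utterances >= 1,
            all(vapply(speakers, inherits, logical(1L), "speaker_config")))
  if (speaker_sequence == "ALTERNATING" && length(speakers) != 2L) {
    stop("ALTERNATING requires exactly 2 speakers", call. = FALSE)
  }
  if (speaker_sequence == "MARKOV") {
    if (is.null(transition) ||
        !is.matrix(transition) ||
        nrow(transition) != length(speakers) ||
        ncol(transition) != length(speakers) ||
        any(abs(rowSums(transition) - 1) > 1e-8)) {
      stop("MARKOV requires a square transition matrix with rows summing",
           " to 1", call. = FALSE)
    }
  }
  if (length(gap_ms_range) != 2L || gap_ms_range[2L] < gap_ms_range[1L] ||
      any(gap_ms_range < 0)) {
    stop("gap_ms_range must be a non-negative (min, max) pair",
         call. = FALSE)
  }
  structure(list(n_utterances = as.integer(n_utterances),
                 speakers = speakers, speaker_sequence = speaker_sequence,
                 transition = transition,
                 gap_ms_range = as.integer(gap_ms_range), seed = seed,
                 session_id = session_id, family_id = family_id,
                 community = community, session_type = session_type,
                 child_age_months = child_age_months),
            class = "session_config")
}

#' Default dyadic configuration emulating the study conditions
#'
#' Convenience constructor for a caregiver-child dyad: alternating
#' speakers, shared coupling and base rates, and unidentifiability rates
#' matching what home recordings of toddlers show — caregiver speech
#' almost always identifiable (default `caregiver_unknown_rate = 0.08`),
#' child speech identifiable well under half the time (default
#' `child_unknown_rate = 0.55`), with a small rate of mixed-language
#' utterances.
#'
#' @param base_rate_A `P(LANG_A)` for both speakers when not coupling.
#' @param coupling alignment strength \eqn{\lambda} for both speakers.
#' @param n_utterances utterances per session.
#' @param child_unknown_rate,caregiver_unknown_rate,mixed_rate relabelling
#'   rates.
#' @param seed,... passed through to [session_config()].
#' @return a `session_config`.
#' @export
synthetic_dyad_config <- function(base_rate_A = 0.5, coupling = 0,
                                  n_utterances = 200,
                                  child_unknown_rate = 0.55,
                                  caregiver_unknown_rate = 0.08,
                                  mixed_rate = 0.05, seed = NULL, ...) {
  session_config(
    n_utterances = n_utterances,
    speakers = list(
      speaker_config("CG1", "PRIMARY_CAREGIVER", base_rate_A = base_rate_A,
                     coupling = coupling,
                     unknown_rate = caregiver_unknown_rate,
                     mixed_rate = mixed_rate),
      speaker_config("CHI", "TARGET_CHILD", base_rate_A = base_rate_A,
                     coupling = coupling,
                     unknown_rate = child_unknown_rate,
                     mixed_rate = mixed_rate)),
    seed = seed, ...)
}

#' Generate one synthetic session
#'
#' Simulates the utterance stream described in [speaker_config()]: the
#' speaker sequence follows the configured model; each utterance copies
#' the most recent identifiable other-speaker language with the speaker's
#' coupling probability, otherwise draws from its base rate; unknown/mixed
#' relabelling is applied afterwards. Onsets strictly increase with
#' uniform gaps and durations. The same seed reproduces the session
#' exactly.
#'
#' @param config a [session_config()].
#' @return a [session_record()].
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  with_seed(config$seed, {
    n <- config$n_utterances
    k <- length(config$speakers)
    sp_idx <- integer(n)
    if (config$speaker_sequence == "ALTERNATING") {
      sp_idx <- rep_len(c(1L, 2L), n)
    } else {
      sp_idx[1L] <- sample.int(k, 1L)
      for (t in seq_len(n)[-1L]) {
        sp_idx[t] <- sample.int(k, 1L,
                                prob = config$transition[sp_idx[t - 1L], ])
      }
    }
    # last identifiable single language and its time per speaker; the
    # coupling target is the most recent identifiable *other* speaker
    last_lang <- rep(NA_character_, k)
    last_t <- rep(-1L, k)
    lang <- character(n)
    status <- character(n)
    for (t in seq_len(n)) {
      s <- config$speakers[[sp_idx[t]]]
      others <- setdiff(seq_len(k), sp_idx[t])
      others <- others[!is.na(last_lang[others])]
      recent <- if (length(others)) {
        last_lang[others[which.max(last_t[others])]]
      } else {
        NA_character_
      }
      lang[t] <- if (!is.na(recent) && runif(1L) < s$coupling) {
        recent
      } else if (runif(1L) < s$base_rate_A) "LANG_A" else "LANG_B"
      u <- runif(1L)
      status[t] <- if (u < s$unknown_rate) "UNKNOWN" else
        if (u < s$unknown_rate + s$mixed_rate) "MIXED" else "SINGLE"
      if (status[t] == "SINGLE") {
        last_lang[sp_idx[t]] <- lang[t]
        last_t[sp_idx[t]] <- t
      }
    }

    gaps <- sample(config$gap_ms_range[1L]:config$gap_ms_range[2L], n,
                   replace = TRUE)
    durs <- vapply(seq_len(n), function(t) {
      r <- config$speakers[[sp_idx[t]]]$duration_ms_range
      sample(r[1L]:r[2L], 1L)
    }, integer(1L))
    onsets <- cumsum(gaps) + c(0L, cumsum(durs)[-n])
    offsets <- onsets + durs

    ids <- sprintf("u%05d", seq_len(n))
    utterances <- data.frame(
      utterance_id = ids,
      speaker_id = vapply(config$speakers[sp_idx], `[[`, character(1L),
                          "speaker_id"),
      onset_ms = as.integer(onsets), offset_ms = as.integer(offsets),
      transcript = NA_character_, stringsAsFactors = FALSE)

    seg_rows <- lapply(seq_len(n), function(t) {
      if (status[t] == "UNKNOWN") return(NULL)
      if (status[t] == "MIXED") {
        mid <- as.integer(onsets[t] + durs[t] %/% 2L)
        return(data.frame(
          utterance_id = ids[c(t, t)],
          language = c(lang[t], other_lang(lang[t])),
          onset_ms = c(as.integer(onsets[t]), mid),
          offset_ms = c(mid, as.integer(offsets[t])),
          stringsAsFactors = FALSE))
      }
      data.frame(utterance_id = ids[t], language = lang[t],
                 onset_ms = as.integer(onsets[t]),
                 offset_ms = as.integer(offsets[t]),
                 stringsAsFactors = FALSE)
    })
    segments <- do.call(rbind, Filter(Negate(is.null), seg_rows))
    if (is.null(segments)) {
      segments <- data.frame(utterance_id = character(),
                             language = character(), onset_ms = integer(),
                             offset_ms = integer(), stringsAsFactors = FALSE)
    }
    roster <- setNames(
      vapply(config$speakers, `[[`, character(1L), "speaker_role"),
      vapply(config$speakers, `[[`, character(1L), "speaker_id"))
    session_record(session_id = config$session_id,
                   family_id = config$family_id,
                   community = config$community,
                   session_type = config$session_type,
                   utterances = utterances, segments = segments,
                   roster = roster,
                   child_age_months = config$child_age_months)
  })
}

#' Generate a cohort of independent synthetic sessions
#'
#' Draws one configuration per family from `config_sampler` and generates
#' each session under a per-family sub-seed derived from the master seed,
#' so the whole cohort is reproducible from `seed` alone.
#'
#' @param n_families number of families.
#' @param config_sampler function of the family index returning a
#'   [session_config()]; it is called with the master-seeded RNG active,
#'   so random configuration draws are reproducible too. A seed already
#'   set inside the returned config is respected.
#' @param seed master integer seed.
#' @return list of [session_record()] objects with family ids
#'   `fam001, fam002, ...`.
#' @export
generate_cohort <- function(n_families, config_sampler, seed = NULL) {
  stopifnot(n_families >= 1)
  with_seed(seed, {
    lapply(seq_len(n_families), function(i) {
      cfg <- config_sampler(i)
      stopifnot(inherits(cfg, "session_config"))
      if (is.null(cfg$seed)) {
        cfg$seed <- sample.int(.Machine$integer.max - 1L, 1L)
      }
      if (identical(cfg$family_id, "fam01")) {
        cfg$family_id <- sprintf("fam%03d", i)
      }
      if (identical(cfg$session_id, "synthetic")) {
        cfg$session_id <- sprintf("fam%03d_%s", i, cfg$session_type)
      }
      generate_session(cfg)
    })
  })
}

#' Moment-based coupling estimator
#'
#' Inverts the generative model `E[match] = lambda + (1 - lambda) * m0`,
#' where `m0` is the analytic independence match rate of the series'
#' empirical language marginals: `lambda_hat = (rate - m0) / (1 - m0)`.
#' The estimate equals 0 exactly when the observed rate equals the
#' independence rate (a kappa-like chance correction) and 1 when every
#' turn matches. The raw value is reported alongside a `[-1, 1]`-clipped
#' one. Recovery is unbiased under balanced base rates; strongly
#' asymmetric preferences shift the response marginal toward the partner's
#' and bias the moment estimator.
#'
#' @param series a `turn_series` with at least one turn.
#' @return object of class `coupling_estimate`: list with `lambda`
#'   (clipped), `lambda_raw`, `m0`, `observed_rate`, `n_turns`.
#' @export
estimate_coupling <- function(series) {
  s <- summarize_turns(series)
  if (s$n_turns < 1L) stop("turn series has no turns", call. = FALSE)
  m0 <- expected_rate_analytic(s$prev_counts / s$n_turns,
                               s$resp_counts / s$n_turns)
  if (m0 >= 1 - 1e-12) {
    stop("degenerate marginals: independence rate is 1, coupling ",
         "estimator undefined", call. = FALSE)
  }
  raw <- (s$match_rate - m0) / (1 - m0)
  structure(list(lambda = min(1, max(-1, raw)), lambda_raw = raw,
                 m0 = m0, observed_rate = s$match_rate,
                 n_turns = s$n_turns),
            class = "coupling_estimate")
}

#' @export
print.coupling_estimate <- function(x, ...) {
  cat(sprintf(
    "<coupling_estimate> lambda = %.3f (raw %.3f), m0 = %.3f, %d turns\n",
    x$lambda, x$lambda_raw, x$m0, x$n_turns))
  invisible(x)
}
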