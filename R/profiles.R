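#' Classify each utterance by language content
#'
#' An utterance is `LANG_A` or `LANG_B` when all of its identifiable
#' segment time lies in that single language, `MIXED` when it contains
#' identifiable segments of both languages, and `UNKNOWN` when it has no
#' identifiable segment time at all (empty segment list or only `UNKNOWN`
#' spans).
#'
#' @param session a [session_record()].
#' @return character vector named by `utterance_id`, in the session's
#'   utterance order, with values `LANG_A`, `LANG_B`, `MIXED`, `UNKNOWN`.
#' @export
classify_utterances <- function(session) {
  stopifnot(inherits(session, "session_record"))
  u <- session$utterances
  s <- session$segments
  ms <- matrix(0, nrow = nrow(u), ncol = 2L,
               dimnames = list(u$utterance_id, LANGS))
  s <- s[s$language %in% LANGS, , drop = FALSE]
  if (nrow(s)) {
    dur <- s$offset_ms - s$onset_ms
    for (l in LANGS) {
      sel <- s$language == l
      if (any(sel)) {
        agg <- tapply(dur[sel], s$utterance_id[sel], sum)
        ms[names(agg), l] <- agg
      }
    }
  }
  out <- ifelse(ms[, "LANG_A"] > 0 & ms[, "LANG_B"] > 0, "MIXED",
         ifelse(ms[, "LANG_A"] > 0, "LANG_A",
         ifelse(ms[, "LANG_B"] > 0, "LANG_B", "UNKNOWN")))
  setNames(as.character(out), u$utterance_id)
}

#' Per-speaker language-use profile
#'
#' Profiles are time-weighted: the proportion of each language is the
#' speaking time in that language divided by the speaker's total
#' identifiable speech time, while `identifiable_prop` divides identifiable
#' time by total utterance time. Time not covered by an identifiable
#' segment counts as `UNKNOWN`. Undefined quantities are reported as `NA`,
#' never `0`: a speaker with no utterances has an undefined
#' `identifiable_prop`, and a speaker with no identifiable speech has
#' undefined language proportions (but `identifiable_prop = 0`).
#'
#' @param session a [session_record()].
#' @param speaker_id a speaker in the session roster.
#' @return object of class `speaker_profile`: a list with `speaker_id`,
#'   `speaker_role`, `n_utterances`, `total_speech_ms`, `ms_by_language`
#'   (named over `LANG_A`, `LANG_B`, `UNKNOWN`), `prop_language` (named
#'   over `LANG_A`, `LANG_B`) and `identifiable_prop`.
#' @export
speaker_profile <- function(session, speaker_id) {
  stopifnot(inherits(session, "session_record"))
  if (!speaker_id %in% names(session$roster)) {
    stop("speaker not in roster: ", speaker_id, call. = FALSE)
  }
  u <- session$utterances[session$utterances$speaker_id == speaker_id, ,
                          drop = FALSE]
  s <- session$segments[session$segments$utterance_id %in% u$utterance_id &
                          session$segments$language %in% LANGS, ,
                        drop = FALSE]
  total <- sum(u$offset_ms - u$onset_ms)
  by_lang <- setNames(numeric(2L), LANGS)
  if (nrow(s)) {
    agg <- tapply(s$offset_ms - s$onset_ms, s$language, sum)
    by_lang[names(agg)] <- agg
  }
  ident <- sum(by_lang)
  props <- if (ident > 0) by_lang / ident else setNames(rep(NA_real_, 2L),
                                                        LANGS)
  structure(
    list(speaker_id = speaker_id,
         speaker_role = session$roster[[speaker_id]],
         n_utterances = nrow(u),
         total_speech_ms = total,
         ms_by_language = c(by_lang, UNKNOWN = total - ident),
         prop_language = props,
         identifiable_prop = if (total > 0) ident / total else NA_real_),
    class = "speaker_profile")
}

#' @export
print.speaker_profile <- function(x, ...) {
  cat(sprintf("<speaker_profile> %s [%s]\n", x$speaker_id, x$speaker_role))
  cat(sprintf("  %d utterances, %.1f s speech, identifiable %s\n",
              x$n_utterances, x$total_speech_ms / 1000,
              ifelse(is.na(x$identifiable_prop), "undefined",
                     sprintf("%.1f%%", 100 * x$identifiable_prop))))
  pa <- x$prop_language[["LANG_A"]]
  cat(sprintf("  LANG_A share of identifiable speech: %s\n",
              ifelse(is.na(pa), "undefined", sprintf("%.1f%%", 100 * pa))))
  invisible(x)
}

#' All speaker profiles of a session as a data frame
#'
#' @param session a [session_record()].
#' @return data frame, one row per roster speaker, with columns
#'   `session_id`, `family_id`, `community`, `session_type`, `speaker_id`,
#'   `speaker_role`, `n_utterances`, `total_speech_ms`, `ms_lang_a`,
#'   `ms_lang_b`, `ms_unknown`, `prop_lang_a`, `prop_lang_b`,
#'   `identifiable_prop`.
#' @export
speaker_profiles <- function(session) {
  rows <- lapply(names(session$roster), function(sp) {
    p <- speaker_profile(session, sp)
    data.frame(
      session_id = session$session_id, family_id = session$family_id,
      community = session$community, session_type = session$session_type,
      speaker_id = sp, speaker_role = p$speaker_role,
      n_utterances = p$n_utterances, total_speech_ms = p$total_speech_ms,
      ms_lang_a = unname(p$ms_by_language[["LANG_A"]]),
      ms_lang_b = unname(p$ms_by_language[["LANG_B"]]),
      ms_unknown = unname(p$ms_by_language[["UNKNOWN"]]),
      prop_lang_a = unname(p$prop_language[["LANG_A"]]),
      prop_lang_b = unname(p$prop_language[["LANG_B"]]),
      identifiable_prop = p$identifiable_prop,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary of language use
#'
#' Summarises speakers' `LANG_A` proportions (share of identifiable speech
#' time) and identifiable-speech proportions across sessions, grouped by
#' any of `community`, `session_type`, `speaker_role`. The layout mirrors a
#' by-community/session/speaker table of means, SDs and ranges. Within a
#' session, other-household speakers are first averaged into a single value
#' so that multi-member households contribute one observation, and each
#' family contributes one value per speaker per session (families weighted
#' equally). Undefined proportions (speakers with no identifiable speech)
#' are excluded from the statistics; `n` counts the values actually
#' entering them. Groups with `n <= 1` report `NA` SD; empty groups report
#' `n = 0` and `NA` statistics.
#'
#' @param sessions list of [session_record()] objects.
#' @param group_by character subset of
#'   `c("community", "session_type", "speaker_role")`.
#' @return data frame with the group keys and columns `n`, `mean_prop_a`,
#'   `sd_prop_a`, `min_prop_a`, `max_prop_a`, `mean_identifiable`,
#'   `sd_identifiable`, `min_identifiable`, `max_identifiable`.
#' @export
usage_summary <- function(sessions,
                          group_by = c("community", "session_type",
                                       "speaker_role")) {
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1L)
  group_by <- match.arg(group_by,
                        c("community", "session_type", "speaker_role"),
                        several.ok = TRUE)
  prof <- do.call(rbind, lapply(sessions, speaker_profiles))

  # collapse other-household members to one value per session
  collapse <- function(df) {
    other <- df$speaker_role == "OTHER_HOUSEHOLD"
    if (!any(other)) return(df)
    oth <- df[other, , drop = FALSE]
    keep <- df[!other, , drop = FALSE]
    mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else
      mean(x, na.rm = TRUE)
    agg <- oth[1L, , drop = FALSE]
    agg$speaker_id <- "OTHER_HOUSEHOLD(pooled)"
    agg$prop_lang_a <- mean_or_na(oth$prop_lang_a)
    agg$prop_lang_b <- mean_or_na(oth$prop_lang_b)
    agg$identifiable_prop <- mean_or_na(oth$identifiable_prop)
    rbind(keep, agg)
  }
  prof <- do.call(rbind, lapply(split(prof, prof$session_id), collapse))

  levels_of <- list(
    community = sort(unique(prof$community)),
    session_type = sort(unique(prof$session_type)),
    speaker_role = ROLES)
  grid <- expand.grid(levels_of[group_by], stringsAsFactors = FALSE)
  names(grid) <- group_by

  stat_row <- function(sel) {
    pa <- prof$prop_lang_a[sel]
    pa <- pa[!is.na(pa)]
    id <- prof$identifiable_prop[sel]
    id <- id[!is.na(id)]
    safe <- function(f, x) if (length(x) == 0L) NA_real_ else f(x)
    data.frame(
      n = length(pa),
      mean_prop_a = safe(mean, pa),
      sd_prop_a = if (length(pa) > 1L) sd(pa) else NA_real_,
      min_prop_a = safe(min, pa), max_prop_a = safe(max, pa),
      mean_identifiable = safe(mean, id),
      sd_identifiable = if (length(id) > 1L) sd(id) else NA_real_,
      min_identifiable = safe(min, id), max_identifiable = safe(max, id))
  }
  stats <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- rep(TRUE, nrow(prof))
    for (g in group_by) sel <- sel & prof[[g]] == grid[[g]][i]
    stat_row(sel)
  }))
  out <- cbind(grid, stats)
  rownames(out) <- NULL
  out
}
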