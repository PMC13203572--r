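#' Construct a session record
#'
#' A session record holds the annotations of one recorded play session: an
#' utterance table, a language-segment table, and a speaker roster. Times are
#' integer milliseconds on half-open intervals `[onset, offset)`, so segment
#' durations sum exactly. Languages use the community-neutral tokens
#' `LANG_A` (the shared community language, English in both study
#' communities), `LANG_B` (French or Spanish depending on community) and
#' `UNKNOWN`. An utterance with no segment rows is wholly unidentifiable.
#'
#' The constructor checks structure (required columns, types); content
#' invariants such as non-overlapping segments or roster role rules are
#' reported — never raised — by [validate_session()].
#'
#' @param session_id,family_id character scalars identifying the session and
#'   family.
#' @param community one of `"FRENCH_ENGLISH"`, `"SPANISH_ENGLISH"`.
#' @param session_type `"A"` (child with primary caregiver only) or `"B"`
#'   (additional household members present).
#' @param utterances data frame with columns `utterance_id`, `speaker_id`,
#'   `onset_ms`, `offset_ms` and optionally `transcript`.
#' @param segments data frame with columns `utterance_id`, `language`
#'   (`LANG_A`/`LANG_B`/`UNKNOWN`), `onset_ms`, `offset_ms`. May have zero
#'   rows.
#' @param roster named character vector mapping `speaker_id` to a role among
#'   `TARGET_CHILD`, `PRIMARY_CAREGIVER`, `OTHER_HOUSEHOLD`.
#' @param child_age_months optional numeric age of the target child.
#' @return An object of class `session_record`.
#' @export
session_record <- function(session_id, family_id, community, session_type,
                           utterances, segments, roster,
                           child_age_months = NA_real_) {
  stopifnot(is.character(session_id), length(session_id) == 1L,
            is.character(family_id), length(family_id) == 1L)
  if (!community %in% COMMUNITIES) {
    stop("unknown community token: ", community, call. = FALSE)
  }
  if (!session_type %in% SESSION_TYPES) {
    stop("unknown session_type token: ", session_type, call. = FALSE)
  }
  utterances <- as.data.frame(utterances, stringsAsFactors = FALSE)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  need_u <- c("utterance_id", "speaker_id", "onset_ms", "offset_ms")
  miss <- setdiff(need_u, names(utterances))
  if (length(miss)) stop("utterances missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"transcript" %in% names(utterances)) {
    utterances$transcript <- NA_character_
  }
  need_s <- c("utterance_id", "language", "onset_ms", "offset_ms")
  if (nrow(segments) == 0L) {
    segments <- data.frame(utterance_id = character(), language = character(),
                           onset_ms = integer(), offset_ms = integer(),
                           stringsAsFactors = FALSE)
  }
  miss <- setdiff(need_s, names(segments))
  if (length(miss)) stop("segments missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(segments$language), LANG_TOKENS)
  if (length(bad)) stop("unknown language token(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(as.character(roster)), ROLES)
  if (length(bad)) stop("unknown speaker role token(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(utterances$utterance_id)) {
    stop("duplicate utterance_id in utterances", call. = FALSE)
  }
  utterances$onset_ms <- as.integer(utterances$onset_ms)
  utterances$offset_ms <- as.integer(utterances$offset_ms)
  segments$onset_ms <- as.integer(segments$onset_ms)
  segments$offset_ms <- as.integer(segments$offset_ms)
  utterances <- utterances[order(utterances$onset_ms, utterances$offset_ms,
                                 utterances$speaker_id,
                                 utterances$utterance_id),
                           c(need_u, "transcript"), drop = FALSE]
  segments <- segments[order(match(segments$utterance_id,
                                   utterances$utterance_id),
                             segments$onset_ms), need_s, drop = FALSE]
  rownames(utterances) <- NULL
  rownames(segments) <- NULL
  roster <- setNames(as.character(roster), names(roster))
  roster <- roster[order(names(roster))]
  structure(
    list(session_id = session_id, family_id = family_id,
         community = community, session_type = session_type,
         child_age_months = as.numeric(child_age_months),
         utterances = utterances, segments = segments, roster = roster),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "<session_record> %s (family %s, %s, session %s)\n",
    x$session_id, x$family_id, x$community, x$session_type))
  cat(sprintf("  %d utterances, %d language segments, %d speakers\n",
              nrow(x$utterances), nrow(x$segments), length(x$roster)))
  for (sp in names(x$roster)) {
    n <- sum(x$utterances$speaker_id == sp)
    cat(sprintf("    %s [%s]: %d utterances\n", sp, x$roster[[sp]], n))
  }
  invisible(x)
}

issue_df <- function(kind = character(), utterance_id = character(),
                     detail = character()) {
  data.frame(kind = kind, utterance_id = utterance_id, detail = detail,
             stringsAsFactors = FALSE)
}

#' Validate a session record's content invariants
#'
#' Checks the content rules a well-formed session must satisfy and returns a
#' machine-readable issue table. Validation never raises on content: a fully
#' valid session yields a zero-row data frame.
#'
#' Issue kinds: `negative_duration` (utterance or segment with
#' `offset <= onset`), `segment_overlap` (overlapping segments within one
#' utterance), `segment_outside` (segment span outside its utterance span),
#' `orphan_segment` (segment referencing no utterance), `unknown_speaker`
#' (utterance speaker absent from the roster), `duplicate_target_child` /
#' `missing_target_child` (roster must name exactly one target child), and
#' `role_violation` (session type A with other-household speech or without
#' exactly one speaking primary caregiver).
#'
#' @param session a [session_record()].
#' @return data frame with columns `kind`, `utterance_id`, `detail`.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "session_record"))
  u <- session$utterances
  s <- session$segments
  issues <- list()
  add <- function(kind, uid, detail) {
    issues[[length(issues) + 1L]] <<- issue_df(kind, uid, detail)
  }

  bad <- u$offset_ms <= u$onset_ms
  for (i in which(bad)) {
    add("negative_duration", u$utterance_id[i],
        sprintf("utterance span [%d, %d)", u$onset_ms[i], u$offset_ms[i]))
  }
  bad <- s$offset_ms <= s$onset_ms
  for (i in which(bad)) {
    add("negative_duration", s$utterance_id[i],
        sprintf("segment span [%d, %d)", s$onset_ms[i], s$offset_ms[i]))
  }

  orphan <- !s$utterance_id %in% u$utterance_id
  for (uid in unique(s$utterance_id[orphan])) {
    add("orphan_segment", uid, "segment references unknown utterance")
  }

  for (uid in unique(s$utterance_id[!orphan])) {
    seg <- s[s$utterance_id == uid, , drop = FALSE]
    seg <- seg[order(seg$onset_ms), , drop = FALSE]
    span <- u[u$utterance_id == uid, , drop = FALSE]
    out <- seg$onset_ms < span$onset_ms | seg$offset_ms > span$offset_ms
    if (any(out)) {
      add("segment_outside", uid,
          sprintf("%d segment(s) outside utterance span", sum(out)))
    }
    if (nrow(seg) > 1L &&
        any(seg$onset_ms[-1L] < seg$offset_ms[-nrow(seg)])) {
      add("segment_overlap", uid, "overlapping segments within utterance")
    }
  }

  unk <- !u$speaker_id %in% names(session$roster)
  for (uid in u$utterance_id[unk]) {
    add("unknown_speaker", uid, "speaker_id not in roster")
  }

  n_child <- sum(session$roster == "TARGET_CHILD")
  if (n_child > 1L) {
    add("duplicate_target_child", NA_character_,
        sprintf("%d speakers labelled TARGET_CHILD", n_child))
  } else if (n_child == 0L) {
    add("missing_target_child", NA_character_, "no TARGET_CHILD in roster")
  }

  if (session$session_type == "A") {
    speaking <- unique(u$speaker_id)
    speaking <- speaking[speaking %in% names(session$roster)]
    roles <- session$roster[speaking]
    if (any(roles == "OTHER_HOUSEHOLD")) {
      add("role_violation", NA_character_,
          "OTHER_HOUSEHOLD speech in a session_type A record")
    }
    if (sum(roles == "PRIMARY_CAREGIVER") != 1L && length(speaking) > 0L) {
      add("role_violation", NA_character_,
          sprintf("session_type A has %d speaking primary caregiver(s)",
                  sum(roles == "PRIMARY_CAREGIVER")))
    }
  }

  if (length(issues)) do.call(rbind, issues) else issue_df()
}
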