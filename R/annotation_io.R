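CANONICAL_COLS <- c("session_id", "family_id", "community", "session_type",
                    "speaker_id", "speaker_role", "utterance_id", "onset_ms",
                    "offset_ms", "language", "seg_onset_ms", "seg_offset_ms",
                    "transcript")

#' Read session records from the canonical utterance table
#'
#' The canonical table is a UTF-8 delimited file (tab by default) with one
#' row per language segment. Utterances with no identifiable language carry
#' a single row with `language = UNKNOWN` spanning the whole utterance; on
#' read, such rows become an utterance with an empty segment list. Required
#' columns: `session_id`, `family_id`, `community`, `session_type`,
#' `speaker_id`, `speaker_role`, `utterance_id`, `onset_ms`, `offset_ms`,
#' `language`, `seg_onset_ms`, `seg_offset_ms`, `transcript`; an optional
#' `child_age_months` column is carried through.
#'
#' @param path path to the delimited file.
#' @param delim field delimiter, `"\t"` by default.
#' @return list of [session_record()] objects, one per distinct
#'   `session_id`, in order of first appearance.
#' @seealso [write_utterance_table()] for the inverse; the two are exact
#'   round-trip inverses on valid records.
#' @export
read_utterance_table <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = delim, colClasses = "character",
                    check.names = FALSE, quote = "", na.strings = NULL,
                    fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  miss <- setdiff(CANONICAL_COLS, names(raw))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) return(list())

  num_cols <- c("onset_ms", "offset_ms", "seg_onset_ms", "seg_offset_ms")
  for (cc in num_cols) {
    v <- suppressWarnings(as.integer(raw[[cc]]))
    if (anyNA(v)) {
      stop(sprintf("row %d: non-numeric %s value '%s'",
                   which(is.na(v))[1L], cc, raw[[cc]][which(is.na(v))[1L]]),
           call. = FALSE)
    }
    raw[[cc]] <- v
  }
  check_enum <- function(col, tokens) {
    bad <- which(!raw[[col]] %in% tokens)
    if (length(bad)) {
      stop(sprintf("row %d: unknown %s token '%s'", bad[1L], col,
                   raw[[col]][bad[1L]]), call. = FALSE)
    }
  }
  check_enum("language", LANG_TOKENS)
  check_enum("speaker_role", ROLES)
  check_enum("community", COMMUNITIES)
  check_enum("session_type", SESSION_TYPES)
  bad <- which(raw$offset_ms <= raw$onset_ms)
  if (length(bad)) {
    stop(sprintf("row %d: utterance offset_ms <= onset_ms", bad[1L]),
         call. = FALSE)
  }
  bad <- which(raw$seg_offset_ms <= raw$seg_onset_ms)
  if (length(bad)) {
    stop(sprintf("row %d: segment seg_offset_ms <= seg_onset_ms", bad[1L]),
         call. = FALSE)
  }

  has_age <- "child_age_months" %in% names(raw)
  lapply(split(raw, factor(raw$session_id, levels = unique(raw$session_id))),
         function(rr) {
    first <- !duplicated(rr$utterance_id)
    utt <- data.frame(
      utterance_id = rr$utterance_id[first],
      speaker_id = rr$speaker_id[first],
      onset_ms = rr$onset_ms[first],
      offset_ms = rr$offset_ms[first],
      transcript = rr$transcript[first],
      stringsAsFactors = FALSE)
    utt$transcript[utt$transcript == ""] <- NA_character_
    # a lone full-span UNKNOWN row is the encoding of "no segments"
    placeholder <- rr$language == "UNKNOWN" &
      rr$seg_onset_ms == rr$onset_ms & rr$seg_offset_ms == rr$offset_ms &
      rr$utterance_id %in% names(which(table(rr$utterance_id) == 1L))
    seg <- rr[!placeholder, c("utterance_id", "language", "seg_onset_ms",
                              "seg_offset_ms"), drop = FALSE]
    names(seg) <- c("utterance_id", "language", "onset_ms", "offset_ms")
    roster_rows <- !duplicated(rr$speaker_id)
    conflicting <- tapply(rr$speaker_role, rr$speaker_id,
                          function(x) length(unique(x)))
    if (any(conflicting > 1L)) {
      stop("speaker with conflicting roles in session ", rr$session_id[1L],
           call. = FALSE)
    }
    age <- if (has_age) {
      v <- rr$child_age_months[1L]
      if (identical(v, "") || is.na(v)) NA_real_ else as.numeric(v)
    } else NA_real_
    session_record(
      session_id = rr$session_id[1L], family_id = rr$family_id[1L],
      community = rr$community[1L], session_type = rr$session_type[1L],
      utterances = utt, segments = seg,
      roster = setNames(rr$speaker_role[roster_rows],
                        rr$speaker_id[roster_rows]),
      child_age_months = age)
  })
}

#' Write session records to the canonical utterance table
#'
#' One row per language segment; wholly unidentifiable utterances (empty
#' segment list) are written as a single `UNKNOWN` row spanning the
#' utterance. Rows are ordered deterministically by session, utterance
#' onset, utterance id, then segment onset, so identical inputs produce
#' byte-identical files.
#'
#' @param sessions a [session_record()] or list of them.
#' @param path output file path.
#' @param delim field delimiter, `"\t"` by default.
#' @return `path`, invisibly.
#' @export
write_utterance_table <- function(sessions, path, delim = "\t") {
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    u <- s$utterances
    if (nrow(u) == 0L) return(NULL)
    per_utt <- lapply(seq_len(nrow(u)), function(i) {
      seg <- s$segments[s$segments$utterance_id == u$utterance_id[i], ,
                        drop = FALSE]
      if (nrow(seg) == 0L) {
        seg <- data.frame(utterance_id = u$utterance_id[i],
                          language = "UNKNOWN", onset_ms = u$onset_ms[i],
                          offset_ms = u$offset_ms[i],
                          stringsAsFactors = FALSE)
      }
      seg <- seg[order(seg$onset_ms), , drop = FALSE]
      data.frame(
        session_id = s$session_id, family_id = s$family_id,
        community = s$community, session_type = s$session_type,
        speaker_id = u$speaker_id[i],
        speaker_role = s$roster[[u$speaker_id[i]]],
        utterance_id = u$utterance_id[i],
        onset_ms = u$onset_ms[i], offset_ms = u$offset_ms[i],
        language = seg$language, seg_onset_ms = seg$onset_ms,
        seg_offset_ms = seg$offset_ms,
        transcript = ifelse(is.na(u$transcript[i]), "", u$transcript[i]),
        child_age_months = ifelse(is.na(s$child_age_months), "",
                                  as.character(s$child_age_months)),
        stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, per_utt)
    df[order(df$onset_ms, df$utterance_id, df$seg_onset_ms), , drop = FALSE]
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    as.data.frame(setNames(
      rep(list(character()), length(CANONICAL_COLS) + 1L),
      c(CANONICAL_COLS, "child_age_months")), stringsAsFactors = FALSE)
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = delim, quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

default_language_map <- c(
  eng = "LANG_A", english = "LANG_A",
  fra = "LANG_B", fre = "LANG_B", french = "LANG_B",
  spa = "LANG_B", spanish = "LANG_B",
  unk = "UNKNOWN", unknown = "UNKNOWN")

#' Read one session from an ELAN EAF file
#'
#' Ingests an ELAN Annotation Format (XML) document. Each entry of
#' `tier_map` names one speech tier and its associated language tier; every
#' annotation on a speaker tier becomes an utterance and annotations on the
#' language tier become language segments of the utterance whose span
#' contains their midpoint (clipped to the utterance span). Utterances with
#' no language-tier coverage get an empty segment list (wholly
#' unidentifiable speech). Both alignable and (span-inheriting) reference
#' annotations are supported.
#'
#' @param path path to the `.eaf` file.
#' @param tier_map list of entries, each a list with elements
#'   `speaker_tier` (tier id of the speech tier), `speaker_id`,
#'   `speaker_role`, and optionally `language_tier` (tier id holding
#'   language labels for that speaker).
#' @param session_id,family_id,community,session_type,child_age_months
#'   session metadata (the EAF format does not carry these).
#' @param language_map named character vector mapping lowercased
#'   language-tier labels to `LANG_A`/`LANG_B`/`UNKNOWN`; labels not in the
#'   map are treated as `UNKNOWN`. The default maps English to `LANG_A` and
#'   French/Spanish to `LANG_B`.
#' @return a [session_record()].
#' @export
read_eaf <- function(path, tier_map, session_id, family_id, community,
                     session_type, child_age_months = NA_real_,
                     language_map = default_language_map) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)

  slots <- xml2::xml_find_all(doc, ".//TIME_ORDER/TIME_SLOT")
  slot_id <- xml2::xml_attr(slots, "TIME_SLOT_ID")
  slot_val <- suppressWarnings(as.integer(xml2::xml_attr(slots, "TIME_VALUE")))
  time_of <- function(ref, where) {
    i <- match(ref, slot_id)
    if (any(is.na(i)) || any(is.na(slot_val[i]))) {
      stop("unresolvable time reference in ", where, call. = FALSE)
    }
    slot_val[i]
  }

  tier_nodes <- xml2::xml_find_all(doc, ".//TIER")
  tier_ids <- xml2::xml_attr(tier_nodes, "TIER_ID")

  # annotation index across the whole document, needed to resolve
  # REF_ANNOTATION chains to a time span
  ali <- xml2::xml_find_all(doc, ".//ALIGNABLE_ANNOTATION")
  ali_id <- xml2::xml_attr(ali, "ANNOTATION_ID")
  ali_t0 <- time_of(xml2::xml_attr(ali, "TIME_SLOT_REF1"), "annotation")
  ali_t1 <- time_of(xml2::xml_attr(ali, "TIME_SLOT_REF2"), "annotation")
  refs <- xml2::xml_find_all(doc, ".//REF_ANNOTATION")
  ref_id <- xml2::xml_attr(refs, "ANNOTATION_ID")
  ref_parent <- xml2::xml_attr(refs, "ANNOTATION_REF")
  span_of <- function(id) {
    seen <- character()
    while (id %in% ref_id) {
      if (id %in% seen) stop("cyclic annotation reference", call. = FALSE)
      seen <- c(seen, id)
      id <- ref_parent[match(id, ref_id)]
    }
    i <- match(id, ali_id)
    if (is.na(i)) stop("unresolvable annotation reference: ", id,
                       call. = FALSE)
    c(ali_t0[i], ali_t1[i])
  }

  tier_annotations <- function(tier) {
    i <- match(tier, tier_ids)
    if (is.na(i)) {
      stop("tier named in tier_map not found in EAF: ", tier, call. = FALSE)
    }
    anns <- xml2::xml_find_all(tier_nodes[[i]],
                               ".//ALIGNABLE_ANNOTATION | .//REF_ANNOTATION")
    if (length(anns) == 0L) {
      return(data.frame(id = character(), t0 = integer(), t1 = integer(),
                        value = character(), stringsAsFactors = FALSE))
    }
    ids <- xml2::xml_attr(anns, "ANNOTATION_ID")
    spans <- vapply(ids, span_of, integer(2L))
    data.frame(
      id = ids, t0 = spans[1L, ], t1 = spans[2L, ],
      value = xml2::xml_text(
        xml2::xml_find_first(anns, ".//ANNOTATION_VALUE")),
      stringsAsFactors = FALSE)
  }

  utt_rows <- list()
  seg_rows <- list()
  roster <- character()
  for (entry in tier_map) {
    u <- tier_annotations(entry$speaker_tier)
    roster[entry$speaker_id] <- entry$speaker_role
    if (nrow(u) == 0L) next
    utt_rows[[length(utt_rows) + 1L]] <- data.frame(
      utterance_id = u$id, speaker_id = entry$speaker_id,
      onset_ms = u$t0, offset_ms = u$t1, transcript = u$value,
      stringsAsFactors = FALSE)
    if (!is.null(entry$language_tier)) {
      lg <- tier_annotations(entry$language_tier)
      if (nrow(lg) > 0L) {
        lang <- unname(language_map[tolower(lg$value)])
        lang[is.na(lang)] <- "UNKNOWN"
        mid <- (lg$t0 + lg$t1) / 2
        parent <- vapply(mid, function(m) {
          j <- which(u$t0 <= m & m < u$t1)
          if (length(j)) j[1L] else NA_integer_
        }, integer(1L))
        keep <- !is.na(parent)
        if (any(keep)) {
          seg_rows[[length(seg_rows) + 1L]] <- data.frame(
            utterance_id = u$id[parent[keep]], language = lang[keep],
            onset_ms = pmax(lg$t0[keep], u$t0[parent[keep]]),
            offset_ms = pmin(lg$t1[keep], u$t1[parent[keep]]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  utterances <- if (length(utt_rows)) do.call(rbind, utt_rows) else
    data.frame(utterance_id = character(), speaker_id = character(),
               onset_ms = integer(), offset_ms = integer(),
               transcript = character(), stringsAsFactors = FALSE)
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame(utterance_id = character(), language = character(),
               onset_ms = integer(), offset_ms = integer(),
               stringsAsFactors = FALSE)
  session_record(session_id = session_id, family_id = family_id,
                 community = community, session_type = session_type,
                 utterances = utterances, segments = segments,
                 roster = roster, child_age_months = child_age_months)
}
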