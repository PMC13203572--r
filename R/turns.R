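#' Deterministic global utterance order
#'
#' Utterances sorted by onset, with ties broken by offset, then
#' `speaker_id`, then `utterance_id` — a total, deterministic order.
#'
#' @param session a [session_record()].
#' @return the session's utterance data frame, reordered.
#' @export
order_utterances <- function(session) {
  stopifnot(inherits(session, "session_record"))
  u <- session$utterances
  u <- u[order(u$onset_ms, u$offset_ms, u$speaker_id, u$utterance_id), ,
         drop = FALSE]
  rownames(u) <- NULL
  u
}

empty_turns <- function() {
  data.frame(prev_utterance_id = character(),
             response_utterance_id = character(),
             prev_speaker_id = character(),
             response_speaker_id = character(),
             prev_language = character(), response_language = character(),
             match = logical(), gap_ms = integer(),
             stringsAsFactors = FALSE)
}

#' Build a turn series directly from language sequences
#'
#' Low-level constructor, mainly for simulation and testing: fabricates a
#' turn series from parallel vectors of previous-utterance and response
#' languages (each `LANG_A` or `LANG_B`).
#'
#' @param prev_language,response_language character vectors of equal
#'   length over `LANG_A`/`LANG_B`.
#' @param session_id,dyad,direction series metadata.
#' @return a `turn_series` object.
#' @export
turn_series <- function(prev_language, response_language,
                        session_id = "series", dyad = c("S1", "S2"),
                        direction = "POOLED") {
  stopifnot(length(prev_language) == length(response_language),
            all(prev_language %in% LANGS),
            all(response_language %in% LANGS),
            direction %in% DIRECTIONS)
  n <- length(prev_language)
  turns <- if (n == 0L) empty_turns() else data.frame(
    prev_utterance_id = sprintf("p%04d", seq_len(n)),
    response_utterance_id = sprintf("r%04d", seq_len(n)),
    prev_speaker_id = dyad[1L], response_speaker_id = dyad[2L],
    prev_language = as.character(prev_language),
    response_language = as.character(response_language),
    match = prev_language == response_language,
    gap_ms = 0L, stringsAsFactors = FALSE)
  structure(list(session_id = session_id, dyad = dyad,
                 direction = direction, turns = turns),
            class = "turn_series")
}

#' Extract dyadic conversational turns from a session
#'
#' A turn is an utterance by one dyad member immediately followed in the
#' global utterance order (see [order_utterances()]) by an utterance from
#' the other member, coded as a match if the response language equals the
#' previous utterance's language and a switch otherwise. Candidate turns
#' where either utterance is `MIXED` or `UNKNOWN` are dropped — but such
#' utterances still break adjacency, since they are real speech events.
#' Consecutive utterances by the same speaker never form turns.
#'
#' By default adjacency is strict: an utterance by any third speaker
#' between the two dyad utterances cancels the turn (the conservative
#' reading for multi-party sessions). Set `skip_third_party = TRUE` to pair
#' each dyad utterance with the dyad's next utterance even across
#' third-party speech (sensitivity analysis). With `chained = TRUE` (the
#' default) a response may serve as the previous utterance of the next
#' turn; `chained = FALSE` consumes it.
#'
#' @param session a [session_record()].
#' @param dyad character vector of two roster speaker ids. Defaults to the
#'   target child and the primary caregiver.
#' @param direction `"POOLED"` (both directions), `"CHILD_RESPONDS"` (only
#'   turns where the dyad's target child responds) or
#'   `"PARTNER_RESPONDS"`.
#' @param max_gap_ms drop turns whose response onset starts more than this
#'   many ms after the previous offset (default unlimited; negative gaps
#'   from overlapping speech are always kept).
#' @param skip_third_party,chained adjacency options, see Details.
#' @return object of class `turn_series`: list with `session_id`, `dyad`,
#'   `direction` and a `turns` data frame (one row per turn: utterance and
#'   speaker ids, languages, `match`, `gap_ms`), ordered by response onset.
#' @export
extract_turns <- function(session, dyad = NULL,
                          direction = c("POOLED", "CHILD_RESPONDS",
                                        "PARTNER_RESPONDS"),
                          max_gap_ms = Inf, skip_third_party = FALSE,
                          chained = TRUE) {
  stopifnot(inherits(session, "session_record"))
  direction <- match.arg(direction)
  if (is.null(dyad)) {
    dyad <- c(names(session$roster)[session$roster == "TARGET_CHILD"][1L],
              names(session$roster)[session$roster ==
                                      "PRIMARY_CAREGIVER"][1L])
  }
  if (length(dyad) != 2L || anyNA(dyad) ||
      !all(dyad %in% names(session$roster))) {
    stop("dyad members must be two speakers present in the roster",
         call. = FALSE)
  }
  responder <- NA_character_
  if (direction != "POOLED") {
    child <- dyad[session$roster[dyad] == "TARGET_CHILD"]
    if (length(child) != 1L) {
      stop("directional extraction requires the dyad to contain exactly ",
           "one TARGET_CHILD", call. = FALSE)
    }
    responder <- if (direction == "CHILD_RESPONDS") child else
      setdiff(dyad, child)
  }

  ord <- order_utterances(session)
  lang <- classify_utterances(session)[ord$utterance_id]

  in_dyad <- which(ord$speaker_id %in% dyad)
  rows <- list()
  last_resp <- -1L
  for (k in seq_along(in_dyad)[-1L]) {
    i <- in_dyad[k - 1L]
    j <- in_dyad[k]
    if (!skip_third_party && j != i + 1L) next
    if (ord$speaker_id[i] == ord$speaker_id[j]) next
    if (direction != "POOLED" && ord$speaker_id[j] != responder) next
    if (!chained && i == last_resp) next
    li <- lang[[i]]
    lj <- lang[[j]]
    if (!li %in% LANGS || !lj %in% LANGS) next
    gap <- ord$onset_ms[j] - ord$offset_ms[i]
    if (gap > max_gap_ms) next
    last_resp <- j
    rows[[length(rows) + 1L]] <- data.frame(
      prev_utterance_id = ord$utterance_id[i],
      response_utterance_id = ord$utterance_id[j],
      prev_speaker_id = ord$speaker_id[i],
      response_speaker_id = ord$speaker_id[j],
      prev_language = li, response_language = lj,
      match = li == lj, gap_ms = gap, stringsAsFactors = FALSE)
  }
  turns <- if (length(rows)) do.call(rbind, rows) else empty_turns()
  rownames(turns) <- NULL
  structure(list(session_id = session$session_id, dyad = dyad,
                 direction = direction, turns = turns),
            class = "turn_series")
}

#' @export
print.turn_series <- function(x, ...) {
  s <- summarize_turns(x)
  cat(sprintf("<turn_series> %s, dyad %s <-> %s, direction %s\n",
              x$session_id, x$dyad[1L], x$dyad[2L], x$direction))
  cat(sprintf("  %d turns, %d matches (rate %s)\n", s$n_turns, s$n_match,
              ifelse(is.na(s$match_rate), "undefined",
                     sprintf("%.3f", s$match_rate))))
  invisible(x)
}

#' @export
as.data.frame.turn_series <- function(x, ...) {
  t <- x$turns
  if (nrow(t) == 0L) {
    return(cbind(data.frame(session_id = character(), dyad = character(),
                            direction = character()), empty_turns()))
  }
  cbind(data.frame(session_id = x$session_id,
                   dyad = paste(x$dyad, collapse = "|"),
                   direction = x$direction, stringsAsFactors = FALSE),
        t)
}

#' Summary counts of a turn series
#'
#' @param series a `turn_series`.
#' @return list with `n_turns`, `n_match`, `match_rate` (`NA` when there
#'   are no turns), and per-language counts `prev_counts`, `resp_counts`
#'   (named over `LANG_A`, `LANG_B`).
#' @export
summarize_turns <- function(series) {
  stopifnot(inherits(series, "turn_series"))
  t <- series$turns
  n <- nrow(t)
  count <- function(x) {
    tab <- table(factor(x, levels = LANGS))
    setNames(as.integer(tab), LANGS)
  }
  list(n_turns = n, n_match = sum(t$match),
       match_rate = if (n > 0L) sum(t$match) / n else NA_real_,
       prev_counts = count(t$prev_language),
       resp_counts = count(t$response_language))
}
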