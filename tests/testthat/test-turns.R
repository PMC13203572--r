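test_that("utterance ordering breaks onset ties by offset", {
  u <- data.frame(
    utterance_id = c("u1", "u2", "u3"),
    speaker_id = c("CG1", "CHI", "CG1"),
    onset_ms = c(0L, 500L, 500L), offset_ms = c(400L, 900L, 700L),
    stringsAsFactors = FALSE)
  s <- session_record("s", "f", "FRENCH_ENGLISH", "A", u,
                      segments = data.frame(),
                      roster = c(CG1 = "PRIMARY_CAREGIVER",
                                 CHI = "TARGET_CHILD"))
  expect_equal(order_utterances(s)$utterance_id, c("u1", "u3", "u2"))
})

test_that("turns are coded match/switch per the adjacency definition", {
  s <- quick_session(c("A", "A", "B", "A"), c("CG1", "CHI", "CG1", "CHI"))
  ts <- extract_turns(s, direction = "CHILD_RESPONDS")
  expect_equal(nrow(ts$turns), 2L)
  expect_equal(ts$turns$match, c(TRUE, FALSE))
  expect_equal(ts$turns$prev_language, c("LANG_A", "LANG_B"))
  # caregiver responses: CHI(A) -> CG1(B) is the only one
  tp <- extract_turns(s, direction = "PARTNER_RESPONDS")
  expect_equal(nrow(tp$turns), 1L)
  expect_false(tp$turns$match)
})

test_that("a third speaker between dyad utterances cancels the turn", {
  s <- quick_session(c("A", "A", "A"), c("CG1", "OTH", "CHI"),
                     session_type = "B")
  expect_equal(nrow(extract_turns(s, dyad = c("CHI", "CG1"))$turns), 0L)
  skip <- extract_turns(s, dyad = c("CHI", "CG1"), skip_third_party = TRUE)
  expect_equal(nrow(skip$turns), 1L)
  expect_true(skip$turns$match)
})

test_that("mixed and unknown utterances are excluded but still intervene", {
  s <- quick_session(c("M", "A"), c("CG1", "CHI"))
  expect_equal(nrow(extract_turns(s)$turns), 0L)
  # CG1(A), CHI(U), CG1 silent...: unknown child reply both kills the turn
  # and blocks CG1(A) -> CG1 adjacency beyond it
  s2 <- quick_session(c("A", "U", "B", "A"), c("CG1", "CHI", "CG1", "CHI"))
  ts <- extract_turns(s2, direction = "CHILD_RESPONDS")
  expect_equal(nrow(ts$turns), 1L)
  expect_equal(ts$turns$prev_language, "LANG_B")
})

test_that("same-speaker consecutive utterances never form turns", {
  set.seed(7)
  cfg <- session_config(
    n_utterances = 80, speaker_sequence = "MARKOV",
    transition = matrix(c(.6, .4, .5, .5), 2, byrow = TRUE),
    speakers = list(speaker_config("CG1", "PRIMARY_CAREGIVER"),
                    speaker_config("CHI", "TARGET_CHILD")),
    seed = 21)
  s <- generate_session(cfg)
  ts <- extract_turns(s)
  expect_true(all(ts$turns$prev_speaker_id != ts$turns$response_speaker_id))
})

test_that("pooled turn count is the sum of the two directions", {
  for (seed in c(3, 14, 25)) {
    s <- generate_session(synthetic_dyad_config(coupling = 0.3,
                                                n_utterances = 60,
                                                seed = seed))
    n_pool <- nrow(extract_turns(s, direction = "POOLED")$turns)
    n_chi <- nrow(extract_turns(s, direction = "CHILD_RESPONDS")$turns)
    n_cg <- nrow(extract_turns(s, direction = "PARTNER_RESPONDS")$turns)
    expect_equal(n_pool, n_chi + n_cg)
  }
})

test_that("relabeling languages leaves match flags unchanged", {
  s <- generate_session(synthetic_dyad_config(coupling = 0.5,
                                              n_utterances = 60, seed = 4))
  t1 <- extract_turns(s)
  t2 <- extract_turns(swap_languages(s))
  expect_equal(t1$turns$match, t2$turns$match)
  expect_equal(t1$turns$prev_language, ifelse(
    t2$turns$prev_language == "LANG_A", "LANG_B", "LANG_A"))
})

test_that("gap handling: overlap allowed, max_gap_ms drops long gaps", {
  u <- data.frame(
    utterance_id = c("u1", "u2", "u3", "u4"),
    speaker_id = c("CG1", "CHI", "CG1", "CHI"),
    onset_ms = c(0L, 900L, 3000L, 9000L),
    offset_ms = c(1000L, 1900L, 4000L, 9500L), stringsAsFactors = FALSE)
  seg <- data.frame(utterance_id = u$utterance_id, language = "LANG_A",
                    onset_ms = u$onset_ms, offset_ms = u$offset_ms,
                    stringsAsFactors = FALSE)
  s <- session_record("s", "f", "FRENCH_ENGLISH", "A", u, seg,
                      roster = c(CG1 = "PRIMARY_CAREGIVER",
                                 CHI = "TARGET_CHILD"))
  ts <- extract_turns(s)
  expect_equal(ts$turns$gap_ms, c(-100L, 1100L, 5000L))
  capped <- extract_turns(s, max_gap_ms = 2000)
  expect_equal(nrow(capped$turns), 2L)
})

test_that("turn summaries handle the empty and degenerate cases", {
  ts <- turn_series(c("LANG_A", "LANG_B"), c("LANG_A", "LANG_A"))
  s <- summarize_turns(ts)
  expect_equal(s$match_rate, 0.5)
  expect_equal(unname(s$resp_counts), c(2L, 0L))
  empty <- turn_series(character(), character())
  expect_true(is.na(summarize_turns(empty)$match_rate))
  all_match <- turn_series(rep("LANG_A", 10), rep("LANG_A", 10))
  expect_equal(summarize_turns(all_match)$match_rate, 1.0)
})

test_that("dyad members must be in the roster", {
  s <- quick_session(c("A", "B"), c("CG1", "CHI"))
  expect_error(extract_turns(s, dyad = c("CG1", "NOBODY")), "roster")
})
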