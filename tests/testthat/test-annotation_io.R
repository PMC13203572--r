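write_lines_tsv <- function(lines, path) {
  writeLines(lines, path, useBytes = TRUE)
  path
}

header <- paste(c("session_id", "family_id", "community", "session_type",
                  "speaker_id", "speaker_role", "utterance_id", "onset_ms",
                  "offset_ms", "language", "seg_onset_ms", "seg_offset_ms",
                  "transcript"), collapse = "\t")

test_that("a minimal one-row table yields one session with one segment", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_lines_tsv(c(header, paste(
    c("s1", "f1", "FRENCH_ENGLISH", "A", "CG1", "PRIMARY_CAREGIVER",
      "u1", "0", "1500", "LANG_A", "0", "1500", "hello"),
    collapse = "\t")), p)
  sess <- read_utterance_table(p)
  expect_length(sess, 1L)
  s <- sess[[1L]]
  expect_s3_class(s, "session_record")
  expect_equal(nrow(s$utterances), 1L)
  expect_equal(nrow(s$segments), 1L)
  expect_equal(s$segments$language, "LANG_A")
  expect_equal(s$segments$offset_ms - s$segments$onset_ms, 1500L)
  expect_equal(unname(s$roster["CG1"]), "PRIMARY_CAREGIVER")
})

test_that("write then read is the identity on valid sessions", {
  cfg <- synthetic_dyad_config(coupling = 0.4, seed = 5, n_utterances = 60,
                               session_type = "A")
  s <- generate_session(cfg)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_utterance_table(s, p)
  s2 <- read_utterance_table(p)[[1L]]
  expect_identical(unclass(s), unclass(s2))

  # also with a multi-party session (MARKOV sequence, third speaker)
  cfg3 <- session_config(
    n_utterances = 50, speaker_sequence = "MARKOV",
    transition = matrix(1 / 3, 3, 3),
    speakers = list(
      speaker_config("CG1", "PRIMARY_CAREGIVER", unknown_rate = 0.1),
      speaker_config("CHI", "TARGET_CHILD", unknown_rate = 0.5,
                     mixed_rate = 0.1),
      speaker_config("GMA", "OTHER_HOUSEHOLD")),
    seed = 11, session_type = "B")
  s3 <- generate_session(cfg3)
  write_utterance_table(s3, p)
  expect_identical(unclass(read_utterance_table(p)[[1L]]), unclass(s3))
})

test_that("schema and row-level validation errors are specific", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_lines_tsv(c(sub("\tlanguage", "", header), "x"), p)
  expect_error(read_utterance_table(p), "language")

  write_lines_tsv(c(header, paste(
    c("s1", "f1", "FRENCH_ENGLISH", "A", "CG1", "PRIMARY_CAREGIVER",
      "u1", "1500", "1000", "LANG_A", "0", "900", ""),
    collapse = "\t")), p)
  expect_error(read_utterance_table(p), "row 1.*offset_ms")

  write_lines_tsv(c(header, paste(
    c("s1", "f1", "FRENCH_ENGLISH", "A", "CG1", "PRIMARY_CAREGIVER",
      "u1", "0", "1000", "KLINGON", "0", "900", ""),
    collapse = "\t")), p)
  expect_error(read_utterance_table(p), "unknown language token")
})

test_that("writing produces one row per segment and a header-only file for
           an empty list", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_utterance_table(list(), p)
  expect_equal(length(readLines(p)), 1L)

  s <- quick_session(c("A", "M"), c("CG1", "CHI"))
  write_utterance_table(s, p)
  expect_equal(length(readLines(p)), 1L + 3L)  # 1 + 2 segments
})

make_eaf <- function(path, lang_values = c("eng", "fra"),
                     with_lang_tier = TRUE) {
  slots <- c(0, 1000, 1100, 2000, 2100, 3000)
  slot_xml <- paste(sprintf(
    '  <TIME_SLOT TIME_SLOT_ID="ts%d" TIME_VALUE="%d"/>',
    seq_along(slots), slots), collapse = "\n")
  ann <- function(id, t1, t2, value) sprintf(
    paste0('  <ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="%s" ',
           'TIME_SLOT_REF1="ts%d" TIME_SLOT_REF2="ts%d">',
           '<ANNOTATION_VALUE>%s</ANNOTATION_VALUE>',
           '</ALIGNABLE_ANNOTATION></ANNOTATION>'), id, t1, t2, value)
  lang_tier <- if (with_lang_tier) paste(
    '<TIER TIER_ID="CG1-lang">',
    ann("l1", 1, 2, lang_values[1L]),
    ann("l2", 3, 4, lang_values[2L]),
    "</TIER>", sep = "\n") else ""
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<ANNOTATION_DOCUMENT>",
    "<TIME_ORDER>", slot_xml, "</TIME_ORDER>",
    '<TIER TIER_ID="CG1">',
    ann("a1", 1, 2, "hello"),
    ann("a2", 3, 4, "bonjour"),
    ann("a3", 5, 6, "mmm"),
    "</TIER>",
    lang_tier,
    '<TIER TIER_ID="CHI">',
    ann("c1", 2, 3, "hi"),
    "</TIER>",
    "</ANNOTATION_DOCUMENT>"), path, useBytes = TRUE)
  path
}

tier_map <- list(
  list(speaker_tier = "CG1", language_tier = "CG1-lang",
       speaker_id = "CG1", speaker_role = "PRIMARY_CAREGIVER"),
  list(speaker_tier = "CHI", speaker_id = "CHI",
       speaker_role = "TARGET_CHILD"))

test_that("a minimal EAF becomes a session record with language segments", {
  p <- withr::local_tempfile(fileext = ".eaf")
  make_eaf(p)
  s <- read_eaf(p, tier_map, session_id = "s1", family_id = "f1",
                community = "FRENCH_ENGLISH", session_type = "A")
  expect_equal(nrow(s$utterances), 4L)
  cls <- classify_utterances(s)
  expect_equal(unname(cls[c("a1", "a2")]), c("LANG_A", "LANG_B"))
  # utterance a3 has no language-tier coverage: wholly unknown
  expect_equal(unname(cls["a3"]), "UNKNOWN")
  expect_equal(unname(cls["c1"]), "UNKNOWN")
  expect_equal(s$utterances$onset_ms[s$utterances$utterance_id == "a1"], 0L)
  expect_equal(s$utterances$offset_ms[s$utterances$utterance_id == "a1"],
               1000L)
})

test_that("EAF and table ingestion of equivalent content agree", {
  p <- withr::local_tempfile(fileext = ".eaf")
  make_eaf(p)
  s_eaf <- read_eaf(p, tier_map, session_id = "s1", family_id = "f1",
                    community = "FRENCH_ENGLISH", session_type = "A")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_utterance_table(s_eaf, p2)
  s_tab <- read_utterance_table(p2)[[1L]]
  expect_identical(unclass(s_eaf), unclass(s_tab))
})

test_that("a tier_map naming a missing tier is a configuration error", {
  p <- withr::local_tempfile(fileext = ".eaf")
  make_eaf(p)
  bad <- tier_map
  bad[[2L]]$speaker_tier <- "NOPE"
  expect_error(
    read_eaf(p, bad, session_id = "s1", family_id = "f1",
             community = "FRENCH_ENGLISH", session_type = "A"),
    "NOPE")
})

test_that("validate_session reports content issues and only those", {
  good <- quick_session(c("A", "B", "A"), c("CG1", "CHI", "CG1"))
  expect_equal(nrow(validate_session(good)), 0L)

  # OTHER_HOUSEHOLD speech in a one-on-one session
  bad_role <- quick_session(c("A", "B", "A"), c("CG1", "CHI", "OTH"),
                            session_type = "A")
  iss <- validate_session(bad_role)
  expect_true("role_violation" %in% iss$kind)

  # overlapping segments within one utterance
  s <- quick_session(c("A", "B"), c("CG1", "CHI"))
  s$segments <- rbind(s$segments, data.frame(
    utterance_id = "u001", language = "LANG_B", onset_ms = 500L,
    offset_ms = 1200L, stringsAsFactors = FALSE))
  iss <- validate_session(s)
  expect_true("segment_overlap" %in% iss$kind)
  expect_true("segment_outside" %in% iss$kind)

  # negative utterance duration and duplicate target child
  s2 <- quick_session(c("A", "B"), c("CG1", "CHI"))
  s2$utterances$offset_ms[1L] <- s2$utterances$onset_ms[1L]
  s2$roster["CG1"] <- "TARGET_CHILD"
  iss2 <- validate_session(s2)
  expect_true("negative_duration" %in% iss2$kind)
  expect_true("duplicate_target_child" %in% iss2$kind)
})
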