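test_that("analytic independence rate follows the closed form", {
  expect_equal(expected_rate_analytic(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(expected_rate_analytic(c(1, 0), c(1, 0)), 1.0)
  expect_equal(expected_rate_analytic(c(0.8, 0.2), c(0.6, 0.4)), 0.56)
  expect_error(expected_rate_analytic(c(0.8, 0.3), c(0.5, 0.5)), "sum to 1")
})

test_that("permutation null equals brute-force enumeration on tiny series", {
  ts <- turn_series(c("LANG_A", "LANG_A", "LANG_B"),
                    c("LANG_A", "LANG_B", "LANG_B"))
  exact <- exact_null_dist(ts)
  null <- permutation_null(ts, n_iterations = 20000, seed = 31)
  emp <- mc_dist(null$rates, 3L)
  expect_lt(tv_distance(emp, exact), 0.02)
  # and the enumeration agrees with the hypergeometric closed form
  expect_equal(exact, hyper_null_dist(ts), tolerance = 1e-12)
})

test_that("the null's mean and distribution match the hypergeometric
           closed form on a larger series", {
  set.seed(8)
  ts <- rand_series(40, p_prev = 0.6, p_resp = 0.7)
  null <- permutation_null(ts, n_iterations = 20000, seed = 17)
  exact <- hyper_null_dist(ts)
  expect_lt(tv_distance(mc_dist(null$rates, 40L), exact), 0.03)
  exact_mean <- sum((0:40) / 40 * exact)
  expect_lt(abs(null$mean - exact_mean), 0.005)
})

test_that("every replicate rate is attainable given the fixed margins", {
  set.seed(9)
  for (rep in 1:5) {
    ts <- rand_series(25, p_prev = runif(1, .3, .7),
                      p_resp = runif(1, .3, .7))
    null <- permutation_null(ts, n_iterations = 500, seed = rep)
    support <- which(hyper_null_dist(ts) > 0) - 1L
    expect_true(all(round(null$rates * 25) %in% support))
  }
})

test_that("permuting both sequences is distributionally equivalent", {
  set.seed(10)
  ts <- rand_series(30, p_prev = 0.6, p_resp = 0.5)
  a <- permutation_null(ts, n_iterations = 10000, seed = 1)
  b <- permutation_null(ts, n_iterations = 10000, seed = 2,
                        permute = "both")
  expect_lt(tv_distance(mc_dist(a$rates, 30L), mc_dist(b$rates, 30L)), 0.04)
})

test_that("the add-one p-value handles floors, ceilings and ties", {
  expect_equal(mc_p_value(0.9, rep(0.5, 9999)), 1 / 10000)
  expect_equal(mc_p_value(0.1, rep(0.5, 999)), 1.0)
  expect_equal(mc_p_value(0.5, rep(0.5, 999)), 1.0)  # ties count against
})

test_that("Cohen's h has the arcsine form and its fixed points", {
  expect_equal(cohens_h(0.3, 0.3), 0)
  expect_equal(cohens_h(1, 0), pi)
  expect_equal(cohens_h(0.2, 0.6), -cohens_h(0.6, 0.2))
  expect_error(cohens_h(1.2, 0.5), "\\[0, 1\\]")
})

test_that("inclusion filters sit exactly at the stated boundaries", {
  balanced29 <- turn_series(rep(c("LANG_A", "LANG_B"), length.out = 29),
                            rep(c("LANG_B", "LANG_A"), length.out = 29))
  f <- apply_inclusion_filters(balanced29)
  expect_false(f$included)
  expect_equal(f$reason, "TOO_FEW_TURNS")

  balanced30 <- turn_series(rep(c("LANG_A", "LANG_B"), length.out = 30),
                            rep(c("LANG_B", "LANG_A"), length.out = 30))
  expect_true(apply_inclusion_filters(balanced30)$included)

  # 100 turns, 79% vs 80% of responses in one language
  prev <- rep(c("LANG_A", "LANG_B"), 50)
  resp79 <- c(rep("LANG_A", 79), rep("LANG_B", 21))
  resp80 <- c(rep("LANG_A", 80), rep("LANG_B", 20))
  expect_true(apply_inclusion_filters(turn_series(prev, resp79))$included)
  f80 <- apply_inclusion_filters(turn_series(prev, resp80))
  expect_false(f80$included)
  expect_equal(f80$reason, "DOMINANCE")

  # both filters at once
  short_dom <- turn_series(rep("LANG_A", 10), rep("LANG_A", 10))
  expect_equal(apply_inclusion_filters(short_dom)$reason, "BOTH")
})

test_that("alignment_test is deterministic under a fixed seed and
           populates results even for excluded series", {
  s <- generate_session(synthetic_dyad_config(coupling = 0.4,
                                              n_utterances = 80, seed = 3))
  a <- alignment_test(s, n_iterations = 500, seed = 99)
  b <- alignment_test(s, n_iterations = 500, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(a$null_rates, b$null_rates)

  short <- turn_series(rep(c("LANG_A", "LANG_B"), 5),
                       c(rep("LANG_A", 6), rep("LANG_B", 4)))
  r <- alignment_test(short, n_iterations = 200, seed = 1)
  expect_false(r$included)
  expect_equal(r$exclusion_reason, "TOO_FEW_TURNS")
  expect_false(is.na(r$p_value))   # filters gate interpretation only
  expect_false(is.na(r$cohens_h))
})

test_that("an all-match series with mixed margins hits the p-value floor
           with a positive effect size", {
  langs <- c(rep("LANG_A", 24), rep("LANG_B", 16))
  ts <- turn_series(langs, langs)   # 40 turns, all match, 60/40 margins
  r <- alignment_test(ts, n_iterations = 2000, seed = 5)
  expect_equal(r$observed_rate, 1.0)
  expect_lt(r$null_mean, 1.0)
  expect_gt(r$cohens_h, 0)
  expect_equal(r$p_value, 1 / 2001)
  expect_equal(r$coupling, 1.0)
})

test_that("relabeling languages leaves the test invariant", {
  set.seed(12)
  ts <- rand_series(50, p_prev = 0.65, p_resp = 0.4)
  a <- alignment_test(ts, n_iterations = 1000, seed = 7)
  b <- alignment_test(swap_series(ts), n_iterations = 1000, seed = 7)
  expect_equal(a$observed_rate, b$observed_rate)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$null_mean, b$null_mean)
  expect_equal(abs(a$cohens_h), abs(b$cohens_h))
})

test_that("a zero-turn extraction yields an NA-filled excluded result", {
  s <- quick_session(c("A", "A"), c("CG1", "CG1"))
  r <- alignment_test(s, n_iterations = 100, seed = 1)
  expect_equal(r$n_turns, 0L)
  expect_true(is.na(r$p_value))
  expect_false(r$included)
})

test_that("attrition accounting counts the doubly excluded once", {
  results <- data.frame(
    community = rep(c("FRENCH_ENGLISH", "SPANISH_ENGLISH"), c(5, 3)),
    session_type = "A",
    included = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    exclusion_reason = c("NONE", "NONE", "DOMINANCE", "TOO_FEW_TURNS",
                         "BOTH", "NONE", "BOTH", "DOMINANCE"),
    p_value = c(0.01, 0.2, 0.03, 0.5, 0.5, 0.002, 0.5, 0.5),
    stringsAsFactors = FALSE)
  rep_ <- attrition_report(results)
  fr <- rep_[rep_$community == "FRENCH_ENGLISH", ]
  expect_equal(fr$initial, 5)
  expect_equal(fr$excluded_dominance, 2)  # DOMINANCE + BOTH
  expect_equal(fr$excluded_turns, 1)
  expect_equal(fr$n_both, 1)
  expect_equal(fr$included, 2)
  expect_equal(fr$significant, 1)
  expect_equal(fr$nonsignificant, 1)
  expect_equal(fr$initial,
               fr$excluded_dominance + fr$excluded_turns + fr$included)
  tot <- rep_[rep_$community == "TOTAL", ]
  expect_equal(tot$initial, 8)
  expect_equal(tot$initial,
               tot$excluded_dominance + tot$excluded_turns + tot$included)
})
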