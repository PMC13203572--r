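#' Analytic match probability under independence
#'
#' If the previous speaker's language is drawn from `prev_dist` and the
#' response language independently from `resp_dist`, the probability of a
#' language match is `sum_l p_prev(l) * p_resp(l)`. This closed form is the
#' large-sample mean of the frequency-preserving permutation null.
#'
#' @param prev_dist,resp_dist numeric vectors of length 2 (proportions of
#'   `LANG_A` and `LANG_B`), each summing to 1.
#' @return the independence match probability.
#' @export
expected_rate_analytic <- function(prev_dist, resp_dist) {
  prev_dist <- as.numeric(prev_dist)
  resp_dist <- as.numeric(resp_dist)
  stopifnot(length(prev_dist) == 2L, length(resp_dist) == 2L)
  if (abs(sum(prev_dist) - 1) > 1e-6 || abs(sum(resp_dist) - 1) > 1e-6) {
    stop("language distributions must each sum to 1", call. = FALSE)
  }
  if (any(prev_dist < 0) || any(resp_dist < 0)) {
    stop("language distributions must be non-negative", call. = FALSE)
  }
  sum(prev_dist * resp_dist)
}

#' Frequency-preserving Monte Carlo null for the match rate
#'
#' Each iteration applies an independent uniform random permutation to the
#' sequence of response languages across the series' turns and records the
#' resulting match rate. Permuting one side preserves both speakers'
#' observed language counts exactly, so every replicate has the observed
#' frequency distributions; only the pairing is randomised. An option to
#' permute both sequences (distributionally equivalent for the match
#' statistic) is provided for verification.
#'
#' @param series a `turn_series` with at least one turn.
#' @param n_iterations number of Monte Carlo replicates.
#' @param seed optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @param permute `"response"` (default) or `"both"`.
#' @return list with `rates` (length `n_iterations`), `mean`, `sd`,
#'   `n_iterations`.
#' @export
permutation_null <- function(series, n_iterations = 10000, seed = NULL,
                             permute = c("response", "both")) {
  stopifnot(inherits(series, "turn_series"), n_iterations >= 1)
  permute <- match.arg(permute)
  prev <- series$turns$prev_language
  resp <- series$turns$response_language
  n <- length(prev)
  if (n == 0L) stop("turn series has no turns", call. = FALSE)
  rates <- with_seed(seed, {
    if (permute == "response") {
      vapply(seq_len(n_iterations),
             function(i) mean(prev == resp[sample.int(n)]), numeric(1L))
    } else {
      vapply(seq_len(n_iterations),
             function(i) mean(prev[sample.int(n)] == resp[sample.int(n)]),
             numeric(1L))
    }
  })
  list(rates = rates, mean = mean(rates), sd = sd(rates),
       n_iterations = as.integer(n_iterations))
}

#' Monte Carlo p-value (add-one estimator)
#'
#' One-sided upper-tail p-value `(1 + #[null >= observed]) / (1 + N)`.
#' Ties count toward the tail and the estimate is never zero, with floor
#' `1 / (N + 1)`.
#'
#' @param observed_rate observed match rate.
#' @param null_rates numeric vector of null replicate rates.
#' @return p-value in `(0, 1]`.
#' @export
mc_p_value <- function(observed_rate, null_rates) {
  stopifnot(length(null_rates) >= 1L, !is.na(observed_rate))
  (1 + sum(null_rates >= observed_rate - 1e-12)) / (1 + length(null_rates))
}

#' Cohen's h effect size for two proportions
#'
#' The arcsine-transform effect size `2*asin(sqrt(p1)) - 2*asin(sqrt(p2))`.
#'
#' @param p1,p2 proportions in `[0, 1]`.
#' @return signed effect size; positive when `p1 > p2`.
#' @export
cohens_h <- function(p1, p2) {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1) || anyNA(c(p1, p2))) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
}

#' Inclusion filters for alignment testing
#'
#' A series is excluded when chance matching would be near ceiling or the
#' baseline unstable: `DOMINANCE` when, for either role (previous-speaker
#' languages or response languages over the series' turns), the most
#' frequent language's share is at or above `dominance_threshold`
#' (inclusion requires strictly less than 80% use of one language by
#' default); `TOO_FEW_TURNS` when the series has fewer than `min_turns`
#' turns (at least 30 by default); `BOTH` when both apply; `NONE`
#' otherwise.
#'
#' @param series a `turn_series`.
#' @param dominance_threshold proportion at or above which one language
#'   counts as dominant (default 0.80).
#' @param min_turns minimum number of turns for inclusion (default 30).
#' @return list with `included` (logical) and `reason` (one of `NONE`,
#'   `DOMINANCE`, `TOO_FEW_TURNS`, `BOTH`).
#' @export
apply_inclusion_filters <- function(series, dominance_threshold = 0.80,
                                    min_turns = 30) {
  s <- summarize_turns(series)
  too_few <- s$n_turns < min_turns
  dominant <- if (s$n_turns > 0L) {
    max(s$prev_counts) / s$n_turns >= dominance_threshold ||
      max(s$resp_counts) / s$n_turns >= dominance_threshold
  } else {
    FALSE
  }
  reason <- if (dominant && too_few) "BOTH" else if (dominant) "DOMINANCE"
    else if (too_few) "TOO_FEW_TURNS" else "NONE"
  list(included = reason == "NONE", reason = reason)
}

#' Test turn-by-turn language alignment against chance
#'
#' Fits the package's core test to one dyadic turn series: the observed
#' match rate is compared against a frequency-preserving Monte Carlo null
#' in which response languages are randomly re-paired with previous
#' languages while both speakers' observed language counts are held fixed
#' (10,000 iterations by default). The result carries a one-sided
#' upper-tail p-value (add-one estimator), the signed Cohen's h between
#' the observed rate and the null mean, the closed-form independence rate
#' of the series' empirical marginals, a moment-based coupling estimate
#' (see [estimate_coupling()]), and the balance/turn-count inclusion
#' filters. Filters gate interpretation, not computation: results are
#' populated whether or not the series passes them.
#'
#' @param x a [session_record()] (turns are extracted first) or a
#'   `turn_series`.
#' @param dyad,direction,max_gap_ms passed to [extract_turns()] when `x`
#'   is a session record.
#' @param n_iterations Monte Carlo iterations (default 10,000).
#' @param seed integer seed recorded in the result; the same seed and
#'   input reproduce the result exactly.
#' @param dominance_threshold,min_turns see [apply_inclusion_filters()].
#' @param keep_null keep the vector of null replicate rates in the result
#'   (needed by `plot`).
#' @return object of class `alignment_test` with fields `session_id`,
#'   `dyad`, `direction`, `n_turns`, `observed_rate`, `null_mean`,
#'   `null_sd`, `expected_rate_analytic`, `p_value`, `cohens_h`,
#'   `coupling`, `n_iterations`, `seed`, `included`, `exclusion_reason`.
#' @examples
#' set.seed(1)
#' prev <- sample(c("LANG_A", "LANG_B"), 60, replace = TRUE)
#' resp <- ifelse(runif(60) < 0.5, prev,
#'                sample(c("LANG_A", "LANG_B"), 60, replace = TRUE))
#' alignment_test(turn_series(prev, resp), n_iterations = 1000, seed = 42)
#' @export
alignment_test <- function(x, dyad = NULL, direction = "POOLED",
                           n_iterations = 10000, seed = NULL,
                           dominance_threshold = 0.80, min_turns = 30,
                           max_gap_ms = Inf, keep_null = TRUE) {
  series <- if (inherits(x, "session_record")) {
    extract_turns(x, dyad = dyad, direction = direction,
                  max_gap_ms = max_gap_ms)
  } else if (inherits(x, "turn_series")) {
    x
  } else {
    stop("x must be a session_record or a turn_series", call. = FALSE)
  }
  s <- summarize_turns(series)
  filt <- apply_inclusion_filters(series, dominance_threshold, min_turns)
  res <- list(session_id = series$session_id, dyad = series$dyad,
              direction = series$direction, n_turns = s$n_turns,
              observed_rate = s$match_rate, null_mean = NA_real_,
              null_sd = NA_real_, expected_rate_analytic = NA_real_,
              p_value = NA_real_, cohens_h = NA_real_,
              coupling = NA_real_,
              n_iterations = as.integer(n_iterations),
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
              included = filt$included, exclusion_reason = filt$reason,
              null_rates = NULL, series = series)
  if (s$n_turns > 0L) {
    null <- permutation_null(series, n_iterations = n_iterations,
                             seed = seed)
    res$null_mean <- null$mean
    res$null_sd <- null$sd
    res$expected_rate_analytic <- expected_rate_analytic(
      s$prev_counts / s$n_turns, s$resp_counts / s$n_turns)
    res$p_value <- mc_p_value(s$match_rate, null$rates)
    res$cohens_h <- cohens_h(s$match_rate, null$mean)
    res$coupling <- if (res$expected_rate_analytic < 1) {
      estimate_coupling(series)$lambda
    } else {
      NA_real_
    }
    if (keep_null) res$null_rates <- null$rates
  }
  class(res) <- "alignment_test"
  res
}

#' @export
print.alignment_test <- function(x, ...) {
  cat(sprintf("<alignment_test> %s, dyad %s <-> %s, direction %s\n",
              x$session_id, x$dyad[1L], x$dyad[2L], x$direction))
  if (x$n_turns == 0L) {
    cat("  no codable turns\n")
    return(invisible(x))
  }
  cat(sprintf(
    "  %d turns; observed match rate %.3f vs null %.3f (sd %.3f)\n",
    x$n_turns, x$observed_rate, x$null_mean, x$null_sd))
  cat(sprintf("  one-sided p = %.4g (%d iterations), Cohen's h = %.2f\n",
              x$p_value, x$n_iterations, x$cohens_h))
  cat(sprintf("  inclusion: %s\n",
              if (x$included) "included" else
                paste0("excluded (", x$exclusion_reason, ")")))
  invisible(x)
}

#' @export
summary.alignment_test <- function(object, ...) {
  print(object)
  if (object$n_turns > 0L) {
    s <- summarize_turns(object$series)
    cat(sprintf("  previous languages: A %d / B %d; responses: A %d / B %d\n",
                s$prev_counts[["LANG_A"]], s$prev_counts[["LANG_B"]],
                s$resp_counts[["LANG_A"]], s$resp_counts[["LANG_B"]]))
    cat(sprintf("  analytic independence rate %.3f; coupling estimate %.3f\n",
                object$expected_rate_analytic, object$coupling))
  }
  invisible(object)
}

#' @export
coef.alignment_test <- function(object, ...) {
  c(observed_rate = object$observed_rate, null_mean = object$null_mean,
    expected_rate = object$expected_rate_analytic,
    cohens_h = object$cohens_h, coupling = object$coupling)
}

#' @export
plot.alignment_test <- function(x, ...) {
  if (is.null(x$null_rates)) {
    stop("no stored null replicates (keep_null = FALSE)", call. = FALSE)
  }
  graphics::hist(x$null_rates, breaks = 30, col = "grey80", border = "white",
                 main = sprintf("Null match rates (%s)", x$session_id),
                 xlab = "match rate",
                 xlim = range(c(x$null_rates, x$observed_rate)), ...)
  graphics::abline(v = x$observed_rate, col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
simulate.alignment_test <- function(object, nsim = 1, seed = NULL, ...) {
  permutation_null(object$series, n_iterations = nsim, seed = seed)$rates
}

#' @export
as.data.frame.alignment_test <- function(x, ...) {
  data.frame(session_id = x$session_id,
             dyad = paste(x$dyad, collapse = "|"),
             direction = x$direction, n_turns = x$n_turns,
             observed_rate = x$observed_rate, null_mean = x$null_mean,
             null_sd = x$null_sd,
             expected_rate_analytic = x$expected_rate_analytic,
             p_value = x$p_value, cohens_h = x$cohens_h,
             coupling = x$coupling, n_iterations = x$n_iterations,
             seed = x$seed, included = x$included,
             exclusion_reason = x$exclusion_reason,
             stringsAsFactors = FALSE)
}

#' Attrition report for a set of alignment tests
#'
#' Tabulates, per community and session type, how many sessions entered
#' the analysis, how many the balance (dominance) and turn-count filters
#' excluded, and how many of the included sessions showed significant
#' alignment. Sessions failing both filters are counted once, in the
#' dominance column, with the overlap reported separately in `n_both`, so
#' `initial = excluded_dominance + excluded_turns + included` holds in
#' every row. A `TOTAL` row is appended.
#'
#' @param results data frame with one row per session test, containing at
#'   least `community`, `session_type`, `included`, `exclusion_reason`,
#'   `p_value` (as produced by [run_pipeline()] or by row-binding
#'   `as.data.frame(alignment_test)` results with session metadata).
#' @param alpha significance threshold for counting a session as showing
#'   alignment (default 0.05).
#' @return data frame with columns `community`, `session_type`, `initial`,
#'   `excluded_dominance`, `excluded_turns`, `n_both`, `included`,
#'   `significant`, `nonsignificant`.
#' @export
attrition_report <- function(results, alpha = 0.05) {
  need <- c("community", "session_type", "included", "exclusion_reason",
            "p_value")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  key <- interaction(results$community, results$session_type, drop = TRUE)
  one <- function(df, comm, st) {
    data.frame(
      community = comm, session_type = st, initial = nrow(df),
      excluded_dominance = sum(df$exclusion_reason %in%
                                 c("DOMINANCE", "BOTH")),
      excluded_turns = sum(df$exclusion_reason == "TOO_FEW_TURNS"),
      n_both = sum(df$exclusion_reason == "BOTH"),
      included = sum(df$included),
      significant = sum(df$included & !is.na(df$p_value) &
                          df$p_value < alpha),
      nonsignificant = sum(df$included &
                             (is.na(df$p_value) | df$p_value >= alpha)),
      stringsAsFactors = FALSE)
  }
  parts <- lapply(levels(key), function(k) {
    df <- results[key == k, , drop = FALSE]
    one(df, df$community[1L], df$session_type[1L])
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$community, out$session_type), , drop = FALSE]
  out <- rbind(out, one(results, "TOTAL", ""))
  rownames(out) <- NULL
  out
}
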