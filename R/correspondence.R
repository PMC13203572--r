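#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the usual t-transform p-value, plus the
#' degenerate-input guards the correspondence pipeline needs.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, finite values.
#' @return list with `r`, `n`, `p`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

comparison_result <- function(method, r1, r2, n1, n2, z, p,
                              ci_r_difference = NULL) {
  structure(list(method = method, r1 = r1, r2 = r2, n1 = n1, n2 = n2,
                 z = z, p = p, ci_r_difference = ci_r_difference),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("<correlation_comparison> %s\n", x$method))
  cat(sprintf("  r1 = %.3f (n = %d) vs r2 = %.3f (n = %d)\n",
              x$r1, x$n1, x$r2, x$n2))
  cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$z, x$p))
  if (!is.null(x$ci_r_difference)) {
    cat(sprintf("  95%% CI for r difference: [%.3f, %.3f]\n",
                x$ci_r_difference[1L], x$ci_r_difference[2L]))
  }
  invisible(x)
}

#' Fisher r-to-z test for two independent correlations
#'
#' Tests whether two correlations from independent samples differ:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' standard-normal reference and two-sided p. The confidence interval for
#' the correlation difference is obtained by back-transforming (tanh) the
#' z-scale interval for the difference.
#'
#' @param r1,r2 sample correlations, `|r| < 1`.
#' @param n1,n2 sample sizes, each at least 4.
#' @param conf_level confidence level for the difference interval.
#' @return a `correlation_comparison` object with fields `z`, `p` and
#'   `ci_r_difference`.
#' @export
fisher_z_independent <- function(r1, n1, r2, n2, conf_level = 0.95) {
  stopifnot(n1 >= 4L, n2 >= 4L)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("correlations of magnitude 1 have infinite z-transform",
         call. = FALSE)
  }
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  d <- atanh(r1) - atanh(r2)
  z <- d / se
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  comparison_result("fisher_z_independent", r1, r2, n1, n2, z,
                    2 * pnorm(-abs(z)),
                    ci_r_difference = tanh(c(d - crit * se, d + crit * se)))
}

#' Steiger's Z for two overlapping dependent correlations
#'
#' Tests whether `r12` and `r13` — two correlations sharing variable 1 and
#' measured on the same sample — differ. Uses the common variant that
#' plugs the average of the two compared correlations into the covariance
#' term:
#' \deqn{\bar r = (r_{12}+r_{13})/2,\quad
#'   \psi = r_{23}(1-2\bar r^2) - \tfrac12 \bar r^2 (1-2\bar r^2-r_{23}^2),
#'   \quad s = \psi/(1-\bar r^2)^2,}
#' \deqn{Z = \sqrt{n-3}\,\frac{\mathrm{atanh}(r_{12}) -
#'   \mathrm{atanh}(r_{13})}{\sqrt{2-2s}},}
#' with a standard-normal reference and two-sided p.
#'
#' @param r12,r13 the two correlations being compared (both involve
#'   variable 1).
#' @param r23 the correlation between the two non-shared variables.
#' @param n sample size, at least 4.
#' @return a `correlation_comparison` object.
#' @export
steiger_dependent_z <- function(r12, r13, r23, n) {
  stopifnot(n >= 4L)
  if (abs(r12) >= 1 || abs(r13) >= 1) {
    stop("correlations of magnitude 1 have infinite z-transform",
         call. = FALSE)
  }
  if (abs(r23) > 1) stop("|r23| must be <= 1", call. = FALSE)
  det3 <- 1 + 2 * r12 * r13 * r23 - r12^2 - r13^2 - r23^2
  if (det3 < -1e-12) {
    stop("correlation triple is not positive semi-definite", call. = FALSE)
  }
  rbar <- (r12 + r13) / 2
  psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  s <- psi / (1 - rbar^2)^2
  z <- sqrt(n - 3) * (atanh(r12) - atanh(r13)) / sqrt(2 - 2 * s)
  comparison_result("steiger_dependent_z", r12, r13, n, n, z,
                    2 * pnorm(-abs(z)))
}

#' Family-level language proportion table
#'
#' One row per family and session type, with the target child's, primary
#' caregiver's, and (for multi-party sessions) other household members'
#' mean `LANG_A` proportions of identifiable speech — the input for the
#' session-level correspondence correlations. Speakers with no
#' identifiable speech contribute `NA`.
#'
#' @param sessions list of [session_record()] objects.
#' @return data frame with columns `family_id`, `session_id`, `community`,
#'   `session_type`, `child_prop_a`, `caregiver_prop_a`, `others_prop_a`.
#' @export
family_proportion_table <- function(sessions) {
  if (inherits(sessions, "session_record")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    prof <- speaker_profiles(s)
    pick <- function(role) {
      v <- prof$prop_lang_a[prof$speaker_role == role]
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    }
    data.frame(family_id = s$family_id, session_id = s$session_id,
               community = s$community, session_type = s$session_type,
               child_prop_a = pick("TARGET_CHILD"),
               caregiver_prop_a = pick("PRIMARY_CAREGIVER"),
               others_prop_a = pick("OTHER_HOUSEHOLD"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Session-level correspondence analysis
#'
#' Computes, per community and session type, the correlation across
#' families between children's and primary caregivers' `LANG_A`
#' proportions (and children vs other household members where present),
#' then the two comparison tests: Fisher's r-to-z between communities on
#' the child-caregiver correlation, and Steiger's Z comparing
#' child-caregiver against child-others within each community (multi-party
#' sessions only). Tests are reported only where at least 4 complete,
#' non-degenerate observations are available; otherwise the row carries
#' `NA`.
#'
#' @param sessions list of [session_record()] objects (or a prebuilt
#'   [family_proportion_table()] data frame).
#' @return list with data frames `correlations` (columns `community`,
#'   `session_type`, `pair`, `r`, `n`, `p`) and `comparisons` (columns
#'   `test`, `session_type`, `community`, `r1`, `r2`, `z`, `p`).
#' @export
correspondence_report <- function(sessions) {
  tbl <- if (is.data.frame(sessions)) sessions else
    family_proportion_table(sessions)

  safe_cor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) {
      return(list(r = NA_real_, n = length(x), p = NA_real_))
    }
    pearson_correlation(x, y)
  }

  combos <- unique(tbl[, c("community", "session_type")])
  cors <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- tbl[tbl$community == combos$community[i] &
                 tbl$session_type == combos$session_type[i], , drop = FALSE]
    for (pair in c("child_caregiver", "child_others")) {
      yv <- if (pair == "child_caregiver") sub$caregiver_prop_a else
        sub$others_prop_a
      if (pair == "child_others" && all(is.na(yv))) next
      cc <- safe_cor(sub$child_prop_a, yv)
      cors[[length(cors) + 1L]] <- data.frame(
        community = combos$community[i],
        session_type = combos$session_type[i], pair = pair,
        r = cc$r, n = cc$n, p = cc$p, stringsAsFactors = FALSE)
    }
  }
  correlations <- if (length(cors)) do.call(rbind, cors) else
    data.frame(community = character(), session_type = character(),
               pair = character(), r = numeric(), n = integer(),
               p = numeric(), stringsAsFactors = FALSE)

  comparisons <- list()
  # Fisher: child-caregiver correlation across communities, per session type
  for (st in unique(correlations$session_type)) {
    cc <- correlations[correlations$session_type == st &
                         correlations$pair == "child_caregiver", ,
                       drop = FALSE]
    if (nrow(cc) == 2L && !anyNA(cc$r) && all(cc$n >= 4L)) {
      f <- fisher_z_independent(cc$r[1L], cc$n[1L], cc$r[2L], cc$n[2L])
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        test = "fisher_z_independent", session_type = st,
        community = paste(cc$community, collapse = " vs "),
        r1 = f$r1, r2 = f$r2, z = f$z, p = f$p, stringsAsFactors = FALSE)
    }
  }
  # Steiger: child-caregiver vs child-others within community (session B)
  for (i in seq_len(nrow(combos))) {
    sub <- tbl[tbl$community == combos$community[i] &
                 tbl$session_type == combos$session_type[i], , drop = FALSE]
    ok <- stats::complete.cases(sub[, c("child_prop_a", "caregiver_prop_a",
                                        "others_prop_a")])
    sub <- sub[ok, , drop = FALSE]
    if (nrow(sub) < 4L) next
    degenerate <- any(vapply(sub[, c("child_prop_a", "caregiver_prop_a",
                                     "others_prop_a")], sd,
                             numeric(1L)) == 0)
    if (degenerate) next
    r12 <- stats::cor(sub$child_prop_a, sub$caregiver_prop_a)
    r13 <- stats::cor(sub$child_prop_a, sub$others_prop_a)
    r23 <- stats::cor(sub$caregiver_prop_a, sub$others_prop_a)
    if (abs(r12) >= 1 || abs(r13) >= 1) next
    st <- steiger_dependent_z(r12, r13, r23, nrow(sub))
    comparisons[[length(comparisons) + 1L]] <- data.frame(
      test = "steiger_dependent_z",
      session_type = combos$session_type[i],
      community = combos$community[i],
      r1 = r12, r2 = r13, z = st$z, p = st$p, stringsAsFactors = FALSE)
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame(test = character(), session_type = character(),
               community = character(), r1 = numeric(), r2 = numeric(),
               z = numeric(), p = numeric(), stringsAsFactors = FALSE)

  list(correlations = correlations, comparisons = comparisons)
}
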