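---
title: "Testing turn-by-turn language alignment against chance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing turn-by-turn language alignment against chance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langalign)
```

## The question and the statistic

In bilingual households, a caregiver and child who both prefer the same
language will frequently "match" each other's language choice even if
neither is reacting to the other. The analysis implemented here separates
that base-rate artefact from genuine moment-to-moment coordination: for a
dyad's sequence of conversational turns, it asks whether the observed
match rate exceeds what independent language selection with the same
individual language frequencies would produce.

The data unit is the **turn**: an utterance by one dyad member followed
immediately, in the global utterance order, by an utterance from the
other member, with both utterances in a single identifiable language. A
turn is a *match* when the response language equals the previous
utterance's language. For a series of $n$ turns, the observed match rate
is $\hat p = \tfrac1n\sum_i \mathbf 1[\ell^{\text{prev}}_i =
\ell^{\text{resp}}_i]$.

## The frequency-preserving null

`permutation_null()` re-pairs the two language sequences: each replicate
applies a uniform random permutation to the response-language sequence
and recomputes the match rate. This holds both speakers' observed
language counts fixed — every replicate has exactly the empirical
language frequency distributions — and destroys only the sequential
coupling. Permuting the previous-language sequence as well changes
nothing distributionally (an option, `permute = "both"`, exists for
verification), so the cheaper one-sided permutation is the default.

Conditional on the margins the permuted match count has a closed form:
if $a$ of $n$ previous languages and $b$ of $n$ responses are language A,
the number of A–A pairs is hypergeometric, and the match count is
$(n-a-b)+2X$, $X \sim \mathrm{Hyper}(a, n-a, b)$. The package
deliberately does **not** use this closed form in the implementation: the
permutation is the definition, and the hypergeometric form serves as an
independent oracle in the test suite (total-variation agreement with
brute-force enumeration of all $n!$ pairings for small $n$). The null
mean converges to the analytic independence rate
$m_0=\sum_\ell \hat p_{\text{prev}}(\ell)\,\hat p_{\text{resp}}(\ell)$
(`expected_rate_analytic()`), which is also reported.

The p-value is one-sided upper-tail with the add-one estimator,
$p = (1 + \#\{\text{null} \ge \hat p\})/(1 + N)$, so $p$ is never zero,
ties count toward the tail, and the floor is $1/(N+1)$. The effect size
is Cohen's $h = 2\arcsin\sqrt{\hat p} - 2\arcsin\sqrt{\bar p_0}$ against
the null mean $\bar p_0$, reported signed (positive = above chance).

### Why tests run per direction

The package computes results per session $\times$ dyad $\times$
direction (child responds / partner responds / pooled). Calibration is a
reason to prefer the directional series for inference, not merely a
reporting choice: in a pooled series the response column mixes both
speakers' language distributions. If the two speakers' base preferences
differ, the pooled empirical response marginal is a mixture whose
independence rate $m_0$ *exceeds* the true cross-speaker matching
probability (by $\tfrac12(b_1-b_2)^2$ for base rates $b_1,b_2$ in the
two-language case), so the pooled null is conservative. The directional
null has no such mixture and is exactly valid conditional on its
margins. Pooled results are still produced — their turn counts are the
sum of the directional ones — but the calibration guarantees in the test
suite are stated for directional series.

### Inclusion filters

Two filters flag sessions where the test is uninformative, applied to
the turn series' own language distributions (both roles, the stricter
reading):

* **Dominance** — if either role uses its most frequent language on at
  least 80% of turns (`dominance_threshold = 0.80`), chance matching is
  near ceiling; inclusion requires strictly less than 80% use of one
  language.
* **Too few turns** — fewer than 30 turns (`min_turns = 30`) makes the
  permutation baseline unstable.

Filters gate *interpretation*, not computation: excluded sessions still
carry a full result, flagged `DOMINANCE`, `TOO_FEW_TURNS` or `BOTH`. In
the attrition report the doubly excluded are counted once, under
dominance, with the overlap reported separately (`n_both`), so
`initial = excluded_dominance + excluded_turns + included` holds in
every row.

## Turn extraction choices

* **Adjacency is strict by default.** In multi-party sessions an
  utterance by a third speaker between two dyad utterances cancels the
  turn; this is the most conservative reading of "followed by" and a
  flag (`skip_third_party = TRUE`) relaxes it for sensitivity analysis.
* **Mixed/unknown utterances are invisible but opaque.** Utterances with
  both languages or no identifiable language cannot be coded and are
  dropped from matching, yet they still count as intervening events —
  they are real speech.
* **Chaining.** A response may serve as the previous utterance of the
  next turn (`chained = TRUE`); the alternative (each utterance used at
  most once) is available since annotation schemes differ on this.
* **Gaps.** No maximum response latency is imposed by default
  (`max_gap_ms = Inf`), and overlapping responses (negative gap) are
  allowed: onset order defines sequence.
* **Ordering is total and deterministic**: onset, then offset, then
  speaker id, then utterance id.

## Time, language and profile conventions

Times are integer milliseconds on half-open intervals `[onset, offset)`,
so segment durations sum exactly. Languages are the neutral tokens
`LANG_A` (the community-shared language) and `LANG_B` (the other family
language), making every statistic symmetric under relabeling — a
property the test suite checks globally. Speaker language proportions
are **time-weighted**, not utterance-counted: share of language
$\ell$ = time in $\ell$ / identifiable time, while the identifiable
proportion divides by total speech time. Undefined quantities are `NA`,
never 0 — a silent speaker is not a monolingual one. Cohort summaries
weight families equally (one value per speaker per session), and
multiple other-household members are averaged within a session before
grouping.

## Correlation comparisons

Session-level correspondence (do families whose caregivers use more of
language A also have children using more of it?) uses Pearson
correlations across families, compared two ways:

* independent samples (e.g. the two communities): Fisher's r-to-z,
  $z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)\big/
  \sqrt{\tfrac1{n_1-3}+\tfrac1{n_2-3}}$, with the difference CI
  back-transformed from the z scale;
* overlapping dependent correlations (child–caregiver vs child–others,
  sharing the child variable): Steiger's Z in the common variant that
  uses the average $\bar r$ of the two compared correlations in the
  covariance term. The specific formula is stated in
  `?steiger_dependent_z`; its correctness is checked in the suite by an
  independently coded arrangement of the formula and by rejection-rate
  calibration under a simulated trivariate-normal null.

Both report two-sided p-values. Inputs must be non-degenerate: zero
variance or $|r|=1$ raise errors rather than propagating infinities.

## The synthetic generator

`generate_session()` emulates the structure of a 20-minute home play
recording: a configured speaker sequence (strict alternation for a dyad,
or a Markov chain over speakers for multi-party sessions), uniform
utterance durations (default 0.5–3 s) and gaps (0.2–1.5 s), and 200
utterances per session by default. Language choice follows a one-
parameter coupling model: with probability $\lambda$ the speaker copies
the most recent identifiable language of *another* speaker, otherwise it
draws from its own base rate. Utterances are then relabelled wholly
unidentifiable with probability `unknown_rate` — much higher for
children (default 0.55 vs 0.08 for caregivers, matching how much toddler
speech defies language identification in home recordings) — or mixed
(default 0.05). Because coupling targets only identifiable
single-language speech, these injections behave as ignorable
missingness: they thin the turn count without biasing the retained match
rate, which the suite verifies.

The model makes $\lambda = 0$ coincide exactly with the test's null
(independent selection), and gives the moment identity
$E[\hat p] = \lambda + (1-\lambda) m_0$, inverted by
`estimate_coupling()` as $\hat\lambda = (\hat p - m_0)/(1 - m_0)$
(clipped to $[-1,1]$, raw value retained). Under balanced base rates the
estimator recovers $\lambda$ essentially unbiasedly; under strongly
asymmetric preferences the response marginal is itself shifted toward
the partner's languages and $\hat\lambda$ is attenuated — it is a
recovery oracle for simulation studies, not a fitted model for real
data. At $\lambda = 1$ a generated conversation collapses into a single
language, so the estimator is undefined there by construction ($m_0=1$).

What the generator does **not** emulate: realistic lexical content,
age- or exposure-dependent coupling, conversational topic structure,
within-utterance switching beyond a half/half split, or annotation
error. Passing tests therefore demonstrate the statistical machinery is
correct under the stated generative assumptions, not that real family
interactions follow the coupling model.

## Numerical and reproducibility choices

* 10,000 Monte Carlo iterations per test by default; the p-value floor
  is then $1/10001$.
* All randomness flows from one integer seed; `permutation_null()` and
  the generator restore the caller's RNG state, and every result records
  its seed. The pipeline derives per-session sub-seeds deterministically
  from the master seed, making whole runs byte-identical.
* Floating-point tie tolerance of $10^{-12}$ when counting null
  replicates at least as extreme as the observed rate.
* Distributions passed to `expected_rate_analytic()` must sum to 1
  within $10^{-6}$; Steiger inputs must form a positive semi-definite
  correlation triple (determinant tolerance $10^{-12}$).

The suite's simulation sizes were chosen to make each check sharp at
desk scale: calibration uses 200 null sessions of 60 directional turns
at 1,000 iterations per session (the rejection rate must land in the
exact binomial 95% band around 0.05); exact-enumeration equivalence uses
series of up to 7 turns at 50,000 iterations against all $n!$ pairings
(total variation < 0.02); coupling recovery uses 100 replicates of
200-turn sessions at $\lambda \in \{0.3, 0.6\}$ (mean error ≤ 0.05); and
power uses 200 replicates of 100-turn sessions at $\lambda = 0.5$
(rejection ≥ 90%).

A note on calibration: with 60 turns the permutation null is discrete,
so the achievable size at $\alpha = 0.05$ is below nominal — typically a
rejection rate of 0.02–0.035 rather than 0.05. That conservatism is a
property of exact discrete tests, not an implementation artefact; the
calibration check accordingly asserts the band, not the point value.

## Known limitations

* The dominance filter evaluates the turn series' own distributions;
  session-level profiles can differ (a configurable choice).
* The canonical table cannot represent a rostered speaker with zero
  utterances; such speakers survive in-memory but not a round trip.
* An utterance whose only segment is a full-span `UNKNOWN` row is
  normalised on read to the equivalent empty-segment representation.
* EAF ingestion assigns language-tier annotations to the utterance
  containing their midpoint and clips them to its span; exotic tier
  geometries may need a custom `tier_map` or pre-processing.
* The pooled-direction test is conservative when the two speakers'
  preferences differ (see above); use directional results for inference.
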