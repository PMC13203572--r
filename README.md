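# langalign

Turn-by-turn language alignment analysis for bilingual conversations.

## The problem

Bilingual caregivers and children constantly choose which language to use.
High matching rates across conversational turns can arise for a trivial
reason — both speakers simply prefer the same language — so apparent
"alignment" must be tested against what independent language selection
would already produce. `langalign` implements that analysis for timed,
speaker- and language-tagged utterance annotations of recorded play
sessions (ELAN EAF files or a plain delimited table):

- **Speaker profiles.** Time-weighted language-use proportions on
  identifiable speech (p_A = t_A / (t_A + t_B)) and the identifiable
  share of each speaker's total speech time.
- **Turn extraction.** Dyadic conversational turns (utterance by one dyad
  member immediately followed by the other), each coded *match* or
  *switch*; mixed-language and unidentifiable utterances are excluded
  from coding but still break adjacency.
- **Monte Carlo alignment test** (the core). For a series of n turns with
  observed match rate p̂, the null re-pairs response languages with
  previous languages by uniform random permutation — preserving both
  speakers' observed language counts exactly — giving a
  frequency-preserving null distribution of match rates. The one-sided
  p-value uses the add-one estimator p = (1 + #{null ≥ p̂}) / (1 + N),
  and the effect size is Cohen's h = 2·asin(√p̂) − 2·asin(√p̄₀) against
  the null mean p̄₀. Sessions with ≥ 80% use of one language or < 30
  turns are flagged as excluded, mirroring the usual balance and
  stability filters.
- **Correspondence statistics.** Pearson correlations between family
  members' language proportions, Fisher's r-to-z test for independent
  correlations, and Steiger's Z for overlapping dependent correlations.
- **Synthetic sessions.** A seeded generator with known coupling λ (the
  probability of copying the partner's last identifiable language;
  E[match] = λ + (1 − λ)·m₀ under independence rate m₀) plus the
  moment estimator λ̂ = (p̂ − m₀)/(1 − m₀), used for calibration, power
  and recovery studies.

Intended users: developmental psycholinguists and speech-interaction
researchers analysing code-switching and language coordination in
annotated multi-speaker recordings.

## Worked example

```r
library(langalign)

cfg <- synthetic_dyad_config(coupling = 0.5, base_rate_A = 0.4,
                             n_utterances = 200, seed = 42)
session <- generate_session(cfg)
turns <- extract_turns(session, direction = "CHILD_RESPONDS")
fit <- alignment_test(turns, n_iterations = 10000, seed = 1)
summary(fit)
#> <alignment_test> synthetic, dyad CHI <-> CG1, direction CHILD_RESPONDS
#>   32 turns; observed match rate 0.781 vs null 0.505 (sd 0.088)
#>   one-sided p = 0.0027 (10000 iterations), Cohen's h = 0.59
#>   inclusion: included
#>   previous languages: A 15 / B 17; responses: A 14 / B 18
#>   analytic independence rate 0.504; coupling estimate 0.559
```

The child matched the caregiver's language on 78% of 32 codable turns.
Random re-pairing of the same language choices matches only 50% of the
time, so the surplus is genuine turn-level coordination (p ≈ 0.003,
medium-to-large effect h ≈ 0.59); the moment estimator recovers a
coupling near the generating λ = 0.5. `coef(fit)` returns these numbers,
`plot(fit)` draws the null distribution with the observed rate marked.

For a whole cohort, `run_pipeline()` (or
`Rscript inst/scripts/run_langalign.R --input cohort.tsv --out results/`)
writes speaker profiles, usage summaries, the model-ready turn-level
table, per-session alignment results, an attrition report, and the
correspondence tables, all reproducible from one seed.

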