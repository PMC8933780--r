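---
title: "Modeling moral dilemma judgments: traditional scores, process dissociation, and the CNI tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling moral dilemma judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnidilemma)
```

## The battery and its three levels of analysis

A sacrificial moral dilemma pits harm to a few against benefit to many: the
respondent accepts or refuses a focal action. The battery analysed here
crosses 6 dilemma stories with two manipulations — the moral norm
(proscriptive: the norm forbids the action; prescriptive: it mandates it)
and the consequences (benefits of acting greater or smaller than its costs) —
giving 24 scenarios and four conditions of 6 trials each. Acceptance is coded
1, refusal 0.

Three progressively finer analyses are implemented:

1. **Traditional score** — the number of acceptances (0–6) in the
   proscriptive/benefits-greater condition, where acceptance is read as a
   utilitarian judgment. Compared against the neutral point 3 (one-sample
   *t*) and between groups (pooled-variance *t*). Its weakness is that it
   treats utilitarian and deontological responding as complements of one
   judgment.

2. **Process dissociation (PD)** — uses the two proscriptive conditions.
   Writing `p_c` and `p_i` for the probabilities of judging the action
   *unacceptable* in the congruent (benefits smaller; norm and consequences
   agree) and incongruent (benefits greater; they conflict) conditions, the
   PD model assumes unacceptability arises as `U + (1-U) D` in congruent and
   `(1-U) D` in incongruent dilemmas, with `U` the utilitarian and `D` the
   deontological inclination. Solving gives `U = p_c - p_i` and
   `D = p_i / (1 - U)`. `U` can be negative in noisy data; at the
   pure-utilitarian corner `U = 1`, `D` is unidentified and returned as
   missing (such participants are excluded listwise from `D` analyses).
   `U` and `D` are z-standardized over the pooled analysed sample — both
   groups together, with the n−1 SD — which is why the group means of the
   z-scores weight to zero. Pooled (rather than within-group)
   standardization was chosen because it preserves between-group location
   differences, which are the object of the group ANOVA.

3. **The CNI multinomial processing tree** — separates three latent
   processes: with probability `C` the respondent follows the consequences;
   failing that, with probability `N` the norm; failing both, with
   probability `I` they default to inaction. The four condition probabilities
   of *accepting* the action are

   | condition | P(action) |
   |---|---|
   | proscriptive, benefits greater | `C + (1-C)(1-N)(1-I)` |
   | proscriptive, benefits smaller | `(1-C)(1-N)(1-I)` |
   | prescriptive, benefits greater | `C + (1-C)N + (1-C)(1-N)(1-I)` |
   | prescriptive, benefits smaller | `(1-C)N + (1-C)(1-N)(1-I)` |

   The model is fitted to *aggregate* counts (trials pooled within group),
   the convention of standard multinomial-tree software: per-participant
   heterogeneity is ignored in estimation, although the simulator can
   generate it to stress robustness.

## Estimation and inference

`fit_cni()` maximizes the binomial log-likelihood over `(C, N, I)` in
`[0,1]^3` with bounded quasi-Newton (`L-BFGS-B`, objective tolerance via
`factr = 1e4`, i.e. about 1e-11 relative) from 10 starts: the closed-form
moment estimate — the tree inverted on the four observed proportions — plus
9 deterministic Halton points. The multi-start guards against ridges; the
number of starts agreeing with the optimum is recorded, and in practice all
starts agree on well-behaved data. Likelihood evaluation clamps cell
probabilities to `[1e-9, 1 - 1e-9]`.

Goodness of fit is `G² = 2 (LL_saturated − LL_model)` with
`df = cells − free parameters` (one group: 4 − 3 = 1; two groups free:
8 − 6 = 2). Hypotheses are tested by refitting under a nested constraint and
referring `ΔG² = G²_constrained − G²_free` to χ² with df equal to the number
of constraints imposed: fixing one parameter in one group is 1 df, and
equating a parameter across two groups is likewise 1 df. Some published
tree analyses report group-equality tests with 2 df; the df convention here
is always the constraint count and is returned explicitly so either can be
reported.

Confidence intervals are Wald: estimate ± z·SE with SE from the inverse of
the numerically differentiated observed information, clipped to `[0,1]`.
Estimates within 1e-4 of a bound are flagged as boundary fits, where Wald
theory is unreliable; a singular information matrix yields flagged `NA`
intervals rather than an error. Profile or bootstrap intervals are not
implemented, so published interval widths should be compared qualitatively.

### Reconstructing counts from printed summaries

When only condition means (0–6 scale, two decimals) and group sizes are
published, `counts_from_condition_means()` recovers the aggregate acceptance
count as the unique integer `a` with `|a/n − mean| < 0.005` whose recomputed
mean rounds back to the printed value; ambiguity or impossibility is an
error rather than a silent guess. The bundled `example_study_means()` — a
two-group battery with 38 healthy controls and 89 participants over an
internet-addiction cutoff — reconstructs exactly and is the worked example
throughout:

```{r}
counts <- counts_from_means_table(example_study_means(), pooled = TRUE)
fit_cni(counts)
```

## Surrounding statistics

The group pipeline (`run_full_analysis()`) mirrors the standard report
order. Group assignment uses Young's Internet Addiction Test (YIAT, total
20–100): scores ≤ 40 are controls, ≥ 50 the internet-addiction group, and
41–49 are retained in the files but excluded from analysis (cutoffs are
configurable). The mixed 2×2 ANOVA (group × within-factor) uses the standard
least-squares partitioning via an `aov()` participant error stratum; with
two within levels sphericity is trivial. Simple effects are pooled-variance
between-group contrasts at each within level. Effect size is partial eta
squared per error stratum. The YIAT–parameter associations are reported by
both Spearman's rho (t-approximation p, exhaustive permutation available for
n ≤ 8) and Pearson's r, since published reports sometimes label one as the
other. Demographic comparisons from printed summaries use the pooled
`t_from_summary()` and the uncorrected 2×2 Pearson χ². Cohen's d always uses
the pooled SD; published d values computed by other conventions will not
match exactly.

## The synthetic respondent generator

`simulate_trials()` emulates what the analysis assumes: each participant
draws `(C, N, I)` — the group values perturbed logit-normally with SD
`heterogeneity_sd` (0 = homogeneous; the clamped-logit map keeps draws in
(0,1) and nests the homogeneous case exactly, including parameters at 0 or
1) — and answers each of the 24 scenarios with an independent Bernoulli draw
at the tree probability. YIAT scores are uniform within the group's cutoff
region; they are grouping covariates only, with no claim of realistic YIAT
psychometrics. Difficulty ratings come from a simple additive model
(baseline 3, shifts for incongruent-proscriptive conflict and group,
Gaussian noise, clipped to 1–5). One integer seed drives a single random
stream, so whole experiments are exactly reproducible.

What the generator does *not* emulate: story-level random effects (the 6
stories within a condition are exchangeable, since published aggregates give
no per-story breakdown), response times, order effects, or realistic
questionnaire distributions. Passing recovery tests therefore validate the
estimator under the model's own assumptions — they do not certify the model
against real-data violations such as story heterogeneity.

```{r}
rec <- recovery_experiment(c(0.2, 0.3, 0.45), n_participants = 100,
                           replicates = 20, seed = 1)
rec$summary
```

## Numerical choices and problem sizes

- Optimizer: 10 starts by default (4 in `recovery_experiment()`, where the
  aggregate surfaces are smooth unimodal); convergence failures across all
  starts raise an error carrying nothing silently.
- Degenerate inputs: zero-variance score vectors, empty margins, constant
  correlation inputs, and `U = 1` PD corners are errors or flagged missing
  values, never silent numbers.
- Test-suite problem sizes were chosen to keep the full run at desk scale:
  parameter recovery uses 200 replicates of 100 participants, interval
  coverage 200 replicates of 500 homogeneous participants, and the
  grid-search oracle a 201³ exhaustive evaluation over 20 random count
  configurations.

## Known limitations

Aggregate fitting ignores participant heterogeneity, so standard errors are
conditional on the homogeneity assumption; hierarchical or latent-trait tree
models are out of scope, as are general tree languages and extensions with
additional parameters. The PD decomposition uses only proscriptive
dilemmas, by construction.
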