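---
title: "Evaluating identifier mapping and filtering by data integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating identifier mapping and filtering by data integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput platforms label their features with identifiers, and any
cross-platform analysis depends on *identifier mapping* (IDM): declaring that
probeset `201234_at` measures the transcript whose protein product is
accession `P07355`, say. Mapping resources disagree with each other, and
*identifier filtering* (IDF) methods that discard less-believable features
disagree too. An analyst choosing among them usually has no data-grounded
way to compare them.

`idmeval` implements a decision-theoretic evaluation: given two
feature-by-sample matrices on the same biological samples (e.g. microarray
signals and protein spectral counts) and the pair sets asserted by several
candidate methods, it scores every pooled ID pair by cross-sample
association, converts scores to posterior probabilities of correct mapping
through a measurement-error mixture model, and ranks methods — or Boolean
combinations of them, or quality thresholds — by expected utility.

## Data model: three kinds of pairs

Every ID pair falls into one of three latent groups:

* **"+"** — correctly identified and mapped, and biologically *coupled*: the
  association across samples is genuinely nonzero;
* **"0"** — correctly mapped but *decoupled* (discordant): post-translational
  regulation, feedback, splicing variation and similar causes detach the two
  measurements;
* **"x"** — mis-identified or mis-mapped.

A single data set cannot tell "0" from "x" — both manifest as association
near zero — so they are pooled into a "−" group for estimation. What *can*
be estimated is each pair's probability of being in "+", and that is enough
to compare methods, because a better method is enriched for correct pairs.

## Scores and their measurement error

The per-pair model-quality score is the correlation (Pearson by default,
Spearman optionally) between the two platforms' measurements over the shared
samples, computed on pairwise-complete observations; pairs with fewer than 4
complete observations, or a constant vector on either side, are excluded and
counted. Each score carries a measurement-error variance
$\sigma^2_p$ estimated by a nonparametric case bootstrap (samples resampled
jointly for the two vectors; 200 replications by default). Replicates where
a resampled vector is constant — common with sparse spectral counts — are
redrawn up to 100 times before the pair is declared degenerate.

For bivariate normal data the bootstrap spread tracks the normal-theory
variance of a correlation estimate; `normal_theory_variance()` provides that
reference curve, in the plain convention $(1-\rho^2)/(n-3)$ by default with
the classical squared-numerator form behind a switch.

Per-pair RNG streams are derived from the master seed and a stable hash of
the pair's IDs, so score tables are reproducible and independent of pair
ordering.

## The mixture model and its ECM fit

Conditional on its group, a pair's observed score is modelled as

$$ MQ_p \sim N\!\left(\psi_{G(p)},\; V_{G(p)} + \sigma^2_p\right), $$

with $\psi_+$ free, the "−" mean constrained to zero, prior weight $\pi_+$
on "+", latent variances $V_+$ and $V_-$ (the latter the
probability-weighted pool of the "0" and "x" variances, which are not
separately identifiable), and the known per-pair $\sigma^2_p$ added on. The
four unknowns $(\psi_+, \pi_+, V_-, V_+)$ are estimated by
expectation–conditional-maximization:

* **E-step** — responsibilities from the current parameters, in log space;
* **CM-steps** — $\pi_+$ as the mean responsibility and $\psi_+$ as the
  responsibility- and precision-weighted mean (weights
  $r_p/(V_+ + \sigma^2_p)$), both closed-form; then $V_+$ and $V_-$ each by
  one-dimensional bounded maximization (Brent search on $[0, 10]$) of the
  expected complete-data log-likelihood, since heteroscedastic
  $\sigma^2_p$ leave no closed form.

Each cycle ascends the observed-data log-likelihood; the trace is stored and
asserted non-decreasing in the test suite. Convergence is declared when the
relative log-likelihood change falls below $10^{-8}$ (at most 2000 cycles).

Numerical choices worth recording:

* **Initialization** — deterministic: $\pi_+$ starts at the fraction of
  scores above 0.25, $\psi_+$ at their mean, both variances at
  $\max(\mathrm{var}(MQ) - \overline{\sigma^2}, 10^{-4})$. The likelihood is
  well-behaved in practice and no random restarts are performed by default;
  pass `init =` to multi-start manually.
* **Boundaries** — if a variance estimate hits 0 the component density runs
  on $\sigma^2_p$ alone, with a $10^{-12}$ variance floor guarding pairs
  whose $\sigma^2_p$ is itself zero.
* **Sign convention** — "+" means positive coupling. For settings where
  correct mappings manifest as *negative* association (microRNA against its
  target transcript), `negative_coupling = TRUE` reflects the scores before
  fitting and un-reflects in every downstream method.
* **Scale** — raw correlations, not Fisher-z; the z-transform is available
  (`fisher_z = TRUE`) but off, since the mixture is specified on the
  correlation scale.

## Posteriors and their uncertainty

Plugging the estimates in gives each pair an empirical-Bayes posterior
probability of correct coupled mapping — the prior odds
$\hat\pi_+/\hat\pi_-$ times the ratio of the two component densities,
computed in log space so extreme scores saturate cleanly. The delta method
converts the score's measurement variance into a posterior-probability
variance

$$ v^*_{+p} = \sigma^2_p\,(\pi^*_{+p}\pi^*_{-p})^2
   \left[\frac{MQ_p}{\hat V_- + \sigma^2_p}
       - \frac{MQ_p - \hat\psi_+}{\hat V_+ + \sigma^2_p}\right]^2 . $$

A very noisy pair ($\sigma^2_p$ large) ends up with a posterior pinned near
a prior-determined value and *insensitive* to its score — the bracket above
vanishes — so its posterior variance is small even though the pair is
uninformative. This behaviour is intended and tested.

## The decision framework

For a candidate method $M$ with pair set $S(M)$, the proportion of correct
pairs is estimated by the precision-weighted mean of the posteriors, weights
$1/v^*_{+p}$. Expected utility per pair is then

$$ EU^{(1)} = \hat P_{+M}\left[U_{TP}\,\delta_+^{-1}
   + L_{FP}\,(2 - \delta_+^{-1})\right] - L_{FP}, $$

with $U_{TP}$ the utility of keeping a correct pair, $L_{FP}$ the loss of
keeping a wrong one, and $\delta_+$ the assumed fraction of correct pairs
that are coupled (default 1: the "0" group treated as empty; at
$\delta_+ = 1$ the expression collapses to
$U_{TP}\hat P_{+M} - L_{FP}(1 - \hat P_{+M})$). Total expected utility is
$n_M \times EU^{(1)}$; the break-even proportion is
$L_{FP}/(U_{TP}+L_{FP})$. A stricter method can win on per-pair utility yet
lose on total utility by returning too few pairs — both criteria are
reported, and the ranking is invariant to rescaling both utility constants.

**Weight capping.** The delta-method variance degenerates to zero both for
saturated posteriors (its $(\pi^*\pi^{*}_-)^2$ factor) and at the score
where the two component log-densities have equal slope. Raw reciprocal
weights would then let a single extreme pair stand for a whole method,
which contradicts the aggregate character of the evaluation — no single ID
pair proves anything about a mapping resource. `weighted_p_plus()` therefore
floors the variances at `median(v*)/100`, capping any record's weight at 100
times the typical record's (tunable via `max_weight_ratio`; exact zeros are
subsumed by the same floor). With well-separated, low-noise data the capped
and uncapped estimates can differ materially; with realistic noisy data the
cap rarely binds.

Display rounding — proportions and per-pair EU to 3 decimals, total EU to
the nearest integer — is applied only by `format_evaluation()`, never inside
a computation.

## Threshold sweeps

For event-level quality thresholds (tandem-MS spectral events carrying
XCorr- and DeltaCn-like scores), `threshold_sweep()` takes a grid of
proportions (canonically $0$ and $2^{-k}, k = 8,\dots,1$), computes each
score's empirical quantile (linear-interpolation convention) at every
proportion, retains events strictly exceeding both, re-aggregates retained
events into per-protein per-sample counts, re-scores the pairs
(correlations *and* bootstrap variances are recomputed, since the data have
changed), but converts to posteriors with the *frozen* mixture fit from the
unfiltered data — refitting would move the yardstick between thresholds.
Proteins that lose all events drop out, so the surviving pair count can
shrink at stringent thresholds.

## What the synthetic module emulates

All tests run on generated data; `sim_config()` fixes the study conditions:

* **98 samples** — the size of the motivating proteotranscriptomic cohort
  (91 cancer + 7 non-cancer), so variance scales are comparable;
* **group composition** 40% "+", 10% "0", 50% "x";
* **score-level generator** — draws directly from the mixture with
  $(\psi_+, \pi_+, V_-, V_+) = (0.45, 0.40, 0.01, 0.02)$ and
  $\sigma^2_p \sim U(0.002, 0.02)$, used for parameter-recovery checks;
* **two-platform generator** — coupled pairs target a correlation drawn
  from $N(0.45, 0.14)$ (truncated to $[0.05, 0.9]$); mis-mapped pairs are
  realized by *rewiring* the secondary feature to a wrong primary feature,
  so they keep realistic marginals; the primary platform passes through a
  sparse Poisson link (mean count 2.5 at average abundance), which
  attenuates observed correlations and inflates bootstrap variances the way
  spectral counting does; and every pair carries a nuisance correlation
  $N(0, 0.2)$ with its listed partner, standing in for global sample-level
  variation (batch, cellularity, RNA quality) that gives real data a broad
  rather than spike-like "−" component;
* **candidate methods** — each draws a configured fraction of its pairs
  from the correct pool and the rest from the mis-mapped pool; uniform
  sampling from the correct pool gives all methods the same expected
  coupled fraction among correct pairs, the condition under which observed
  proportions of strong correlations rank mapping quality consistently;
* **event tables** — genuine events follow latent protein abundance with
  high quality scores; a configurable fraction are mis-assigned to random
  proteins with low scores, so moderate quantile filtering provably helps.

What the generator does **not** emulate: real annotation structure
(one-to-many mappings are supported by the data model but not generated by
default), platform-specific normalization artifacts, missingness patterns,
or correlated quality scores within a protein. Passing tests therefore
demonstrate the statistical machinery under the assumed model, not the
quality of any real annotation resource.

Problem sizes in the test suite were chosen to keep the full run around a
minute on one core: parameter recovery uses 20 replicates of 5000 scores,
the bootstrap-versus-theory comparison 500 pairs at 200 replications, the
end-to-end ranking study 20 replicates of 400-pair cohorts.

## Known limitations

* The "0"/"x" split is not identifiable from one data-set pair; $\delta_+$
  is a subjective input, not an estimate.
* The plug-in posterior ignores the sampling uncertainty of the mixture
  parameters; with thousands of pairs this is minor, with hundreds it is
  not.
* Eq-style weighting (inverse delta-method variance) is a heuristic, not an
  optimality result, once posteriors leave the mid-range — hence the weight
  cap discussed above.
* The weighted regression of posteriors on method indicator variables is
  deliberately out of scope; the posterior table exports the
  $1/v^*$ weights so any modelling environment can fit it.

## A minimal run

```{r, eval = FALSE}
library(idmeval)

cfg <- sim_config(n_pairs = 300, seed = 1)
sim <- simulate_two_platform_data(cfg)
maps <- simulate_methods(sim$true_map, cfg$method_specs, seed = 2)
pairs <- pool_pairs(maps)

merged <- merge_by_sample(sim$primary, sim$secondary, pairs)
scores <- score_all_pairs(merged, n_boot = 200, master_seed = 1)

fit <- mq_mixture(scores)
plot(fit)
post <- posterior_table(scores, fit)
format_evaluation(evaluate_methods(post, sort_by = "eu_mean"))
```
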