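---
title: "Methods: simulating an in silico ADHD trial with virtrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating an in silico ADHD trial with virtrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtrial)
```

## What the package models

`virtrial` is an engine for *in silico* clinical trials (ISCT) of CNS
stimulants in ADHD. The trial it simulates has four layers:

1. **Virtual populations.** Randomized cohorts of virtual patients (age, sex,
   weight, height, BMI, comorbidity profile) matched to reference trial
   demographics within a tolerance, with hard quotas per comorbidity profile.
2. **Per-patient pharmacokinetics.** A 14-compartment whole-body PBPK model
   turns a dosing regimen into per-patient concentration curves, and those
   into signed per-target modulation intensities.
3. **Network response models.** Drug effects propagate through a directed
   signed protein network. One *mathematical solution* is a positive weight
   assignment to the network's edges; ensembles of solutions trained against
   drug-efficacy restrictions represent biological variability. Propagating
   a patient-specific stimulus through a solution yields protein activities
   in $[-1, 1]$.
4. **Outcome statistics.** The *tSignal* efficacy proxy, the reverted-protein
   taxonomy, enrichment, stimulus sensitivity analyses, and demographic /
   comorbidity / co-treatment comparisons.

The protein network, disease definition, expression data, reference
demographics and comparator drug pools used by the original trial platform
are proprietary or external. The `generate_*` family therefore produces
synthetic counterparts with controlled statistical structure, so that every
pipeline stage is exercised offline and every statistical guarantee is
testable. Results obtained on these synthetic inputs validate the
*machinery*, not the biology: they show the pipeline computes what it claims
to compute, not that a particular drug works.

## Disease, drugs and stimuli

ADHD is represented as four signed protein sets ("motives"): neurotransmitter
imbalance, neuroinflammation, circadian system imbalance and altered neural
viability. A disease sign of $+1$ means the protein is abnormally active in
the disease state. Drugs are signed target sets ($+1$ activation, $-1$
inhibition); the shipped `stimulant_targets.tsv` fixture carries the
lisdexamfetamine (7 targets) and methylphenidate (3 targets) definitions,
with per-drug membership decided by the presence of a literature-reference
cell.

A *stimulus set* maps proteins to signed intensities in $[-1, 1]$. Stimuli
are built by summing contributions — the drug's PK-attenuated target
modulation, a comorbidity profile's molecular definition at a baseline
intensity (default 0.5, a deliberate mid-scale choice; nothing in the
pipeline is sensitive to it being exactly 0.5, and it is a
`baseline_intensity` argument throughout) — and clipping to $[-1, 1]$.
Summation makes opposite-sign co-treatment conflicts antagonize: a protein
activated by one drug and inhibited by the other at equal intensity receives
a net stimulus of zero. Both entries are kept in the merged drug definition
with a `conflict` flag, so the cancellation is visible rather than silent.

## Synthetic input generators

Every generator is a pure function of (configuration, seed).

* **Network** — directed Erdős–Rényi topology with Rademacher ($\pm 1$) edge
  signs and half-normal $|N(0,1)|$ weights, regenerated until weakly
  connected. This is the simplest signed substrate on which propagation,
  training and sensitivity behave nondegenerately. It does not emulate the
  scale-free degree structure, motif composition or curated edge signs of a
  real interactome; conclusions about *which* proteins matter do not
  transfer.
* **Disease embedding** — motive members sampled without replacement with
  random signs, giving disjoint motives (real motives may overlap; the
  counting code supports overlap and is tested on constructed overlapping
  cases).
* **Expression data** — controls are unit-variance Gaussian noise; cases are
  shifted by `effect_size` on the disease genes only. This makes the
  power computation analytically checkable: the pooled disease-gene score has
  a known standardized effect. Real transcriptomic covariance, batch
  structure and heavy tails are deliberately absent.
* **Reference demographics** — per-block age ranges fixed to the trial
  strata (children 6–12, adolescents 13–17, adults 18–65); block means
  jittered ±2% by seed to emulate drawing references from different source
  trials.
* **Drug pool** — target-set sizes uniform over a range, uniform node
  targets, random signs; the stand-in for sampling comparators from a large
  drug database.
* **Restrictions** — one per training drug with known clinical efficacy: its
  full-intensity stimulus must produce a sign-adjusted tSignal within
  `efficacy ± 0.15`. The band half-width makes "accuracy = fraction of
  restrictions satisfied" well defined; 0.15 is wide enough for a random
  synthetic network to satisfy several bands simultaneously and narrow
  enough that training is not vacuous. It is configurable and echoed in
  every restriction object.

## Population construction

`minimum_cohort_size()` computes the per-sample pooled disease-gene score,
estimates its standardized case–control effect $\hat d$, and returns the
smallest per-group $n$ at which the two-sided two-sample t test reaches the
target power (default 95% at $\alpha = 0.05$), by integer search on the
noncentral-t power curve. The paper-level configuration fixes the resulting
study minimum at 71 patients per cohort; `cohort_spec()` carries that value
and `sample_cohort()` rejects any request below it.

The default specification per population is 1,300 patients: at least 100 in
each of the eight comorbidity profiles and at least 500 in the main
no-comorbidity group. Quotas are hard postconditions — profiles are assigned
by exact counts and shuffled, never "best effort". Continuous variables are
drawn from truncated normals (inverse-CDF method) within the reference
bounds, sex from a Bernoulli, and whole cohorts are redrawn until every
per-block summary (mean age, weight, height, proportion female) lies within
the tolerance of its reference value. The "5% tolerance" is interpreted as
±5% *relative* deviation of each summary statistic: it is scale-free and
auditable from the validation report. Pediatric populations split the child
and adolescent blocks evenly in expectation.

## The PBPK layer

The 14 compartments are gut lumen, gut tissue, liver, kidney, brain, heart,
lung, spleen, muscle, adipose, skin, bone, and arterial and venous blood —
the canonical whole-body flow-limited topology. Gut tissue and spleen drain
portally into the liver; all organ outflows collect in venous blood, pass
the lung, and return arterially. Reference volumes and flows describe a
70 kg adult with a cardiac output of 322 L/h.

Design choices worth knowing:

* **Bioavailability as an absorption fraction.** Oral input is first-order
  from the gut lumen; the fraction $F$ multiplies the absorption flux, and
  $1 - F$ is booked as unabsorbed (lumping gut and first-pass hepatic loss).
  Because the system is linear, the realized oral/iv venous AUC ratio equals
  the configured $F$ identically — the shipped Elvanse (96.4%), Medikinet
  (30%) and Concerta (32%) parameter files reproduce their labels by
  construction, which is the intended contract.
* **Renal-only elimination**, from the kidney compartment at clearance
  `CL`, hepatic loss being folded into $F$.
* **Scaling.** Volumes scale as $W/70$, flows and clearance as
  $(W/70)^{0.75}$. The shipped demographic multiplier table applies a 0.95
  flow factor for females; age-block factors are neutral because the
  allometric exponent already carries the pediatric perfusion trend — an
  explicit design choice, kept in a table so it can be revised without
  touching code.
* **Numerics.** `deSolve::lsoda` with relative tolerance $10^{-8}$,
  absolute $10^{-10}$, output grid 0.1 h; repeated doses enter as solver
  events. The venous AUC is accumulated as an extra ODE state rather than by
  trapezoid on the output grid — an iv bolus decays on a minutes scale and
  grid-based quadrature overestimates its AUC substantially.
* **Exposure summary.** Per-target modulation intensity is the mean receptor
  occupancy $C/(C + \mathrm{EC}_{50})$ at the effect site (brain by default)
  over the final dosing interval. An interval average is stable under
  regimen changes where a $C_{\max}$ summary is not.

Mass balance closes exactly: in-system amount plus eliminated plus
$F \times$ residual lumen content equals $F \times$ dose, tested to
$10^{-4}$ relative across random patients, and AUC is linear in dose to
$10^{-6}$.

## The network response engine

Propagation is the bounded recursion
$x_{t+1}(v) = \tanh\!\big(\sum_{u \to v} \mathrm{sign}_{uv}\, w_{uv}\,
x_t(u) + s(v)\big)$ from $x_0 = 0$, run for diameter + 2 steps by default so
signal can traverse the graph with margin. The tanh keeps activities
strictly inside $(-1, 1)$; a node receiving no signal stays exactly 0.

Training draws a candidate by multiplicative log-normal re-weighting of the
network's edges, then hill-climbs for up to 500 iterations, perturbing 15%
of the weights per step and accepting whenever a smooth loss (squared
distance of each restriction's tSignal from its band) does not increase.
Accuracy — the *fraction of restrictions satisfied* — is too coarse to climb
on directly, which is why the loss exists. A candidate is retained only if
its accuracy is strictly greater than 0.85; training repeats until the
requested ensemble size is reached or a retry budget (10× the ensemble size)
is exhausted, and fails loudly if nothing is retainable. Everything is
deterministic per seed.

Two structural readings were fixed here and matter for interpretation:
retained solutions have accuracy **strictly above** 0.85 (the filter's
purpose is excluding low-accuracy solutions); and solutions are **shared at
the population level** with patient-specificity entering through the
stimulus (PK-attenuated intensities and comorbidity definitions), not
through per-patient retraining.

## Outcome statistics

The **tSignal** is the mean *sign-adjusted* activity over the disease set:
each protein contributes $-\mathrm{sign}_D(p)\, x(p)$, so positive tSignal =
disease reversion and the value works directly as an efficacy proxy. The
sign convention lives in exactly one function (`tsignal()`); if raw signed
averaging is ever wanted, that is the only place to change.

A disease protein is **reverted** when $|x(p)| > 0.5$ (strict) *and* the
direction opposes its disease sign — the magnitude threshold alone would
count proteins pushed further into their disease state.
**Differentially reverted** proteins differ between two drugs by two-sided
Wilcoxon rank-sum across solutions, BH-corrected over the tested family;
all-tied proteins stay in the family with FDR 1. **Most strongly reverted**
proteins additionally admit a single activity threshold separating the two
drugs' solutions with 100% accuracy, which for one dimension is exactly
range disjointness (verified against brute-force threshold enumeration). The
nesting most-strongly ⊆ differentially ⊆ reverted-by-either is asserted on
every pipeline run. Enrichment is upper-tail hypergeometric over a stated
universe with BH across terms.

## Sensitivity analyses

The one-at-a-time sweep scales a single target's stimulus to 0/25/50/75/100%
of the drug's modulation, propagates the solution sample, and reports the
mean tSignal as a percentage of the unmodified model — the reference row is
100% by construction, and a level-0 entry equals deleting the target. The
derivative of the tSignal with respect to a target intensity is realized as
this finite-difference grid, not an analytic derivative.

Target-set robustness extends the stimulus with $j = 1..20$ random non-target
proteins at full intensity with random signs, 50 fresh sets per $j$ (sets at
different $j$ do not nest), and reports percent-of-reference per set. The
solution subsample for these analyses is a uniform draw of
round-half-up(fraction × pool), floor one — at the study's 5% this maps a
25,000-solution pool to exactly 1,250.

## Cohort-level comparisons

Group tests are gated by a Jarque–Bera normality check on each group (the
closed-form moment statistic against $\chi^2_2$): both normal → Student's t,
otherwise Wilcoxon, with significance bands `ns` / `<0.05` / `<0.001`.
Demographic effects use Pearson correlation with the categorical strength
bands Strong ($|\rho| \ge 0.8$), Moderate ($\ge 0.5$), Low ($\ge 0.3$),
Negligible, overridden to NotSignificant at FDR ≥ 0.05. When a single test
is corrected for a family of $m$ tests computed elsewhere, the rank-1 BH
bound $\min(1, p\,m)$ is used — exact when the test has the family's
smallest p, conservative otherwise.

"Isolating" age from BMI (and vice versa) is implemented as correlation
within quantile strata of the other covariate (default 3 strata), mirroring
the question "does the age effect persist when BMI is held low?"; a partial
correlation answers a different, model-based question and was deliberately
not made the default. Co-treatment impact combines a direct two-group test
with an empirical null over a random drug pool: the pool p-value is
$(r + 1)/(n + 1)$, the add-one-smoothed fraction of pool co-treatments
shifting the mean tSignal at least as much as the observed one.

## Problem sizes, calibration and limits

The test suite runs the full battery at deliberately small scale — a 40-node
synthetic network, 4-protein motives, 6-solution ensembles, cohorts of
71–1,300 — so a complete run takes under a minute; the sizes are a package
choice to keep the feedback loop tight, and every size-dependent claim
(quotas, subsample arithmetic, the 50 × 20 robustness design) is asserted at
the study's own numbers. Statistical calibration is checked by simulation:
null demographic correlations reject at the nominal rate over 200
replicates, and a planted age effect of $\rho = 0.65$ at $n = 500$ is
recovered with the right sign and category in at least 95 of 100 seeds.

Known limitations: the synthetic network carries no biological identity, so
protein-level findings on it are exercises, not predictions; the PBPK
parameter files are plausibility-level parameterizations whose contract is
the bioavailability identity, not fitted concentration curves; prodrug
conversion (lisdexamfetamine → d-amphetamine) is not modeled as a separate
species; and the hill-climbing trainer is a documented stand-in for a
proprietary model-fitting technology — downstream statistics depend only on
its contract (stimulus in, bounded activities out, accuracy-filtered
ensembles), which is the part the tests pin down.
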