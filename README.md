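# virtrial

An R engine for *in silico* clinical trials (ISCT) of CNS stimulants in
attention-deficit/hyperactivity disorder (ADHD). It is aimed at quantitative
systems pharmacology work where you want to simulate a whole trial on a
laptop: generate randomized virtual patient cohorts matched to reference
trial demographics, compute per-patient drug exposure with a 14-compartment
whole-body PBPK model, propagate patient-specific drug stimuli through
ensembles of signed protein-network response models, and run the downstream
comparison statistics between two virtual drugs.

## The model in brief

* **Disease** — four signed protein sets ("motives": neurotransmitter
  imbalance, neuroinflammation, circadian system imbalance, altered neural
  viability); sign +1 means abnormally active in disease.
* **Drug** — a signed target set (+1 activation, −1 inhibition) plus PK
  parameters. The shipped `stimulant_targets.tsv` carries the
  lisdexamfetamine (vLDX, 7 targets) and methylphenidate (vMPH, 3 targets)
  definitions.
* **Exposure** — flow-limited 14-compartment PBPK; oral bioavailability *F*
  applied to the absorption flux, renal elimination, allometric patient
  scaling (volumes ∝ *W*, flows ∝ *W*^0.75). Per-target modulation intensity
  is mean effect-site occupancy *C*/(*C* + EC₅₀) over a dosing interval.
* **Response** — a *mathematical solution* is a positive weight assignment
  on the signed network; activity propagates as
  *x*ₜ₊₁(v) = tanh(Σ sign·w·*x*ₜ(u) + stimulus(v)), bounded in (−1, 1).
  Ensembles are trained against restrictions (known drug stimulus → required
  band on the disease-level response) and filtered at accuracy > 85%.
* **Outcome** — the **tSignal**: mean sign-adjusted predicted activity over
  the disease set (positive = disease reversion), plus the reverted /
  differentially reverted / most-strongly-reverted protein taxonomy,
  hypergeometric enrichment, one-at-a-time stimulus sweeps, random
  target-set extension robustness, and demographic/comorbidity/co-treatment
  statistics with Benjamini–Hochberg correction.

All external inputs (protein network, disease definition, expression data,
demographics, drug pools) have synthetic generators with controlled
statistical structure, so the full pipeline runs and is tested offline. See
`vignettes/virtual-trial-methods.Rmd` for the modelling decisions and their
rationale.

## Worked example

```r
library(virtrial)

# synthetic trial substrate: signed network + embedded disease definition
net     <- generate_network(40, 0.08, seed = 101)
disease <- generate_disease_embedding(net, c(4, 4, 4, 4), seed = 102)

# train a solution ensemble against three efficacy restrictions
training <- lapply(1:3, function(i)
  list(drug = generate_drug_pool(net, 1, c(2, 4), seed = 110 + i)[[1]],
       efficacy = c(0.2, 0.3, 0.4)[i]))
ens <- train_ensemble(net, generate_restrictions(net, disease, training),
                      n_solutions = 6, seed = 103)
ens
#> <solution_ensemble> 6 solutions, accuracy 1.00-1.00 (filter > 0.85)

# a default-spec adult cohort and one patient's realized bioavailability
ref    <- generate_reference_demographics(seed = 31)
cohort <- sample_cohort(ref, default_cohort_spec(), seed = 32,
                        population = "adult")
nrow(cohort)
#> [1] 1300
pk <- read_pk_parameters(system.file("extdata", "pk", "elvanse.yaml",
                                     package = "virtrial"))
round(100 * realized_bioavailability(build_patient_params(cohort[1, ], pk),
                                     pk), 1)
#> [1] 96.4

# compare two in-network virtual drugs through the ensemble
pair <- generate_drug_pool(net, 2, c(3, 5), seed = 120)
acts <- lapply(pair, function(d)
  patient_drug_model(cohort[1, ], d, disease, ensemble = ens, network = net))
sapply(acts, function(a) round(mean(ensemble_tsignals(a, disease)), 3))
#> pool_001 pool_002
#>   -0.074    0.169
differentially_reverted(acts[[1]], acts[[2]], disease)
#>   gene     mean_A     mean_B           p        fdr
#> 1 P003  0.4819099 -0.5696154 0.008658009 0.02164502
#> 2 P027 -0.5750713  0.7771478 0.008658009 0.02164502
```

The mean tSignal says the second drug reverts the disease signature
(positive, 0.169) while the first slightly worsens it; two proteins differ
significantly between the drugs' solution ensembles at FDR < 0.05 (here
neither survives the stricter 100%-separability criterion of
`most_strongly_reverted()`). A one-at-a-time sweep
(`single_target_sweep(ens, net, disease, build_stimulus(drug_stimulus(pair[[1]])))`)
then attributes the drug-level signal to individual targets as a percentage
of the full-stimulus model, whose full-intensity row is 100% by
construction.

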