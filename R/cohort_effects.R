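# Comparative statistics over per-patient / per-solution tSignals:
# efficacy change versus baseline, demographic correlations with categorical
# strength labels, normality-gated two-group tests, covariate isolation by
# quantile stratification, and co-treatment impact against a random drug
# pool. Multiple testing uses Benjamini-Hochberg throughout; test families
# are defined per analysis report.

#' Jarque-Bera normality test
#'
#' Moment-based test: `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with skewness `S`
#' and kurtosis `K`, referred to a chi-squared distribution with 2 degrees of
#' freedom.
#'
#' @param x Numeric vector (n ≥ 8 recommended).
#' @return List with `statistic` and `p.value`.
#' @export
jarque_bera <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(list(statistic = Inf, p.value = 0))  # degenerate
  S <- mean((x - m)^3) / s2^1.5
  K <- mean((x - m)^4) / s2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p.value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Efficacy change from baseline
#'
#' Mean paired change in tSignal under treatment, expressed both absolutely
#' and as a percentage of the change achieved in a reference group (the main
#' no-comorbidity population in the study design).
#'
#' @param treated_tsignals,baseline_tsignals Paired per-patient values.
#' @param reference_group_mean_change Mean change of the reference group;
#'   must be nonzero.
#' @return List with `delta` and `percent_of_reference`.
#' @export
efficacy_change <- function(treated_tsignals, baseline_tsignals,
                            reference_group_mean_change) {
  stopifnot(length(treated_tsignals) == length(baseline_tsignals),
            length(treated_tsignals) >= 1L)
  if (reference_group_mean_change == 0) {
    stop("reference group mean change is 0; percentage undefined",
         call. = FALSE)
  }
  delta <- mean(treated_tsignals - baseline_tsignals)
  list(delta = delta,
       percent_of_reference = 100 * delta / reference_group_mean_change)
}

#' Categorize a correlation coefficient
#'
#' Strength bands on `|rho|`: Strong ≥ 0.8 > Moderate ≥ 0.5 > Low ≥ 0.3 >
#' Negligible; overridden to `NotSignificant` when the FDR is at or above
#' `alpha`.
#'
#' @param rho Pearson coefficient.
#' @param fdr BH-corrected p-value (`NA` to skip the significance override).
#' @param alpha Significance level (default 0.05).
#' @return One of `"Strong"`, `"Moderate"`, `"Low"`, `"Negligible"`,
#'   `"NotSignificant"`.
#' @export
correlation_category <- function(rho, fdr = NA_real_, alpha = 0.05) {
  if (!is.na(fdr) && fdr >= alpha) return("NotSignificant")
  a <- abs(rho)
  if (a >= 0.8) "Strong"
  else if (a >= 0.5) "Moderate"
  else if (a >= 0.3) "Low"
  else "Negligible"
}

#' Correlation of a demographic variable with treatment efficacy
#'
#' Pearson correlation of a per-patient demographic variable with per-patient
#' tSignals, corrected for a test family of size `m_tests` (rank-1
#' Benjamini-Hochberg bound `min(1, p * m_tests)`; exact when the test is the
#' smallest p of its family, conservative otherwise).
#'
#' @param values Per-patient demographic values (≥ 3, finite, non-constant).
#' @param tsignals Per-patient tSignals.
#' @param m_tests Size of the BH family this test belongs to (default 1).
#' @param alpha Significance level for the category override.
#' @return A `correlation_result`: `rho`, `p`, `fdr`, `category`, `n`.
#' @export
demographic_correlation <- function(values, tsignals, m_tests = 1L,
                                    alpha = 0.05) {
  stopifnot(length(values) == length(tsignals), length(values) >= 3L,
            all(is.finite(values)), all(is.finite(tsignals)))
  if (stats::sd(values) == 0 || stats::sd(tsignals) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(values, tsignals, method = "pearson")
  fdr <- min(1, ct$p.value * m_tests)
  structure(list(rho = unname(ct$estimate), p = ct$p.value, fdr = fdr,
                 category = correlation_category(unname(ct$estimate), fdr,
                                                 alpha),
                 n = length(values)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.3f, FDR = %.3g -> %s (n = %d)\n",
              x$rho, x$fdr, x$category, x$n))
  invisible(x)
}

#' Isolate the effect of one covariate from another
#'
#' Correlates each covariate with the tSignal inside quantile strata of the
#' other covariate (so a correlation that survives stratification is not
#' driven by the stratified-out variable), plus the pooled unstratified
#' correlation. FDR is Benjamini-Hochberg over all rows of the report.
#'
#' @param age,bmi Per-patient covariates (any two covariates work; the names
#'   reflect the standard use).
#' @param tsignals Per-patient tSignals.
#' @param strata Number of quantile strata (default 3; 1 reduces to the plain
#'   correlation).
#' @param min_n Minimum patients per stratum (smaller strata are skipped with
#'   a warning).
#' @return Data frame: `covariate`, `isolated_from`, `stratum`, `n`, `rho`,
#'   `p`, `fdr`, `category`.
#' @export
covariate_isolation <- function(age, bmi, tsignals, strata = 3L, min_n = 3L) {
  stopifnot(length(age) == length(bmi), length(bmi) == length(tsignals),
            strata >= 1L)
  vars <- list(age = age, bmi = bmi)
  rows <- list()
  for (a in names(vars)) {
    b <- setdiff(names(vars), a)
    strat_var <- vars[[b]]
    idx_list <- if (strata == 1L) list(pooled = seq_along(strat_var)) else {
      qs <- stats::quantile(strat_var, probs = seq(0, 1, length.out = strata + 1))
      grp <- cut(strat_var, breaks = unique(qs), include.lowest = TRUE,
                 labels = FALSE)
      c(split(seq_along(strat_var), grp),
        list(pooled = seq_along(strat_var)))
    }
    for (snm in names(idx_list)) {
      idx <- idx_list[[snm]]
      if (length(idx) < min_n || stats::sd(vars[[a]][idx]) == 0 ||
          stats::sd(tsignals[idx]) == 0) {
        warning("skipping stratum ", snm, " for ", a, " (too small or constant)")
        next
      }
      ct <- stats::cor.test(vars[[a]][idx], tsignals[idx], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = a, isolated_from = b,
        stratum = if (snm == "pooled") "pooled" else paste0(b, "_q", snm),
        n = length(idx), rho = unname(ct$estimate), p = ct$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$category <- vapply(seq_len(nrow(out)), function(i) {
    correlation_category(out$rho[i], out$fdr[i])
  }, "")
  rownames(out) <- NULL
  out
}

#' Normality-gated two-group comparison
#'
#' Applies the Jarque-Bera test to each group at `alpha_normality`; when both
#' pass, an unpaired two-sided Student's t test compares the groups,
#' otherwise a Wilcoxon rank-sum test (constant groups always take the
#' Wilcoxon path). The significance band follows the study convention
#' (`ns`, `<0.05`, `<0.001`) on the family-corrected FDR.
#'
#' @param groupA_tsignals,groupB_tsignals Values per group (≥ 3 each).
#' @param m_tests BH family size (rank-1 bound, see
#'   [demographic_correlation]).
#' @param alpha_normality Jarque-Bera gate level (default 0.05).
#' @param labels Length-2 group labels for `higher_group`.
#' @return A `group_test_result`: `test_used`, `p`, `fdr`, `higher_group`,
#'   `band`.
#' @export
group_comparison <- function(groupA_tsignals, groupB_tsignals, m_tests = 1L,
                             alpha_normality = 0.05, labels = c("A", "B")) {
  a <- groupA_tsignals; b <- groupB_tsignals
  stopifnot(length(a) >= 3L, length(b) >= 3L, length(labels) == 2L)
  const <- stats::sd(a) == 0 || stats::sd(b) == 0
  normal <- !const &&
    jarque_bera(a)$p.value >= alpha_normality &&
    jarque_bera(b)$p.value >= alpha_normality
  if (normal) {
    test_used <- "t"
    p <- stats::t.test(a, b, var.equal = TRUE)$p.value
  } else {
    test_used <- "wilcoxon"
    p <- if (identical(sort(a), sort(b)) || length(unique(c(a, b))) == 1L) 1
         else suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  fdr <- min(1, p * m_tests)
  band <- if (fdr < 0.001) "<0.001" else if (fdr < 0.05) "<0.05" else "ns"
  structure(list(test_used = test_used, p = p, fdr = fdr,
                 higher_group = labels[if (mean(a) >= mean(b)) 1L else 2L],
                 band = band),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> %s test, FDR = %.3g (%s), higher: %s\n",
              x$test_used, x$fdr, x$band, x$higher_group))
  invisible(x)
}

#' Co-treatment impact versus a random drug pool
#'
#' Tests (i) whether the tSignal under drug + co-treatment differs from the
#' drug alone (normality-gated two-group test) and (ii) whether the observed
#' mean shift is large relative to an empirical null of random pool
#' co-treatments: `pool_p = (r + 1) / (n + 1)` where `r` pool combinations
#' shift the mean tSignal at least as much (add-one smoothing avoids p = 0).
#'
#' @param drug_alone_tsignals tSignals under the primary drug alone.
#' @param combo_tsignals tSignals under drug + co-treatment.
#' @param pool_tsignals List (length ≥ 20) of tSignal vectors, one per random
#'   pool co-treatment combination.
#' @param m_tests BH family size for the direct test.
#' @return A `cotreatment_result`: `direct` ([group_comparison] result),
#'   `observed_delta`, `pool_deltas`, `pool_p`.
#' @export
cotreatment_impact <- function(drug_alone_tsignals, combo_tsignals,
                               pool_tsignals, m_tests = 1L) {
  stopifnot(length(pool_tsignals) >= 20L)
  direct <- group_comparison(drug_alone_tsignals, combo_tsignals,
                             m_tests = m_tests,
                             labels = c("alone", "combo"))
  obs <- abs(mean(combo_tsignals) - mean(drug_alone_tsignals))
  pool_deltas <- vapply(pool_tsignals, function(v) {
    abs(mean(v) - mean(drug_alone_tsignals))
  }, numeric(1))
  pool_p <- (sum(pool_deltas >= obs) + 1) / (length(pool_deltas) + 1)
  structure(list(direct = direct, observed_delta = obs,
                 pool_deltas = unname(pool_deltas), pool_p = pool_p),
            class = "cotreatment_result")
}

#' tSignal vectors for a pool of random co-treatments
#'
#' Convenience wrapper running the propagation pipeline once per pool drug:
#' each pool drug is merged with the primary drug ([combine_treatments]) and
#' the combined full-intensity stimulus propagated through the ensemble.
#'
#' @param primary_drug A [drug_definition].
#' @param pool_drugs List of pool [drug_definition]s.
#' @param ensemble A [solution_ensemble].
#' @param network The [protein_network] the ensemble was trained on.
#' @param disease A [disease_definition].
#' @param profile Optional [comorbidity_profile] applied to every run.
#' @param steps Propagation depth.
#' @return List of numeric tSignal vectors (one per pool drug, one value per
#'   solution).
#' @export
cotreatment_pool_tsignals <- function(primary_drug, pool_drugs, ensemble,
                                      network, disease, profile = NULL,
                                      steps = NULL) {
  if (is.null(steps)) steps <- default_steps(network)
  lapply(pool_drugs, function(pd) {
    combo <- combine_treatments(primary_drug, pd)
    acts <- patient_drug_model(list(id = "pool"), combo, disease,
                               profile = profile, ensemble = ensemble,
                               network = network, steps = steps)
    ensemble_tsignals(acts, disease)
  })
}
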