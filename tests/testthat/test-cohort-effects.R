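test_that("the Jarque-Bera gate routes groups to the right test", {
  set.seed(101)
  lognorm <- exp(stats::rnorm(200))
  expect_lt(jarque_bera(lognorm)$p.value, 0.05)
  normal <- stats::rnorm(200)
  expect_gte(jarque_bera(normal)$p.value, 0.05)
  # both normal -> t; skewed -> wilcoxon; constant -> wilcoxon path
  res_t <- group_comparison(stats::rnorm(50), stats::rnorm(50, 0.5))
  expect_equal(res_t$test_used, "t")
  res_w <- group_comparison(exp(stats::rnorm(200)), exp(stats::rnorm(200)))
  expect_equal(res_w$test_used, "wilcoxon")
  res_c <- group_comparison(rep(1, 5), c(1, 1, 2, 2, 2))
  expect_equal(res_c$test_used, "wilcoxon")
})

test_that("identical groups are maximally non-significant", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  res <- group_comparison(x, x)
  expect_equal(res$p, 1)
  expect_equal(res$band, "ns")
})

test_that("significance bands follow the study convention", {
  skewed <- function(n, shift) exp(stats::rnorm(n)) + shift
  set.seed(5)
  strong <- group_comparison(skewed(200, 0), skewed(200, 3))
  expect_equal(strong$band, "<0.001")
  # family correction can demote a band: same data, larger family
  ga <- stats::rnorm(20); gb <- stats::rnorm(20, 0.8)
  mild <- group_comparison(ga, gb)
  demoted <- group_comparison(ga, gb, m_tests = 1e6)
  expect_equal(demoted$band, "ns")
  expect_lte(mild$fdr, demoted$fdr)
})

test_that("efficacy change scales against the reference group", {
  base <- c(0.0, 0.1, 0.2)
  treated <- c(0.3, 0.5, 0.4)
  delta <- mean(treated - base)  # 0.3
  res <- efficacy_change(treated, base, reference_group_mean_change = delta)
  expect_equal(res$percent_of_reference, 100)
  half <- efficacy_change(treated, base, reference_group_mean_change = 2 * delta)
  expect_equal(half$percent_of_reference, 50)
  expect_equal(half$delta, 0.3, tolerance = 1e-12)
  expect_error(efficacy_change(treated, base, 0), "undefined")
})

test_that("correlation categories partition the strength scale per the band rules", {
  expect_equal(correlation_category(0.85, fdr = 0.01), "Strong")
  expect_equal(correlation_category(0.80, fdr = 0.01), "Strong")   # inclusive
  expect_equal(correlation_category(-0.79, fdr = 0.01), "Moderate")
  expect_equal(correlation_category(0.50, fdr = 0.01), "Moderate")
  expect_equal(correlation_category(0.49, fdr = 0.01), "Low")
  expect_equal(correlation_category(0.30, fdr = 0.01), "Low")
  expect_equal(correlation_category(0.29, fdr = 0.01), "Negligible")
  expect_equal(correlation_category(0.95, fdr = 0.2), "NotSignificant")
})

test_that("demographic correlations recover planted linear effects", {
  set.seed(21)
  age <- stats::runif(100, 18, 65)
  res <- demographic_correlation(-age, -(-age))  # perfectly linear decreasing
  expect_equal(res$rho, -1, tolerance = 1e-12)
  expect_equal(res$category, "Strong")
  expect_error(demographic_correlation(rep(1, 10), stats::rnorm(10)),
               "zero variance")
})

test_that("quantile stratification isolates the driving covariate", {
  set.seed(31)
  n <- 600
  age <- stats::rnorm(n)
  bmi <- stats::rnorm(n)                      # independent of age
  tsig <- 0.9 * age + 0.3 * stats::rnorm(n)   # age-driven only
  iso <- covariate_isolation(age, bmi, tsig, strata = 3)
  age_rows <- iso[iso$covariate == "age" & iso$stratum != "pooled", ]
  bmi_rows <- iso[iso$covariate == "bmi" & iso$stratum != "pooled", ]
  expect_true(all(abs(age_rows$rho) > 0.8))
  expect_true(all(abs(bmi_rows$rho) < 0.2))
  # one stratum reduces to the plain correlation
  flat <- covariate_isolation(age, bmi, tsig, strata = 1)
  expect_equal(flat$rho[flat$covariate == "age"], stats::cor(age, tsig),
               tolerance = 1e-12)
})

test_that("co-treatment impact combines a direct test with an empirical pool null", {
  set.seed(41)
  alone <- stats::rnorm(30, 0.2, 0.02)
  # identical combo: not significant, pool p near 1
  pool_null <- replicate(99, alone + stats::rnorm(30, 0, 1e-6),
                         simplify = FALSE)
  same <- cotreatment_impact(alone, alone, pool_null)
  expect_equal(same$direct$p, 1)
  expect_equal(same$direct$band, "ns")
  # shift larger than every pool shift: add-one smoothed minimum
  combo <- alone + 0.5
  pool_small <- replicate(99, alone + stats::rnorm(30, 0, 0.001),
                          simplify = FALSE)
  big <- cotreatment_impact(alone, combo, pool_small)
  expect_equal(big$pool_p, 1 / 100)
  # observed shift at the pool median lands near p = 0.5
  shifts <- seq(0.01, 0.99, length.out = 99)
  pool_med <- lapply(shifts, function(s) alone + s)
  med <- cotreatment_impact(alone, alone + 0.5, pool_med)
  expect_equal(med$pool_p, (50 + 1) / 100)  # 50 of 99 shifts >= the observed
  expect_error(cotreatment_impact(alone, combo, pool_small[1:5]), ">= 20")
})

test_that("pool tSignals run through the full propagation pipeline", {
  net <- small_network()
  dis <- small_disease()
  ens <- trained_ensemble()
  primary <- network_drug_pair()[[1]]
  pool <- generate_drug_pool(net, 3, c(1, 3), seed = 90)
  ts_list <- cotreatment_pool_tsignals(primary, pool, ens, net, dis)
  expect_length(ts_list, 3L)
  expect_true(all(vapply(ts_list, length, integer(1)) ==
                    length(ens$solutions)))
  expect_true(all(abs(unlist(ts_list)) <= 1))
})

test_that("null demographic correlations reject at the nominal rate", {
  set.seed(51)
  hits <- vapply(1:200, function(i) {
    x <- stats::rnorm(100)
    y <- stats::rnorm(100)
    demographic_correlation(x, y)$fdr < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.005)
  expect_lt(mean(hits), 0.12)
})

test_that("a planted age effect at n = 500 is recovered with its category", {
  rho_true <- 0.65
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    age <- stats::rnorm(500)
    tsig <- rho_true * age + sqrt(1 - rho_true^2) * stats::rnorm(500)
    res <- demographic_correlation(age, tsig)
    res$rho > 0 && res$category %in% c("Moderate", "Strong")
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
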