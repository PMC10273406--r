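# Virtual cohort construction: a power-derived minimum cohort size, quota-
# and tolerance-constrained randomized sampling against a reference
# demographic table, and the matching validation report.

#' Two-sample t-test power (noncentral t)
#'
#' Power of the two-sided two-sample t test at per-group size `n` and
#' standardized effect `d`, via the noncentral t distribution.
#'
#' @param n Per-group sample size (≥ 2).
#' @param d Standardized mean difference.
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
two_sample_power <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- abs(d) * sqrt(n / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
}

#' Minimum cohort size from case/control expression data
#'
#' Estimates the standardized case-vs-control effect of the pooled
#' disease-gene score (per-sample mean over the disease genes) and returns
#' the smallest per-group size at which the two-sample t test attains the
#' target power, found by integer search on the noncentral-t power curve.
#'
#' @param expr An `expression_matrix` (see [generate_expression_matrix]).
#' @param power_target Target power (default 0.95).
#' @param alpha Two-sided significance level (default 0.05).
#' @param n_max Search ceiling.
#' @return Integer per-group size, ≥ 2.
#' @export
minimum_cohort_size <- function(expr, power_target = 0.95, alpha = 0.05,
                                n_max = 1e6L) {
  stopifnot(inherits(expr, "expression_matrix"))
  case <- expr$labels == "case"
  if (sum(case) < 2L || sum(!case) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  score <- colMeans(expr$values[expr$disease_genes, , drop = FALSE])
  m1 <- mean(score[case]); m0 <- mean(score[!case])
  v1 <- stats::var(score[case]); v0 <- stats::var(score[!case])
  sp <- sqrt(((sum(case) - 1) * v1 + (sum(!case) - 1) * v0) /
               (sum(case) + sum(!case) - 2))
  d <- abs(m1 - m0) / sp
  if (!is.finite(d) || d == 0) {
    stop("power target unattainable: estimated effect size is 0", call. = FALSE)
  }
  for (n in 2:n_max) {
    if (two_sample_power(n, d, alpha) >= power_target) return(as.integer(n))
  }
  stop("power target unattainable below n_max = ", n_max, call. = FALSE)
}

#' Construct a cohort sampling specification
#'
#' @param total_size Total patients to generate.
#' @param profile_quotas Named integer vector: minimum patients per
#'   comorbidity profile (excluding `"none"`).
#' @param main_group_minimum Minimum size of the main (no-comorbidity) group.
#' @param tolerance Maximum relative deviation of each cohort summary
#'   statistic from its reference value (default 0.05, i.e. 5%).
#' @param power_minimum Minimum admissible cohort size (requests below it are
#'   rejected); the study default of 71 comes from the expression-data power
#'   analysis, see [minimum_cohort_size].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(total_size, profile_quotas = integer(),
                        main_group_minimum = 0L, tolerance = 0.05,
                        power_minimum = 71L) {
  stopifnot(total_size >= 1L, tolerance > 0, tolerance < 1,
            all(profile_quotas >= 0L))
  if (length(profile_quotas)) {
    bad <- setdiff(names(profile_quotas), setdiff(study_profile_names, "none"))
    if (length(bad)) stop("unknown profile(s) in quotas: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (sum(profile_quotas) + main_group_minimum > total_size) {
    stop("infeasible quotas: minima sum to ",
         sum(profile_quotas) + main_group_minimum, " > total_size ",
         total_size, call. = FALSE)
  }
  structure(list(total_size = as.integer(total_size),
                 profile_quotas = profile_quotas,
                 main_group_minimum = as.integer(main_group_minimum),
                 tolerance = tolerance,
                 power_minimum = as.integer(power_minimum)),
            class = "cohort_spec")
}

#' Default study cohort specification
#'
#' 1,300 patients per population: at least 100 per comorbidity profile
#' (8 profiles) and at least 500 in the main no-comorbidity group, a 5%
#' inclusion tolerance, and a power-derived minimum cohort size of 71.
#'
#' @return A [cohort_spec].
#' @export
default_cohort_spec <- function() {
  quotas <- stats::setNames(rep(100L, 8L), setdiff(study_profile_names, "none"))
  cohort_spec(total_size = 1300L, profile_quotas = quotas,
              main_group_minimum = 500L, tolerance = 0.05, power_minimum = 71L)
}

# inverse-CDF truncated normal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Sample a randomized virtual cohort
#'
#' Draws `spec$total_size` virtual patients whose per-block demographic
#' summaries match the reference table within the spec tolerance (rejection
#' sampling over whole cohorts), with every comorbidity-profile quota and the
#' main-group minimum met exactly as hard constraints. Deterministic per seed.
#'
#' @param reference A `reference_table` ([generate_reference_demographics]).
#' @param spec A [cohort_spec].
#' @param seed Integer seed.
#' @param population `"adult"` (adult block only) or `"pediatric"` (children
#'   and adolescents, split evenly in expectation).
#' @param max_retries Whole-cohort redraws before failing.
#' @return Data frame of class `virtual_cohort` with columns `id`, `cohort`,
#'   `age`, `sex`, `weight`, `height`, `bmi`, `profile`.
#' @export
sample_cohort <- function(reference, spec, seed,
                          population = c("adult", "pediatric"),
                          max_retries = 25L) {
  population <- match.arg(population)
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$total_size < spec$power_minimum) {
    stop("requested cohort size ", spec$total_size,
         " is below the minimum population size per cohort (",
         spec$power_minimum, ")", call. = FALSE)
  }
  blocks <- if (population == "adult") "adult" else c("child", "adolescent")
  ref <- as.data.frame(reference)
  if (!all(blocks %in% ref$block)) {
    stop("reference table lacks block(s): ",
         paste(setdiff(blocks, ref$block), collapse = ", "), call. = FALSE)
  }
  n <- spec$total_size
  local_rng(seed)

  # hard profile assignment: quotas, then the remainder to the main group
  profiles <- c(rep(names(spec$profile_quotas), times = spec$profile_quotas),
                rep("none", n - sum(spec$profile_quotas)))
  if (sum(profiles == "none") < spec$main_group_minimum) {
    stop("infeasible quotas: main group would have ", sum(profiles == "none"),
         " < ", spec$main_group_minimum, " patients", call. = FALSE)
  }
  profiles <- sample(profiles)

  last_report <- NULL
  for (try in seq_len(max_retries)) {
    blk <- if (length(blocks) == 1L) rep(blocks, n) else sample(blocks, n, TRUE)
    cohort <- do.call(rbind, lapply(blocks, function(b) {
      r <- ref[ref$block == b, ]
      k <- sum(blk == b)
      if (k == 0L) return(NULL)
      age <- rtruncnorm(k, r$age_mean, r$age_sd, r$age_min, r$age_max)
      data.frame(
        cohort = b,
        age    = age,
        sex    = ifelse(stats::runif(k) < r$prop_female, "female", "male"),
        weight = rtruncnorm(k, r$weight_mean, r$weight_sd,
                            max(1, r$weight_mean - 3 * r$weight_sd),
                            r$weight_mean + 3 * r$weight_sd),
        height = rtruncnorm(k, r$height_mean, r$height_sd,
                            max(40, r$height_mean - 3 * r$height_sd),
                            r$height_mean + 3 * r$height_sd)
      )
    }))
    cohort <- cohort[sample(nrow(cohort)), ]
    cohort$bmi <- cohort$weight / (cohort$height / 100)^2
    cohort$profile <- profiles
    cohort$id <- sprintf("%s_%04d", population, seq_len(n))
    cohort <- cohort[, c("id", "cohort", "age", "sex", "weight", "height",
                         "bmi", "profile")]
    rownames(cohort) <- NULL
    class(cohort) <- c("virtual_cohort", "data.frame")
    report <- validate_cohort(cohort, reference, spec$tolerance)
    if (attr(report, "overall")) return(cohort)
    last_report <- report
  }
  bad <- last_report[!last_report$pass, ]
  stop("could not match the reference within tolerance after ", max_retries,
       " redraws; offending variable(s): ",
       paste(unique(paste0(bad$block, "/", bad$variable)), collapse = ", "),
       call. = FALSE)
}

#' Validate a cohort against its reference demographics
#'
#' Per block and variable (mean age, weight, height; proportion female),
#' checks that the observed cohort summary lies within `tolerance` relative
#' deviation of the reference value, and that ages respect the block bounds.
#'
#' @param cohort A `virtual_cohort`.
#' @param reference A `reference_table`.
#' @param tolerance Maximum relative deviation (default 0.05).
#' @return Data frame (class `cohort_validation`) with one row per
#'   block × variable: `observed`, `reference`, `rel_dev`, `pass`; attributes
#'   `overall` (logical) and `tolerance`.
#' @export
validate_cohort <- function(cohort, reference, tolerance = 0.05) {
  stopifnot(nrow(cohort) > 0L, tolerance > 0)
  ref <- as.data.frame(reference)
  rows <- list()
  for (b in intersect(unique(cohort$cohort), ref$block)) {
    r <- ref[ref$block == b, ]
    sub <- cohort[cohort$cohort == b, ]
    obs <- c(age = mean(sub$age), weight = mean(sub$weight),
             height = mean(sub$height), prop_female = mean(sub$sex == "female"))
    tgt <- c(age = r$age_mean, weight = r$weight_mean, height = r$height_mean,
             prop_female = r$prop_female)
    rel <- abs(obs - tgt) / abs(tgt)
    in_range <- all(sub$age >= r$age_min - 1e-9 & sub$age <= r$age_max + 1e-9)
    rows[[b]] <- rbind(
      data.frame(block = b, variable = names(obs), observed = unname(obs),
                 reference = unname(tgt), rel_dev = unname(rel),
                 pass = unname(rel) <= tolerance),
      data.frame(block = b, variable = "age_range", observed = NA_real_,
                 reference = NA_real_, rel_dev = NA_real_, pass = in_range)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, overall = all(out$pass), tolerance = tolerance,
            class = c("cohort_validation", "data.frame"))
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("<cohort_validation> overall:",
      if (attr(x, "overall")) "PASS" else "FAIL",
      sprintf("(tolerance %.0f%%)\n", 100 * attr(x, "tolerance")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Read / write a virtual cohort CSV
#'
#' Fixed column order `id, cohort, age, sex, weight, height, bmi, profile`.
#'
#' @param path CSV path.
#' @return `read_cohort`: a `virtual_cohort` data frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "cohort", "age", "sex", "weight", "height", "bmi", "profile")
  if (!identical(names(x), need)) {
    stop("cohort file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  class(x) <- c("virtual_cohort", "data.frame")
  x
}

#' @rdname read_cohort
#' @param cohort A `virtual_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
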