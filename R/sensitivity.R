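# Stimulus sensitivity analysis: one-at-a-time target intensity sweeps on a
# 0/25/50/75/100% grid, robustness of the tSignal to random extension of the
# target set, and the random solution subsample both analyses run on.

#' Random subsample of mathematical solutions
#'
#' Uniform sample without replacement of size `round_half_up(fraction * n)`,
#' with a floor of one solution. With the study's 5% fraction, a pool of
#' 25,000 solutions yields 1,250.
#'
#' @param pool Nonempty list of [mathematical_solution] objects (or a
#'   [solution_ensemble], whose solution list is used).
#' @param fraction Sampling fraction in (0, 1\]; default 0.05.
#' @param seed Integer seed.
#' @return List of solutions.
#' @export
subsample_solutions <- function(pool, fraction = 0.05, seed = 1L) {
  if (inherits(pool, "solution_ensemble")) pool <- pool$solutions
  if (length(pool) == 0L) stop("empty solution pool", call. = FALSE)
  stopifnot(fraction > 0, fraction <= 1)
  size <- max(1L, as.integer(floor(fraction * length(pool) + 0.5)))
  local_rng(seed)
  pool[sort(sample.int(length(pool), size))]
}

# mean tSignal over solutions for one stimulus (weight matrices prebuilt)
mean_tsignal_W <- function(Ws, nodes, stimulus, disease, steps) {
  mean(vapply(Ws, function(W) {
    tsignal(propagate_W(W, nodes, stimulus, steps), disease)$value
  }, numeric(1)))
}

#' One-at-a-time target intensity sweep
#'
#' Scales a single target's stimulus to each level of the grid (0, 25, 50,
#' 75, 100% of the drug's modulation by default), propagates every solution,
#' and reports the mean tSignal as a percentage of the reference (unmodified)
#' model's mean tSignal. The full-intensity row is 100% by construction.
#'
#' @param solutions Nonempty list of [mathematical_solution] objects (or a
#'   [solution_ensemble]).
#' @param network A [protein_network].
#' @param disease A [disease_definition].
#' @param drug_stimulus Named nonempty stimulus set (see [build_stimulus]).
#' @param levels Intensity multipliers (default `c(0, .25, .5, .75, 1)`).
#' @param steps Propagation depth (default [default_steps]).
#' @return A `sweep_result` data frame: `target`, `level`, `percent`;
#'   reference mean tSignal in attribute `"reference"`.
#' @export
single_target_sweep <- function(solutions, network, disease, drug_stimulus,
                                levels = c(0, 0.25, 0.5, 0.75, 1),
                                steps = NULL) {
  if (inherits(solutions, "solution_ensemble")) solutions <- solutions$solutions
  stopifnot(length(solutions) >= 1L, length(drug_stimulus) >= 1L)
  if (is.null(steps)) steps <- default_steps(network)
  Ws <- lapply(solutions, function(s) network_matrix(network, s$weights))
  ref <- mean_tsignal_W(Ws, network$nodes, drug_stimulus, disease, steps)
  if (ref == 0) stop("percentage undefined: reference mean tSignal is 0",
                     call. = FALSE)
  targets <- names(drug_stimulus)
  grid <- expand.grid(target = targets, level = levels,
                      stringsAsFactors = FALSE)
  grid$percent <- vapply(seq_len(nrow(grid)), function(i) {
    stim <- drug_stimulus
    stim[grid$target[i]] <- stim[grid$target[i]] * grid$level[i]
    100 * mean_tsignal_W(Ws, network$nodes, stim, disease, steps) / ref
  }, numeric(1))
  structure(grid, reference = ref,
            class = c("sweep_result", "data.frame"))
}

#' Robustness of the tSignal to random target-set extension
#'
#' For each addition count `j = 1..max_added`, draws `n_sets` random
#' extensions of the drug's stimulus by `j` non-target proteins (uniform over
#' the remaining nodes, random ±1 effects at `added_intensity`), propagates
#' every solution, and records the mean tSignal as a percentage of the
#' unmodified model. The `j = 0` entry is 100% by definition. Extension sets
#' at different `j` are drawn independently.
#'
#' @inheritParams single_target_sweep
#' @param n_sets Extension sets per addition count (default 50).
#' @param max_added Maximum number of added proteins (default 20).
#' @param added_intensity Intensity of each added protein (default 1).
#' @param seed Integer seed.
#' @return A `robustness_curve` data frame: `j`, `set`, `percent` (one row
#'   for `j = 0`, `n_sets` rows per `j ≥ 1`).
#' @export
extended_set_robustness <- function(solutions, network, disease, drug_stimulus,
                                    n_sets = 50L, max_added = 20L,
                                    added_intensity = 1, seed = 1L,
                                    steps = NULL) {
  if (inherits(solutions, "solution_ensemble")) solutions <- solutions$solutions
  stopifnot(length(solutions) >= 1L, length(drug_stimulus) >= 1L,
            n_sets >= 1L, max_added >= 1L,
            added_intensity > 0, added_intensity <= 1)
  if (is.null(steps)) steps <- default_steps(network)
  free <- setdiff(network$nodes, names(drug_stimulus))
  if (max_added > length(free)) {
    stop("max_added exceeds the number of non-target nodes", call. = FALSE)
  }
  Ws <- lapply(solutions, function(s) network_matrix(network, s$weights))
  ref <- mean_tsignal_W(Ws, network$nodes, drug_stimulus, disease, steps)
  if (ref == 0) stop("percentage undefined: reference mean tSignal is 0",
                     call. = FALSE)
  local_rng(seed)
  rows <- list(data.frame(j = 0L, set = 1L, percent = 100))
  for (j in seq_len(max_added)) {
    pct <- vapply(seq_len(n_sets), function(s) {
      added <- sample(free, j)
      stim <- c(drug_stimulus,
                stats::setNames(sample(c(-1, 1), j, replace = TRUE) *
                                  added_intensity, added))
      100 * mean_tsignal_W(Ws, network$nodes, stim, disease, steps) / ref
    }, numeric(1))
    rows[[j + 1L]] <- data.frame(j = j, set = seq_len(n_sets), percent = pct)
  }
  out <- do.call(rbind, rows)
  structure(out, reference = ref,
            class = c("robustness_curve", "data.frame"))
}

#' Mean percent tSignal per addition count
#'
#' @param curve A `robustness_curve`.
#' @return Data frame `j` / `mean_percent`.
#' @export
robustness_means <- function(curve) {
  agg <- tapply(curve$percent, curve$j, mean)
  data.frame(j = as.integer(names(agg)), mean_percent = as.numeric(agg))
}
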