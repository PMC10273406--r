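# Signed-network propagation engine. A "mathematical solution" is one
# assignment of positive weights to the network's signed edges; stimuli are
# signed per-protein intensities in [-1, 1]; propagation is a bounded tanh
# recursion, so every predicted protein activity lies in (-1, 1). Ensembles
# of solutions trained against drug-efficacy restrictions represent the
# biological variability of the response.

# ---- stimuli ---------------------------------------------------------------

#' Signed stimulus contribution of a drug
#'
#' Each target contributes `effect * intensity`. With the default full
#' intensity this is the drug's maximal modulation; per-target intensities
#' from a PK exposure model (see [modulation_from_curve]) attenuate it.
#'
#' @param drug A [drug_definition].
#' @param intensity Scalar in \[0, 1\] or named vector per target gene.
#' @return Data frame `gene`/`value`, one row per target entry (sign-conflict
#'   entries stay separate and cancel when summed).
#' @export
drug_stimulus <- function(drug, intensity = 1) {
  stopifnot(inherits(drug, "drug_definition"))
  tg <- drug$targets
  if (length(intensity) == 1L && is.null(names(intensity))) {
    iv <- rep(intensity, nrow(tg))
  } else {
    iv <- intensity[tg$gene]
    if (any(is.na(iv))) {
      stop("missing intensity for target(s): ",
           paste(tg$gene[is.na(iv)], collapse = ", "), call. = FALSE)
    }
  }
  if (any(iv < 0 | iv > 1)) stop("intensities must be in [0, 1]", call. = FALSE)
  data.frame(gene = tg$gene, value = tg$effect * iv)
}

#' Signed stimulus contribution of a comorbidity profile
#'
#' The profile's molecular definition applied at a fixed baseline intensity,
#' modelling the standing perturbation of the comorbid condition.
#'
#' @param profile A [comorbidity_profile].
#' @param baseline_intensity Intensity in \[0, 1\] (default 0.5).
#' @return Data frame `gene`/`value` (zero rows for the `"none"` profile).
#' @export
profile_stimulus <- function(profile, baseline_intensity = 0.5) {
  stopifnot(inherits(profile, "comorbidity_profile"),
            baseline_intensity >= 0, baseline_intensity <= 1)
  md <- profile$molecular_definition
  if (nrow(md) == 0L) return(data.frame(gene = character(), value = numeric()))
  data.frame(gene = md$gene, value = md$sign * baseline_intensity)
}

#' Assemble a stimulus set
#'
#' Sums any number of signed contributions per protein and clips the totals to
#' \[-1, 1\]. Opposite-sign contributions at the same protein therefore
#' antagonize (equal and opposite ones cancel to a net stimulus of zero).
#'
#' @param ... Data frames with columns `gene` and `value`.
#' @param nodes Optional node universe; keys outside it raise an error.
#' @return Named numeric vector (class `stimulus_set`), values in \[-1, 1\].
#' @export
build_stimulus <- function(..., nodes = NULL) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) NROW(p) > 0L, TRUE)]
  if (length(parts) == 0L) {
    return(structure(stats::setNames(numeric(0), character(0)),
                     class = "stimulus_set"))
  }
  all <- do.call(rbind, lapply(parts, function(p) p[, c("gene", "value")]))
  agg <- tapply(all$value, all$gene, sum)
  v <- pmin(1, pmax(-1, as.numeric(agg)))
  names(v) <- names(agg)
  if (!is.null(nodes) && !all(names(v) %in% nodes)) {
    stop("stimulus keys outside the network: ",
         paste(setdiff(names(v), nodes), collapse = ", "), call. = FALSE)
  }
  structure(v, class = "stimulus_set")
}

# ---- restrictions ----------------------------------------------------------

#' Construct a training restriction
#'
#' A restriction pairs a known drug stimulus with the band in which the
#' sign-adjusted tSignal over the disease protein set must fall for a
#' mathematical solution to be counted as satisfying it.
#'
#' @param stimulus A stimulus set (named numeric in \[-1, 1\]).
#' @param disease A [disease_definition] giving the response protein set.
#' @param band Numeric `(lo, hi)` with `-1 <= lo <= hi <= 1`.
#' @param band_halfwidth Recorded half-width used to build the band.
#' @return An object of class `restriction`.
#' @export
restriction <- function(stimulus, disease, band, band_halfwidth = NA_real_) {
  stopifnot(length(band) == 2L, band[1] <= band[2],
            band[1] >= -1, band[2] <= 1,
            inherits(disease, "disease_definition"))
  structure(list(stimulus = stimulus, disease = disease,
                 band = as.numeric(band), band_halfwidth = band_halfwidth),
            class = "restriction")
}

# ---- solutions and propagation --------------------------------------------

#' Construct a mathematical solution
#'
#' @param weights Positive finite weight per network edge (edge order of the
#'   network it was trained on).
#' @param accuracy Training accuracy in \[0, 1\] (fraction of restrictions
#'   satisfied), recorded at training time.
#' @param seed Seed of the training run that produced it.
#' @return An object of class `mathematical_solution`.
#' @export
mathematical_solution <- function(weights, accuracy = NA_real_, seed = NA_integer_) {
  weights <- as.numeric(weights)
  if (any(!is.finite(weights))) stop("non-finite weights", call. = FALSE)
  structure(list(weights = weights, accuracy = accuracy, seed = seed),
            class = "mathematical_solution")
}

# Dense signed weight matrix W with W[target, source] = sign * weight, so the
# update reads x' = tanh(W x + s).
network_matrix <- function(network, weights = NULL) {
  n <- length(network$nodes)
  e <- network$edges
  if (is.null(weights)) weights <- e$weight
  stopifnot(length(weights) == nrow(e))
  W <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  W[cbind(match(e$target, network$nodes), match(e$source, network$nodes))] <-
    e$sign * weights
  W
}

#' Default propagation depth for a network
#'
#' Network diameter (longest finite directed shortest path) plus 2, so a
#' stimulus can traverse the whole graph with margin.
#'
#' @param network A [protein_network].
#' @return Integer number of propagation steps.
#' @export
default_steps <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = network$nodes)
  d <- igraph::diameter(g, directed = TRUE, unconnected = TRUE)
  as.integer(max(1, d) + 2L)
}

#' Propagate a stimulus through a mathematical solution
#'
#' Iterates `x[t+1](v) = tanh( sum_incoming sign * weight * x[t](u) +
#' stimulus(v) )` from `x[0] = 0` for `steps` iterations. The tanh keeps every
#' activity strictly inside (-1, 1) (exactly 0 where no signal arrives).
#'
#' @param solution A [mathematical_solution] (or `NULL` to use the network's
#'   own edge weights).
#' @param network A [protein_network].
#' @param stimulus Named numeric stimulus set; keys must be network nodes.
#' @param steps Number of iterations (default [default_steps]).
#' @return Named numeric activity vector over all nodes, values in \[-1, 1\].
#' @examples
#' net <- protein_network(data.frame(source = "A", target = "B",
#'                                   sign = 1, weight = 1))
#' propagate(NULL, net, c(A = 1), steps = 2)["B"]  # tanh(tanh(1))
#' @export
propagate <- function(solution, network, stimulus, steps = NULL) {
  stopifnot(inherits(network, "protein_network"))
  if (is.null(steps)) steps <- default_steps(network)
  stopifnot(steps >= 1L)
  W <- network_matrix(network,
                      weights = if (is.null(solution)) NULL else solution$weights)
  propagate_W(W, network$nodes, stimulus, steps)
}

# inner loop shared by propagate() and the trainer (W prebuilt)
propagate_W <- function(W, nodes, stimulus, steps) {
  s <- stats::setNames(numeric(length(nodes)), nodes)
  if (length(stimulus)) {
    if (!all(names(stimulus) %in% nodes)) {
      stop("stimulus keys outside the network: ",
           paste(setdiff(names(stimulus), nodes), collapse = ", "),
           call. = FALSE)
    }
    s[names(stimulus)] <- as.numeric(stimulus)
  }
  x <- numeric(length(nodes))
  for (t in seq_len(steps)) {
    x <- tanh(as.numeric(W %*% x) + s)
    if (any(!is.finite(x))) stop("non-finite activity during propagation",
                                 call. = FALSE)
  }
  stats::setNames(x, nodes)
}

#' Fraction of restrictions a solution satisfies
#'
#' For each restriction, propagates its stimulus and checks whether the
#' sign-adjusted tSignal over the restriction's disease set falls inside the
#' required band.
#'
#' @param solution A [mathematical_solution] (or `NULL` for the network's own
#'   weights).
#' @param network A [protein_network].
#' @param restrictions List of [restriction] objects (≥ 1).
#' @param steps Propagation depth (default [default_steps]).
#' @return Fraction in \[0, 1\].
#' @export
solution_accuracy <- function(solution, network, restrictions, steps = NULL) {
  stopifnot(length(restrictions) >= 1L)
  if (is.null(steps)) steps <- default_steps(network)
  W <- network_matrix(network,
                      weights = if (is.null(solution)) NULL else solution$weights)
  mean(vapply(restrictions, function(r) {
    ts <- tsignal(propagate_W(W, network$nodes, r$stimulus, steps), r$disease)
    ts$value >= r$band[1] && ts$value <= r$band[2]
  }, logical(1)))
}

# Smooth training loss: squared distance of each restriction's tSignal from
# its band (0 inside the band). Accuracy is too coarse to hill-climb on.
restriction_loss <- function(W, nodes, restrictions, steps) {
  sum(vapply(restrictions, function(r) {
    ts <- tsignal(propagate_W(W, nodes, r$stimulus, steps), r$disease)$value
    max(0, r$band[1] - ts, ts - r$band[2])^2
  }, numeric(1)))
}

#' Train an ensemble of mathematical solutions
#'
#' Repeats (random multiplicative re-weighting of the network's edges →
#' hill-climbing local search minimizing the distance of each restriction's
#' tSignal from its required band) until `n_solutions` candidates pass the
#' accuracy filter or the retry budget is exhausted. Every retained solution
#' has `accuracy > accuracy_min`; training is deterministic per seed.
#'
#' @param network A [protein_network].
#' @param restrictions Nonempty list of [restriction] objects.
#' @param n_solutions Target ensemble size (≥ 1).
#' @param accuracy_min Strict retention threshold (default 0.85: a retained
#'   solution must satisfy more than 85% of the restrictions).
#' @param seed Integer seed.
#' @param n_iter Hill-climbing iterations per candidate (default 500).
#' @param retry_budget Candidate attempts before giving up (default
#'   `10 * n_solutions`).
#' @param steps Propagation depth (default [default_steps]).
#' @param init_sd,step_sd Log-normal SD of the initial re-weighting and of the
#'   per-iteration perturbations.
#' @param frac_perturb Fraction of edges perturbed per iteration.
#' @return A [solution_ensemble].
#' @export
train_ensemble <- function(network, restrictions, n_solutions,
                           accuracy_min = 0.85, seed = 1L, n_iter = 500L,
                           retry_budget = 10L * n_solutions, steps = NULL,
                           init_sd = 0.5, step_sd = 0.25, frac_perturb = 0.15) {
  stopifnot(inherits(network, "protein_network"), n_solutions >= 1L,
            length(restrictions) >= 1L)
  if (is.null(steps)) steps <- default_steps(network)
  local_rng(seed)
  nodes <- network$nodes
  base_w <- network$edges$weight
  m <- length(base_w)
  k <- max(1L, round(frac_perturb * m))
  retained <- list()
  for (attempt in seq_len(max(retry_budget, n_solutions))) {
    w <- base_w * exp(stats::rnorm(m, 0, init_sd))
    W <- network_matrix(network, w)
    loss <- restriction_loss(W, nodes, restrictions, steps)
    if (loss > 0) {
      for (it in seq_len(n_iter)) {
        idx <- sample.int(m, k)
        w2 <- w
        w2[idx] <- w2[idx] * exp(stats::rnorm(k, 0, step_sd))
        W2 <- network_matrix(network, w2)
        loss2 <- restriction_loss(W2, nodes, restrictions, steps)
        if (loss2 <= loss) {
          w <- w2; W <- W2; loss <- loss2
        }
        if (loss == 0) break
      }
    }
    sol <- mathematical_solution(w, seed = seed)
    sol$accuracy <- solution_accuracy(sol, network, restrictions, steps)
    if (sol$accuracy > accuracy_min) {
      retained[[length(retained) + 1L]] <- sol
      if (length(retained) == n_solutions) break
    }
  }
  if (length(retained) == 0L) {
    stop("restrictions unsatisfiable at accuracy_min = ", accuracy_min,
         " within the retry budget", call. = FALSE)
  }
  solution_ensemble(retained, accuracy_min = accuracy_min)
}

#' Construct a solution ensemble
#'
#' @param solutions Nonempty list of [mathematical_solution] objects, each
#'   with `accuracy > accuracy_min`.
#' @param patient_id,drug Optional metadata.
#' @param accuracy_min The filter the ensemble was built with.
#' @return An object of class `solution_ensemble`.
#' @export
solution_ensemble <- function(solutions, patient_id = NA_character_,
                              drug = NA_character_, accuracy_min = 0.85) {
  stopifnot(length(solutions) >= 1L)
  acc <- vapply(solutions, `[[`, numeric(1), "accuracy")
  if (any(is.na(acc)) || any(acc <= accuracy_min)) {
    stop("every retained solution must have accuracy > ", accuracy_min,
         call. = FALSE)
  }
  structure(list(patient_id = patient_id, drug = drug, solutions = solutions,
                 accuracy_min = accuracy_min),
            class = "solution_ensemble")
}

#' @export
print.solution_ensemble <- function(x, ...) {
  acc <- vapply(x$solutions, `[[`, numeric(1), "accuracy")
  cat("<solution_ensemble> ", length(x$solutions), " solutions, accuracy ",
      sprintf("%.2f-%.2f", min(acc), max(acc)),
      " (filter > ", x$accuracy_min, ")\n", sep = "")
  invisible(x)
}

#' Predicted protein activities for one patient x drug model
#'
#' Builds the patient-specific stimulus — the drug's PK-attenuated target
#' modulation summed with the comorbidity profile's molecular definition at a
#' fixed baseline intensity, clipped to \[-1, 1\] — and propagates it through
#' every solution of the ensemble.
#'
#' @param patient One-row data frame (or list) with at least an `id` field.
#' @param drug A [drug_definition].
#' @param disease A [disease_definition] (kept with the result for downstream
#'   statistics).
#' @param profile A [comorbidity_profile]; `"none"` leaves the drug modulation
#'   unchanged.
#' @param modulation Target modulation as returned by [modulation_from_curve]
#'   (`NULL` for full-intensity targets).
#' @param ensemble A [solution_ensemble] trained on `network`.
#' @param network The [protein_network] the ensemble was trained on.
#' @param steps Propagation depth (default [default_steps]).
#' @param baseline_intensity Comorbidity baseline intensity (default 0.5).
#' @return Matrix of activities (solutions × proteins), class `activity_set`,
#'   with the stimulus and metadata attached as attributes.
#' @export
patient_drug_model <- function(patient, drug, disease, profile = NULL,
                               modulation = NULL, ensemble, network,
                               steps = NULL, baseline_intensity = 0.5) {
  stopifnot(inherits(ensemble, "solution_ensemble"),
            inherits(drug, "drug_definition"))
  if (is.null(steps)) steps <- default_steps(network)
  if (is.null(modulation)) {
    drug_part <- drug_stimulus(drug)
  } else {
    extra <- setdiff(modulation$gene, drug$targets$gene)
    if (length(extra)) {
      stop("modulation references non-target protein(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    drug_part <- data.frame(gene = modulation$gene, value = modulation$signed)
  }
  prof_part <- if (is.null(profile)) {
    data.frame(gene = character(), value = numeric())
  } else {
    profile_stimulus(profile, baseline_intensity)
  }
  stim <- build_stimulus(drug_part, prof_part, nodes = network$nodes)
  acts <- t(vapply(ensemble$solutions, function(s) {
    propagate(s, network, stim, steps)
  }, numeric(length(network$nodes))))
  colnames(acts) <- network$nodes
  rownames(acts) <- sprintf("sol_%03d", seq_len(nrow(acts)))
  structure(acts, class = c("activity_set", "matrix", "array"),
            stimulus = stim,
            patient_id = if (!is.null(patient$id)) patient$id[1] else NA,
            drug = drug$name,
            profile = if (is.null(profile)) "none" else profile$name)
}
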