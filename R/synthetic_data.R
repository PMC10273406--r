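# Synthetic stand-ins for every external input of the trial pipeline: the
# proprietary protein network, the curated disease definition, case/control
# expression data, reference trial demographics, a random drug pool and the
# drug-efficacy training restrictions. Every generator is a pure function of
# (configuration, seed).

#' Generate a random directed signed protein network
#'
#' Directed Erdős–Rényi topology with Rademacher (±1) edge signs and
#' half-normal `|N(0, 1)|` edge weights. Regenerates (up to `max_retries`
#' times) until the graph is weakly connected, so every node can in principle
#' receive signal.
#'
#' @param n_proteins Number of nodes (≥ 10). Nodes are named `P001`, `P002`, …
#' @param edge_density Probability of each directed edge, in (0, 1).
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @param max_retries Connectivity retries before giving up.
#' @return A [protein_network].
#' @examples
#' net <- generate_network(50, 0.05, seed = 1)
#' net
#' @export
generate_network <- function(n_proteins, edge_density, seed, max_retries = 100L) {
  stopifnot(n_proteins >= 10L, edge_density > 0, edge_density < 1)
  nodes <- sprintf("P%03d", seq_len(n_proteins))
  rng <- local_rng(seed)
  for (try in seq_len(max_retries)) {
    g <- igraph::sample_gnp(n_proteins, edge_density, directed = TRUE)
    if (igraph::is_connected(g, mode = "weak") && igraph::ecount(g) > 0L) {
      el <- igraph::as_edgelist(g, names = FALSE)
      m <- nrow(el)
      edges <- data.frame(
        source = nodes[el[, 1]],
        target = nodes[el[, 2]],
        sign   = sample(c(-1L, 1L), m, replace = TRUE),
        weight = abs(stats::rnorm(m))
      )
      return(protein_network(edges, nodes = nodes))
    }
  }
  stop(sprintf(
    "could not generate a weakly connected network at density %g after %d tries",
    edge_density, max_retries), call. = FALSE)
}

#' Embed a synthetic disease definition in a network
#'
#' Samples disjoint motive member sets (without replacement across motives)
#' from the network's nodes and assigns each member a random disease sign.
#' Motives carry the four canonical names in [adhd_motive_names].
#'
#' @param network A [protein_network].
#' @param motive_sizes Integer vector of length 4: members per motive.
#' @param seed Integer seed.
#' @return A [disease_definition] with 4 motives.
#' @export
generate_disease_embedding <- function(network, motive_sizes, seed) {
  stopifnot(inherits(network, "protein_network"), length(motive_sizes) == 4L,
            all(motive_sizes >= 0))
  total <- sum(motive_sizes)
  if (total > length(network$nodes)) {
    stop(sprintf("motive sizes sum to %d but the network has only %d nodes",
                 total, length(network$nodes)), call. = FALSE)
  }
  if (any(motive_sizes == 0L)) {
    stop("every motive needs at least one member", call. = FALSE)
  }
  rng <- local_rng(seed)
  members <- sample(network$nodes, total)
  motive <- rep(adhd_motive_names, times = motive_sizes)
  disease_definition("synthetic_adhd",
                     data.frame(motive = motive, gene = members,
                                sign = sample(c(-1L, 1L), total, replace = TRUE)),
                     n_motives = 4L)
}

#' Generate a synthetic case/control expression matrix
#'
#' Controls are unit-variance Gaussian noise for every gene; cases are shifted
#' by `effect_size` on the designated disease genes only. This makes the
#' downstream power computation analytically checkable: with `g` disease
#' genes, the per-sample pooled disease-gene score has a standardized
#' case-vs-control effect of `effect_size * sqrt(g)`.
#'
#' @param n_case,n_control Samples per class (≥ 2 each).
#' @param effect_size Per-gene mean shift in the cases (≥ 0), in SD units.
#' @param n_genes Total genes.
#' @param seed Integer seed.
#' @param n_disease_genes Number of shifted genes (default 1, giving a pooled
#'   score effect equal to `effect_size`).
#' @return An `expression_matrix`: list with `values` (genes × samples),
#'   `labels` (`"case"`/`"control"` per sample) and `disease_genes`.
#' @export
generate_expression_matrix <- function(n_case, n_control, effect_size, n_genes,
                                       seed, n_disease_genes = 1L) {
  stopifnot(n_case >= 2L, n_control >= 2L, effect_size >= 0, n_genes >= 1L,
            n_disease_genes >= 1L, n_disease_genes <= n_genes)
  rng <- local_rng(seed)
  n <- n_case + n_control
  vals <- matrix(stats::rnorm(n_genes * n), nrow = n_genes, ncol = n,
                 dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                 sprintf("S%03d", seq_len(n))))
  labels <- c(rep("case", n_case), rep("control", n_control))
  disease_genes <- rownames(vals)[seq_len(n_disease_genes)]
  vals[disease_genes, labels == "case"] <-
    vals[disease_genes, labels == "case"] + effect_size
  structure(list(values = vals, labels = labels, disease_genes = disease_genes),
            class = "expression_matrix")
}

#' Default cohort blocks for reference demographics
#'
#' Age ranges follow the standard trial strata: children 6–12 years,
#' adolescents 13–17, adults 18–65.
#'
#' @return Data frame, one row per block, with age bounds and the
#'   weight/height/sex summaries used as sampling targets.
#' @export
default_cohort_blocks <- function() {
  data.frame(
    block       = c("child", "adolescent", "adult"),
    age_min     = c(6, 13, 18),
    age_max     = c(12, 17, 65),
    age_mean    = c(9.5, 15, 35),
    age_sd      = c(2, 1.4, 11),
    prop_female = c(0.32, 0.32, 0.45),
    weight_mean = c(32, 58, 75),
    weight_sd   = c(8, 11, 14),
    height_mean = c(134, 166, 171),
    height_sd   = c(10, 9, 9.5)
  )
}

#' Generate a reference demographic table
#'
#' Produces the per-block target distributions that cohort sampling matches:
#' age range and Gaussian shape, sex proportion, and weight/height summaries.
#' The `seed` jitters the block means slightly (±2% relative) to emulate
#' drawing references from different source trials; structure and ranges are
#' fixed by `cohort_spec`.
#'
#' @param cohort_spec Data frame as returned by [default_cohort_blocks].
#' @param seed Integer seed.
#' @return A `reference_table` (data frame subclass).
#' @export
generate_reference_demographics <- function(cohort_spec = default_cohort_blocks(),
                                            seed = 1L) {
  spec <- as.data.frame(cohort_spec)
  need <- c("block", "age_min", "age_max", "age_mean", "age_sd", "prop_female",
            "weight_mean", "weight_sd", "height_mean", "height_sd")
  if (!all(need %in% names(spec))) {
    stop("cohort_spec missing columns: ",
         paste(setdiff(need, names(spec)), collapse = ", "), call. = FALSE)
  }
  if (any(spec$age_min >= spec$age_max)) {
    stop("inverted age bounds in cohort_spec", call. = FALSE)
  }
  if (any(spec$prop_female < 0 | spec$prop_female > 1)) {
    stop("sex proportion outside [0, 1]", call. = FALSE)
  }
  rng <- local_rng(seed)
  for (v in c("age_mean", "weight_mean", "height_mean")) {
    spec[[v]] <- spec[[v]] * stats::runif(nrow(spec), 0.98, 1.02)
  }
  spec$age_mean <- pmin(pmax(spec$age_mean, spec$age_min), spec$age_max)
  class(spec) <- c("reference_table", "data.frame")
  spec
}

#' Generate a random drug pool
#'
#' Emulates drawing co-treatment comparators from a large drug database:
#' each pool drug targets a uniformly sized random subset of network nodes
#' with random ±1 effects.
#'
#' @param network A [protein_network].
#' @param n_drugs Pool size (≥ 1).
#' @param target_size_range Integer `(min, max)` target-set size.
#' @param seed Integer seed.
#' @return List of [drug_definition] objects named `pool_001`, …
#' @export
generate_drug_pool <- function(network, n_drugs, target_size_range, seed) {
  stopifnot(inherits(network, "protein_network"), n_drugs >= 1L,
            length(target_size_range) == 2L)
  lo <- target_size_range[1]; hi <- target_size_range[2]
  if (lo < 1L || hi < lo) stop("invalid target_size_range", call. = FALSE)
  if (hi > length(network$nodes)) {
    stop("target_size_range exceeds the node count", call. = FALSE)
  }
  rng <- local_rng(seed)
  pool <- lapply(seq_len(n_drugs), function(i) {
    k <- sample(lo:hi, 1L)
    drug_definition(sprintf("pool_%03d", i),
                    data.frame(gene = sample(network$nodes, k),
                               effect = sample(c(-1L, 1L), k, replace = TRUE)))
  })
  stats::setNames(pool, vapply(pool, `[[`, "", "name"))
}

#' Build training restrictions from drugs with known clinical efficacy
#'
#' Each training drug contributes one restriction: its full-intensity signed
#' target set as the stimulus, and a required band on the sign-adjusted
#' tSignal over the disease protein set, centred at the drug's efficacy
#' (scaled onto the tSignal axis, so efficacy 0 centres the band at 0) with a
#' configurable half-width.
#'
#' @param network A [protein_network]; all training targets must be nodes.
#' @param disease A [disease_definition].
#' @param training_drugs List of `list(drug = <drug_definition>,
#'   efficacy = <real in [0, 1]>)`.
#' @param seed Integer seed (kept for interface uniformity; restriction
#'   construction is deterministic).
#' @param band_halfwidth Half-width of the required response band
#'   (default 0.15).
#' @return List of `restriction` objects (see [restriction]).
#' @export
generate_restrictions <- function(network, disease, training_drugs, seed = 1L,
                                  band_halfwidth = 0.15) {
  stopifnot(inherits(network, "protein_network"),
            inherits(disease, "disease_definition"),
            length(training_drugs) >= 1L)
  lapply(training_drugs, function(td) {
    eff <- td$efficacy
    if (!is.numeric(eff) || eff < 0 || eff > 1) {
      stop("efficacy must be in [0, 1]", call. = FALSE)
    }
    if (!all(td$drug$targets$gene %in% network$nodes)) {
      stop("training drug '", td$drug$name, "' has targets outside the network",
           call. = FALSE)
    }
    stim <- build_stimulus(drug_stimulus(td$drug))
    restriction(stimulus = stim, disease = disease,
                band = c(max(-1, eff - band_halfwidth),
                         min(1, eff + band_halfwidth)),
                band_halfwidth = band_halfwidth)
  })
}

#' Generate synthetic comorbidity profiles
#'
#' Builds the eight study comorbidity profiles plus `"none"`, each with a
#' random signed molecular definition sampled from the network (synthetic
#' stand-ins for curated comorbidity protein sets, which are not public).
#' Combination profiles (`binge_eating_anxiety`, …) take the union of their
#' constituents' definitions.
#'
#' @param network A [protein_network].
#' @param n_proteins_each Proteins per base comorbidity definition.
#' @param seed Integer seed.
#' @param co_treatments Optional named list mapping profile name to
#'   co-treatment drug names.
#' @return Named list of [comorbidity_profile] objects (length 9).
#' @export
generate_comorbidity_profiles <- function(network, n_proteins_each = 5L,
                                          seed = 1L, co_treatments = list()) {
  stopifnot(inherits(network, "protein_network"), n_proteins_each >= 1L)
  rng <- local_rng(seed)
  base <- c("depression", "anxiety", "bipolar_disorder", "tics", "binge_eating")
  defs <- lapply(base, function(b) {
    data.frame(gene = sample(network$nodes, n_proteins_each),
               sign = sample(c(-1L, 1L), n_proteins_each, replace = TRUE))
  })
  names(defs) <- base
  union_def <- function(a, b) {
    m <- rbind(a, b)
    m[!duplicated(m$gene), ]   # first sign wins on overlap
  }
  defs$binge_eating_anxiety    <- union_def(defs$binge_eating, defs$anxiety)
  defs$binge_eating_depression <- union_def(defs$binge_eating, defs$depression)
  defs$depression_anxiety      <- union_def(defs$depression, defs$anxiety)
  profs <- c(list(none = comorbidity_profile("none")),
             lapply(stats::setNames(names(defs), names(defs)), function(nm) {
               comorbidity_profile(nm, defs[[nm]],
                                   co_treatments = unlist(co_treatments[[nm]]))
             }))
  profs[study_profile_names]
}

# Seed the RNG at the top of every stochastic operation so each is a pure
# function of (config, seed). Callers chaining several generators pass each
# its own seed.
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
  invisible(seed)
}
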