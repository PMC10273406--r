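# brute-force propagation oracle: plain loops over the edge list, no shared
# code with the package's matrix implementation
oracle_propagate <- function(net, weights, stimulus, steps) {
  x <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  s <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  s[names(stimulus)] <- stimulus
  e <- net$edges
  for (t in seq_len(steps)) {
    nxt <- s
    for (i in seq_len(nrow(e))) {
      nxt[e$target[i]] <- nxt[e$target[i]] + e$sign[i] * weights[i] * x[e$source[i]]
    }
    x <- tanh(nxt)
  }
  x
}

test_that("propagation matches hand computations on tiny graphs", {
  chain <- protein_network(data.frame(source = "A", target = "B",
                                      sign = 1, weight = 1))
  act <- propagate(NULL, chain, c(A = 1), steps = 2)
  expect_equal(unname(act["B"]), tanh(tanh(1)), tolerance = 1e-12)
  expect_equal(unname(act["A"]), tanh(1), tolerance = 1e-12)
  # empty stimulus: tanh(0) = 0 fixed point
  expect_true(all(propagate(NULL, chain, numeric(0), steps = 3) == 0))
})

test_that("propagation matches a brute-force recursion oracle on a 3-node graph", {
  net <- protein_network(data.frame(
    source = c("A", "B", "A"), target = c("B", "C", "C"),
    sign = c(1L, -1L, 1L), weight = c(0.7, 1.3, 0.4)))
  sol <- mathematical_solution(c(0.9, 1.1, 0.5), accuracy = 1)
  stim <- c(A = 0.8, C = -0.2)
  for (steps in 1:3) {
    expect_equal(propagate(sol, net, stim, steps = steps),
                 oracle_propagate(net, sol$weights, stim, steps),
                 tolerance = 1e-12)
  }
})

test_that("activities are bounded and monotone in stimulus on positive chains", {
  # path graph with all-positive signs
  path <- protein_network(data.frame(
    source = paste0("N", 1:4), target = paste0("N", 2:5),
    sign = 1L, weight = c(0.8, 1.2, 0.6, 1.0)))
  downstream <- vapply(seq(0.1, 1, by = 0.1), function(s) {
    propagate(NULL, path, c(N1 = s), steps = 6)[["N5"]]
  }, numeric(1))
  expect_true(all(diff(downstream) >= 0))
  # bound: |activity| < 1 everywhere under an extreme stimulus
  act <- propagate(NULL, small_network(),
                   stats::setNames(rep(1, 10), small_network()$nodes[1:10]),
                   steps = 12)
  expect_true(all(abs(act) < 1))
})

test_that("solution accuracy is the fraction of satisfied restrictions", {
  net <- small_network()
  dis <- small_disease()
  stim <- build_stimulus(drug_stimulus(network_drug_pair()[[1]]))
  ts <- tsignal(propagate(NULL, net, stim), dis)$value
  mk <- function(lo, hi) restriction(stim, dis, c(lo, hi))
  hit <- function(eps) mk(ts - eps, ts + eps)
  miss <- mk(min(ts + 0.5, 1), 1)
  restr <- list(hit(0.01), hit(0.02), hit(0.03), miss)
  expect_equal(solution_accuracy(NULL, net, restr), 0.75)
  expect_equal(solution_accuracy(NULL, net, list(miss)), 0)
  expect_equal(solution_accuracy(NULL, net, restr[1:3]), 1)
})

test_that("trained ensembles satisfy the strict accuracy filter", {
  ens <- trained_ensemble()
  acc <- vapply(ens$solutions, `[[`, numeric(1), "accuracy")
  expect_length(ens$solutions, 6L)
  expect_true(all(acc > 0.85))
  # the ensemble constructor enforces the same invariant
  bad <- mathematical_solution(small_network()$edges$weight, accuracy = 0.5)
  expect_error(solution_ensemble(list(bad)), "accuracy > 0.85")
})

test_that("training is deterministic per seed", {
  net <- small_network()
  restr <- small_restrictions()
  e1 <- train_ensemble(net, restr, n_solutions = 2, seed = 55, n_iter = 50)
  e2 <- train_ensemble(net, restr, n_solutions = 2, seed = 55, n_iter = 50)
  expect_identical(lapply(e1$solutions, `[[`, "weights"),
                   lapply(e2$solutions, `[[`, "weights"))
})

test_that("a trivially satisfiable restriction retains every candidate", {
  net <- small_network()
  loose <- list(restriction(build_stimulus(drug_stimulus(network_drug_pair()[[1]])),
                            small_disease(), c(-1, 1)))
  ens <- train_ensemble(net, loose, n_solutions = 4, seed = 56, n_iter = 1)
  expect_length(ens$solutions, 4L)
  expect_true(all(vapply(ens$solutions, `[[`, numeric(1), "accuracy") == 1))
})

test_that("unsatisfiable restrictions exhaust the retry budget with an error", {
  net <- small_network()
  # required band far above anything a mean-of-bounded-activities can reach
  impossible <- list(restriction(
    build_stimulus(drug_stimulus(network_drug_pair()[[1]])),
    small_disease(), c(0.999, 1)))
  expect_error(train_ensemble(net, impossible, n_solutions = 2, seed = 57,
                              n_iter = 5, retry_budget = 3),
               "unsatisfiable")
})

test_that("patient models build the documented stimulus and one activity per solution", {
  net <- small_network()
  dis <- small_disease()
  ens <- trained_ensemble()
  drug <- network_drug_pair()[[1]]
  acts <- patient_drug_model(list(id = "p1"), drug, dis, ensemble = ens,
                             network = net)
  expect_equal(nrow(acts), length(ens$solutions))
  expect_equal(ncol(acts), length(net$nodes))
  expect_true(all(abs(acts) < 1))
  # profile "none": stimulus equals the drug modulation exactly
  none <- comorbidity_profile("none")
  acts_none <- patient_drug_model(list(id = "p1"), drug, dis, profile = none,
                                  ensemble = ens, network = net)
  full <- build_stimulus(drug_stimulus(drug))
  expect_equal(attr(acts_none, "stimulus")[names(full)], full,
               ignore_attr = TRUE)
  expect_equal(unclass(acts_none), unclass(acts), ignore_attr = TRUE)
})

test_that("drug and profile contributions cancel at a shared protein", {
  net <- small_network()
  dis <- small_disease()
  ens <- trained_ensemble()
  g <- net$nodes[1]
  drug <- drug_definition("up", data.frame(gene = g, effect = 1))
  prof <- comorbidity_profile("depression",
                              data.frame(gene = g, sign = -1))
  acts <- patient_drug_model(list(id = "p"), drug, dis, profile = prof,
                             ensemble = ens, network = net,
                             baseline_intensity = 1)
  expect_equal(unname(attr(acts, "stimulus")[g]), 0)
  expect_true(all(acts == 0))
})

test_that("modulation entries outside the drug's target set are rejected", {
  net <- small_network()
  drug <- drug_definition("d", data.frame(gene = net$nodes[1], effect = 1))
  mod <- data.frame(gene = net$nodes[2], effect = 1, intensity = 1, signed = 1)
  expect_error(
    patient_drug_model(list(id = "p"), drug, small_disease(),
                       modulation = mod, ensemble = trained_ensemble(),
                       network = net),
    "non-target")
})
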