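# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; the only file fixtures are the shipped
# drug table and PK parameter files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

small_network <- function() {
  fixture("net", function() generate_network(40, 0.08, seed = 101))
}

small_disease <- function() {
  fixture("dis", function() {
    generate_disease_embedding(small_network(), c(4, 4, 4, 4), seed = 102)
  })
}

training_set <- function() {
  fixture("training", function() {
    effs <- c(0.2, 0.3, 0.4)
    lapply(seq_along(effs), function(i) {
      list(drug = generate_drug_pool(small_network(), 1, c(2, 4),
                                     seed = 110 + i)[[1]],
           efficacy = effs[i])
    })
  })
}

small_restrictions <- function() {
  fixture("restrictions", function() {
    generate_restrictions(small_network(), small_disease(), training_set())
  })
}

trained_ensemble <- function() {
  fixture("ensemble", function() {
    train_ensemble(small_network(), small_restrictions(), n_solutions = 6,
                   seed = 103)
  })
}

study_drugs <- function() {
  fixture("drugs", function() {
    parse_drug_table(system.file("extdata", "stimulant_targets.tsv",
                                 package = "virtrial"))
  })
}

pk_fixture <- function(which) {
  read_pk_parameters(system.file("extdata", "pk", paste0(which, ".yaml"),
                                 package = "virtrial"))
}

# a pair of small in-network virtual drugs for MoA comparisons
network_drug_pair <- function() {
  fixture("drug_pair", function() {
    generate_drug_pool(small_network(), 2, c(3, 5), seed = 120)
  })
}

# activity matrices for the drug pair through the shared ensemble
activity_pair <- function() {
  fixture("acts", function() {
    pair <- network_drug_pair()
    lapply(pair, function(d) {
      patient_drug_model(list(id = "fix"), d, small_disease(),
                         ensemble = trained_ensemble(),
                         network = small_network())
    })
  })
}
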