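test_that("the shipped stimulant target table parses to the printed drug definitions", {
  drugs <- study_drugs()
  expect_named(drugs, c("vLDX", "vMPH"))
  expect_equal(nrow(drugs$vLDX$targets), 7L)
  expect_equal(nrow(drugs$vMPH$targets), 3L)
  # amfetamine prodrug: TAAR1 agonism plus monoamine transporter inhibition
  ldx <- drugs$vLDX$targets
  expect_equal(ldx$effect[ldx$gene == "TAAR1"], 1L)
  expect_true(all(ldx$effect[ldx$gene != "TAAR1"] == -1L))
  # methylphenidate: DAT/NET inhibition, 5-HT1A agonism
  mph <- drugs$vMPH$targets
  expect_setequal(mph$gene, c("SLC6A3", "SLC6A2", "HTR1A"))
  expect_equal(stats::setNames(mph$effect, mph$gene)[c("SLC6A3", "SLC6A2", "HTR1A")],
               c(SLC6A3 = -1L, SLC6A2 = -1L, HTR1A = 1L))
})

test_that("drug table parsing rejects malformed input", {
  empty <- tempfile(fileext = ".tsv")
  writeLines("gene\tprotein_name\teffect\tx_ref", empty)
  expect_error(parse_drug_table(empty), "empty")

  bad_sign <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tprotein_name\teffect\tx_ref", "A\tA\t2\tlit"), bad_sign)
  expect_error(parse_drug_table(bad_sign), "effect")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tprotein_name\teffect\tx_ref",
               "A\tA\t1\tlit", "A\tA\t1\tlit"), dup)
  expect_error(parse_drug_table(dup), "duplicate")

  expect_error(drug_definition("d", data.frame(gene = character(),
                                               effect = integer())),
               "no targets")
})

test_that("disease definitions enforce the four-motive structure and valid signs", {
  path <- system.file("extdata", "synthetic_adhd_motives.tsv",
                      package = "virtrial")
  dis <- parse_disease_definition(path)
  expect_s3_class(dis, "disease_definition")
  expect_setequal(unique(dis$motives$motive), adhd_motive_names)
  expect_equal(nrow(disease_members(dis)), 20L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("motive\tgene\tsign", "m1\tA\t0"), bad)
  expect_error(parse_disease_definition(bad, n_motives = NULL), "sign")

  expect_error(
    disease_definition("x", data.frame(motive = "m", gene = "A", sign = 1),
                       n_motives = 4L),
    "expected 4 motives")
})

test_that("definitions round-trip through their file dialects", {
  drugs <- study_drugs()
  p1 <- tempfile(fileext = ".tsv")
  write_drug_table(drugs, p1)
  back <- parse_drug_table(p1)
  for (d in names(drugs)) {
    expect_equal(back[[d]]$targets[order(back[[d]]$targets$gene), ],
                 drugs[[d]]$targets[order(drugs[[d]]$targets$gene), ],
                 ignore_attr = TRUE)
  }

  dis <- small_disease()
  p2 <- tempfile(fileext = ".tsv")
  write_disease_definition(dis, p2)
  expect_equal(parse_disease_definition(p2, name = dis$name)$motives,
               dis$motives)

  net <- small_network()
  p3 <- tempfile(fileext = ".tsv")
  write_network(net, p3)
  back_net <- read_network(p3, nodes = net$nodes)
  expect_equal(back_net$edges, net$edges)
  expect_equal(back_net$nodes, net$nodes)

  profs <- generate_comorbidity_profiles(net, seed = 9)
  p4 <- tempfile(fileext = ".yaml")
  write_comorbidity_profiles(profs, p4)
  back_profs <- read_comorbidity_profiles(p4)
  expect_equal(names(back_profs), names(profs))
  expect_equal(back_profs$depression$molecular_definition,
               profs$depression$molecular_definition, ignore_attr = TRUE)
})

test_that("co-treatment merging unions targets and flags sign conflicts", {
  a <- drug_definition("a", data.frame(gene = "A", effect = 1))
  b <- drug_definition("b", data.frame(gene = "B", effect = -1))
  ab <- combine_treatments(a, b)
  expect_setequal(ab$targets$gene, c("A", "B"))
  expect_false(any(ab$targets$conflict))

  # idempotent same-sign merge
  a2 <- drug_definition("a2", data.frame(gene = "A", effect = 1))
  expect_equal(nrow(combine_treatments(a, a2)$targets), 1L)

  # opposite signs: both retained, conflict-flagged, net stimulus zero
  a3 <- drug_definition("a3", data.frame(gene = "A", effect = -1))
  conflict <- combine_treatments(a, a3)
  expect_equal(nrow(conflict$targets), 2L)
  expect_true(all(conflict$targets$conflict))
  stim <- build_stimulus(drug_stimulus(conflict))
  expect_equal(unname(stim["A"]), 0)
})

test_that("co-treatment merging is commutative and associative up to ordering", {
  pool <- generate_drug_pool(small_network(), 3, c(2, 5), seed = 77)
  canon <- function(d) d$targets[order(d$targets$gene, d$targets$effect), ]
  ab <- combine_treatments(pool[[1]], pool[[2]])
  ba <- combine_treatments(pool[[2]], pool[[1]])
  expect_equal(canon(ab), canon(ba), ignore_attr = TRUE)
  abc1 <- combine_treatments(ab, pool[[3]])
  abc2 <- combine_treatments(pool[[1]], combine_treatments(pool[[2]], pool[[3]]))
  expect_equal(canon(abc1), canon(abc2), ignore_attr = TRUE)
})

test_that("comorbidity profiles validate their names and definitions", {
  expect_error(comorbidity_profile("narcolepsy"), "unknown profile")
  expect_error(comorbidity_profile("depression"), "nonempty molecular")
  none <- comorbidity_profile("none")
  expect_equal(nrow(none$molecular_definition), 0L)
  profs <- generate_comorbidity_profiles(small_network(), seed = 4)
  expect_setequal(names(profs), study_profile_names)
  expect_true(all(vapply(profs[setdiff(study_profile_names, "none")],
                         function(p) nrow(p$molecular_definition) > 0, TRUE)))
})
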