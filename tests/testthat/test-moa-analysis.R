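# exact two-sided rank-sum p by enumeration of all group assignments
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  obs <- sum(rank(pooled)[seq_len(n)])
  idx <- utils::combn(length(pooled), n)
  stats <- apply(idx, 2, function(i) sum(rank(pooled)[i]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

test_that("tSignal follows the sign-adjusted mean convention", {
  d <- disease_definition("toy", data.frame(
    motive = c("m1", "m1"), gene = c("A", "B"), sign = c(1L, -1L)))
  # all-zero activities
  expect_equal(tsignal(c(A = 0, B = 0), d)$value, 0)
  # perfect reversion: activity opposite to the disease sign everywhere
  expect_equal(tsignal(c(A = -1, B = 1), d)$value, 1)
  # partial: (-(1)(-0.5) + -(-1)(0)) / 2 = 0.25
  expect_equal(tsignal(c(A = -0.5, B = 0), d)$value, 0.25)
  # missing member is an error
  expect_error(tsignal(c(A = 0.1), d), "absent")
})

test_that("tSignal is linear, permutation-invariant and bounded", {
  dis <- small_disease()
  genes <- disease_members(dis)$gene
  set.seed(1)
  act <- stats::setNames(stats::runif(length(genes), -1, 1), genes)
  t1 <- tsignal(act, dis)$value
  # linearity in activities
  expect_equal(tsignal(0.3 * act, dis)$value, 0.3 * t1, tolerance = 1e-12)
  act2 <- stats::setNames(stats::runif(length(genes), -1, 1), genes)
  expect_equal(tsignal(act + act2, dis)$value,
               t1 + tsignal(act2, dis)$value, tolerance = 1e-12)
  # permutation invariance in protein order
  perm <- sample(genes)
  expect_equal(tsignal(act[perm], dis)$value, t1, tolerance = 1e-12)
  expect_true(abs(t1) <= 1)
  # per-motive values average to the global value for equal motive sizes
  ts <- tsignal(act, dis)
  expect_equal(mean(ts$per_motive), ts$value, tolerance = 1e-12)
})

test_that("reverted proteins need strict magnitude and opposite direction", {
  d <- disease_definition("toy", data.frame(
    motive = "m1", gene = c("A", "B", "C"), sign = c(1L, 1L, 1L)))
  # 0.5 exactly is not reverted (strict inequality)
  expect_equal(reverted_proteins(c(A = -0.5, B = -0.8, C = 0.8), d),
               "B")
  # same-direction activity is never reverted, whatever its size
  expect_length(reverted_proteins(c(A = 0.9, B = 0.99, C = 0.7), d), 0L)
})

test_that("the rank-sum test matches exact enumeration for small groups", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    a <- round(stats::runif(n, -1, 1), 3)
    b <- round(stats::runif(n, -1, 1), 3)
    if (anyDuplicated(c(a, b))) next
    expect_equal(suppressWarnings(stats::wilcox.test(a, b)$p.value),
                 oracle_ranksum_p(a, b), tolerance = 1e-10)
  }
  # fully separated groups of 3: p = 2 / C(6, 3) = 0.1
  expect_equal(oracle_ranksum_p(c(0.1, 0.2, 0.3), c(0.9, 1.0, 1.1)), 0.1)
})

test_that("differentially reverted proteins are found and FDR-controlled", {
  d <- disease_definition("toy", data.frame(
    motive = "m1", gene = c("A", "B"), sign = c(1L, 1L)))
  # drug 1 reverts A strongly; drug 2 does not; B identical under both
  actsA <- cbind(A = c(-0.9, -0.8, -0.7, -0.85, -0.75),
                 B = rep(-0.6, 5))
  actsB <- cbind(A = c(-0.1, 0.0, 0.1, 0.05, -0.05),
                 B = rep(-0.6, 5))
  res <- differentially_reverted(actsA, actsB, d, alpha = 0.05)
  expect_equal(res$gene, "A")
  tested <- attr(res, "tested")
  # raw two-sided p for complete separation at n = 5: 2 / C(10, 5)
  expect_equal(tested$p[tested$gene == "A"], 2 / choose(10, 5),
               tolerance = 1e-10)
  # all-tied protein reported with FDR 1, not dropped
  expect_true("B" %in% tested$gene)
  expect_equal(tested$fdr[tested$gene == "B"], 1)
  # identical ensembles: nothing retained
  none <- differentially_reverted(actsA, actsA, d)
  expect_equal(nrow(none), 0L)
})

test_that("most strongly reverted proteins match a threshold-enumeration oracle", {
  # independent oracle: try every midpoint threshold, both orientations
  oracle_separable <- function(a, b) {
    v <- sort(unique(c(a, b)))
    thr <- c(v[1] - 1, (utils::head(v, -1) + utils::tail(v, -1)) / 2,
             v[length(v)] + 1)
    any(vapply(thr, function(t) {
      all(a < t) && all(b > t) || all(b < t) && all(a > t)
    }, logical(1)))
  }
  set.seed(11)
  for (rep in 1:20) {
    a <- stats::runif(5, -1, 1)
    b <- stats::runif(5, -1, 1) + stats::runif(1, -0.5, 0.5)
    actsA <- cbind(G = pmin(1, pmax(-1, a)))
    actsB <- cbind(G = pmin(1, pmax(-1, b)))
    expect_equal(length(most_strongly_reverted("G", actsA, actsB)) == 1L,
                 oracle_separable(actsA[, "G"], actsB[, "G"]))
  }
  # explicit disjoint / overlapping cases
  expect_equal(most_strongly_reverted("G", cbind(G = c(0.1, 0.2, 0.3)),
                                      cbind(G = c(0.7, 0.8, 0.9))), "G")
  expect_length(most_strongly_reverted("G", cbind(G = c(0.1, 0.8)),
                                       cbind(G = c(0.5, 0.6))), 0L)
})

test_that("the reverted-set taxonomy nests on a full pipeline run", {
  acts <- activity_pair()
  dis <- small_disease()
  revA <- reverted_proteins(colMeans(acts[[1]]), dis)
  revB <- reverted_proteins(colMeans(acts[[2]]), dis)
  diff_rev <- differentially_reverted(acts[[1]], acts[[2]], dis)
  strongest <- most_strongly_reverted(diff_rev, acts[[1]], acts[[2]])
  expect_true(all(diff_rev$gene %in% union(revA, revB)))
  expect_true(all(strongest %in% diff_rev$gene))
})

test_that("motive counts respect multiplicity across motives", {
  d <- disease_definition("toy", data.frame(
    motive = c("m1", "m1", "m2", "m2"),
    gene = c("A", "B", "B", "C"), sign = c(1L, 1L, 1L, -1L)))
  expect_equal(unname(motive_counts(character(), d)), c(0L, 0L))
  expect_equal(motive_counts("A", d), c(m1 = 1L, m2 = 0L))
  # B sits in both motives and is counted in each
  expect_equal(motive_counts("B", d), c(m1 = 1L, m2 = 1L))
  expect_error(motive_counts("Z", d), "outside")
})

test_that("hypergeometric enrichment matches the closed form", {
  universe <- paste0("U", 1:10)
  term5 <- universe[1:5]
  res <- enrich(universe[1:3], list(t5 = term5), universe, alpha = 1)
  # all 3 of the query inside a 5-protein term: C(5,3)/C(10,3)
  expect_equal(res$p[res$term == "t5"], choose(5, 3) / choose(10, 3),
               tolerance = 1e-12)
  # single term: FDR equals the raw p
  expect_equal(res$fdr, res$p)
  # disjoint query: upper-tail p at overlap 0 is 1 (and never retained)
  res0 <- enrich(universe[6:8], list(t5 = term5), universe, alpha = 1)
  expect_equal(attr(res0, "tested")$p, 1)
  expect_equal(nrow(res0), 0L)
  expect_error(enrich("A", list(t = "A"), character()), "empty universe")
})

test_that("GMT annotation files round-trip through the standard parser", {
  skip_if_not_installed("fgsea")
  p <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG2\tG4"), p)
  gmt <- read_gmt(p)
  expect_equal(gmt, list(setA = c("G1", "G2", "G3"), setB = c("G2", "G4")))
})
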