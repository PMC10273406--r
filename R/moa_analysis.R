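# Outcome statistics over predicted protein activities: the tSignal efficacy
# proxy, the reverted-protein taxonomy (reverted / differentially reverted /
# most strongly reverted), per-motive breakdowns, and hypergeometric
# enrichment of protein sets.

#' tSignal: mean sign-adjusted activity over the disease protein set
#'
#' Each disease protein contributes `-disease_sign * activity`, so a protein
#' driven opposite to its disease activation sign contributes positively and
#' a positive tSignal means disease reversion. The tSignal is the mean of
#' these contributions over the disease set; per-motive values are computed
#' the same way within each motive.
#'
#' @param activity Named numeric activity vector (proteins in \[-1, 1\]).
#' @param disease A [disease_definition]; every member must be present in
#'   `activity`.
#' @return A `tsignal_result`: `value`, `per_motive` (named), `n_proteins`.
#' @examples
#' d <- disease_definition("toy", data.frame(
#'   motive = c("m1", "m1"), gene = c("A", "B"), sign = c(1, -1)))
#' tsignal(c(A = -1, B = 1), d)$value  # perfect reversion
#' @export
tsignal <- function(activity, disease) {
  stopifnot(inherits(disease, "disease_definition"))
  members <- disease_members(disease)
  if (nrow(members) == 0L) stop("empty disease set", call. = FALSE)
  missing <- setdiff(members$gene, names(activity))
  if (length(missing)) {
    stop("disease protein(s) absent from the activity vector: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  adj <- -members$sign * activity[members$gene]
  per_motive <- vapply(unique(disease$motives$motive), function(m) {
    sub <- disease$motives[disease$motives$motive == m, ]
    mean(-sub$sign * activity[sub$gene])
  }, numeric(1))
  structure(list(value = mean(adj), per_motive = per_motive,
                 n_proteins = nrow(members)),
            class = "tsignal_result")
}

#' tSignal of every solution in an activity set
#'
#' @param acts Activity matrix (solutions × proteins), e.g. from
#'   [patient_drug_model].
#' @param disease A [disease_definition].
#' @return Numeric vector, one tSignal per solution.
#' @export
ensemble_tsignals <- function(acts, disease) {
  apply(acts, 1L, function(a) tsignal(a, disease)$value)
}

#' Reverted proteins
#'
#' A disease protein counts as reverted when its predicted activity exceeds
#' the threshold in magnitude (strictly) *and* points opposite to its disease
#' activation sign.
#'
#' @param mean_activity Named numeric vector (typically the ensemble mean).
#' @param disease A [disease_definition].
#' @param threshold Magnitude threshold in (0, 1); default 0.5.
#' @return Character vector of reverted protein names.
#' @export
reverted_proteins <- function(mean_activity, disease, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  members <- disease_members(disease)
  act <- mean_activity[members$gene]
  hit <- !is.na(act) & abs(act) > threshold & sign(act) == -members$sign
  unique(members$gene[hit])
}

#' Differentially reverted proteins between two drugs
#'
#' For every protein reverted by either drug (judged on ensemble mean
#' activities), compares the per-solution activity values of the two drugs
#' with a two-sided Wilcoxon rank-sum test (exact for small tie-free groups,
#' normal approximation with tie correction otherwise) and applies
#' Benjamini-Hochberg correction across the tested proteins. All-tied
#' proteins are kept in the tested family with FDR 1.
#'
#' @param actsA,actsB Activity matrices (solutions × proteins) for the two
#'   drugs, ≥ 2 solutions each.
#' @param disease A [disease_definition].
#' @param alpha FDR retention threshold (default 0.05).
#' @param threshold Reversion magnitude threshold passed to
#'   [reverted_proteins].
#' @return Data frame of retained proteins (`gene`, `mean_A`, `mean_B`, `p`,
#'   `fdr`), ordered by FDR; the full tested table is attached as attribute
#'   `"tested"` and the either-drug reverted set as `"reverted"`.
#' @export
differentially_reverted <- function(actsA, actsB, disease, alpha = 0.05,
                                    threshold = 0.5) {
  stopifnot(nrow(actsA) >= 2L, nrow(actsB) >= 2L)
  revA <- reverted_proteins(colMeans(actsA), disease, threshold)
  revB <- reverted_proteins(colMeans(actsB), disease, threshold)
  candidates <- union(revA, revB)
  empty <- data.frame(gene = character(), mean_A = numeric(),
                      mean_B = numeric(), p = numeric(), fdr = numeric())
  if (length(candidates) == 0L) {
    return(structure(empty, tested = empty, reverted = character()))
  }
  p <- vapply(candidates, function(g) {
    a <- actsA[, g]; b <- actsB[, g]
    if (length(unique(c(a, b))) == 1L) return(1)   # degenerate: all tied
    suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
  }, numeric(1))
  tested <- data.frame(gene = candidates,
                       mean_A = colMeans(actsA)[candidates],
                       mean_B = colMeans(actsB)[candidates],
                       p = unname(p),
                       fdr = stats::p.adjust(unname(p), method = "BH"))
  tested <- tested[order(tested$fdr, tested$p), ]
  rownames(tested) <- NULL
  out <- tested[tested$fdr < alpha, ]
  rownames(out) <- NULL
  structure(out, tested = tested, reverted = candidates)
}

#' Most strongly reverted proteins
#'
#' Keeps a differentially reverted protein when a single threshold on its
#' activity separates the two drugs' solutions with 100% accuracy, i.e. the
#' two per-drug activity ranges are disjoint.
#'
#' @param candidates Character vector of differentially reverted proteins (or
#'   the data frame returned by [differentially_reverted]).
#' @param actsA,actsB Activity matrices (solutions × proteins).
#' @return Character vector, a subset of `candidates`.
#' @export
most_strongly_reverted <- function(candidates, actsA, actsB) {
  if (is.data.frame(candidates)) candidates <- candidates$gene
  keep <- vapply(candidates, function(g) {
    a <- actsA[, g]; b <- actsB[, g]
    max(a) < min(b) || max(b) < min(a)
  }, logical(1))
  candidates[keep]
}

#' Per-motive counts of a reverted protein set
#'
#' Proteins belonging to several motives are counted in each.
#'
#' @param reverted Character vector of reverted proteins (must be disease
#'   members).
#' @param disease A [disease_definition].
#' @return Named integer vector, one count per motive.
#' @export
motive_counts <- function(reverted, disease) {
  stopifnot(inherits(disease, "disease_definition"))
  members <- unique(disease$motives$gene)
  if (!all(reverted %in% members)) {
    stop("reverted protein(s) outside the disease definition: ",
         paste(setdiff(reverted, members), collapse = ", "), call. = FALSE)
  }
  vapply(unique(disease$motives$motive), function(m) {
    sum(disease$motives$gene[disease$motives$motive == m] %in% reverted)
  }, integer(1))
}

#' Hypergeometric enrichment of a protein set
#'
#' Upper-tail hypergeometric test of each annotation term's overlap with the
#' query set, Benjamini-Hochberg corrected across terms.
#'
#' @param protein_set Character query set (must lie in `universe`).
#' @param annotations Named list: term → character vector of member proteins.
#' @param universe Background protein set.
#' @param alpha FDR retention threshold (default 0.05).
#' @return Data frame of retained terms (`term`, `overlap`, `term_size`, `p`,
#'   `fdr`); full tested table as attribute `"tested"`.
#' @export
enrich <- function(protein_set, annotations, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (!all(protein_set %in% universe)) {
    stop("query proteins outside the universe", call. = FALSE)
  }
  stopifnot(length(annotations) >= 1L, !is.null(names(annotations)))
  n <- length(protein_set)
  N <- length(universe)
  rows <- lapply(names(annotations), function(tm) {
    term <- intersect(annotations[[tm]], universe)
    k <- length(intersect(term, protein_set))
    K <- length(term)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = K, p = p)
  })
  tested <- do.call(rbind, rows)
  tested$fdr <- stats::p.adjust(tested$p, method = "BH")
  tested <- tested[order(tested$fdr, tested$p), ]
  rownames(tested) <- NULL
  out <- tested[tested$fdr < alpha, ]
  rownames(out) <- NULL
  structure(out, tested = tested)
}

#' Read a GMT annotation file
#'
#' Standard tab-separated gene-set format (term, description, members…),
#' parsed with `fgsea::gmtPathways`.
#'
#' @param path Path to the `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("read_gmt needs the 'fgsea' package", call. = FALSE)
  }
  fgsea::gmtPathways(path)
}
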