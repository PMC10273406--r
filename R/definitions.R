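# Data model for virtual drugs, disease motives, comorbidity profiles and
# signed protein networks, plus the plain-text file dialects used throughout:
# drugs and motives travel as tab-separated tables with a one-line header,
# networks as 4-column signed edge lists. Everything is diff-able text.

#' Canonical ADHD motive names
#'
#' The four pathophysiological sub-processes ("motives") that make up the
#' disease definition: each is a signed protein set describing how the proteins
#' behave in the disease state.
#'
#' @format Character vector of length 4.
#' @export
adhd_motive_names <- c(
  "neurotransmitter imbalance",
  "neuroinflammation",
  "circadian system imbalance",
  "altered neural viability"
)

#' Names of the study comorbidity profiles
#'
#' The eight virtual patient profiles built from five common ADHD
#' comorbidities (alone or in the studied combinations), plus `"none"` for the
#' main ADHD population without comorbidities.
#'
#' @format Character vector of length 9.
#' @export
study_profile_names <- c(
  "none", "depression", "anxiety", "bipolar_disorder", "tics",
  "binge_eating", "binge_eating_anxiety", "binge_eating_depression",
  "depression_anxiety"
)

parse_sign <- function(x, what = "sign") {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | !(v %in% c(-1, 1))
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s (must be 1 or -1)", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  as.integer(v)
}

#' Construct a virtual drug definition
#'
#' A drug is defined by its signed protein-target set: `effect = +1` denotes
#' activation of the protein's function, `-1` inhibition.
#'
#' @param name Drug name.
#' @param targets Data frame with columns `gene` (uppercase symbol) and
#'   `effect` (`+1`/`-1`); an optional logical `conflict` column marks targets
#'   carried with both signs after a co-treatment merge.
#' @param pk_ref Optional name of the PK parameter record driving the drug's
#'   exposure model.
#' @return An object of class `drug_definition`.
#' @export
drug_definition <- function(name, targets, pk_ref = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  targets <- as.data.frame(targets)
  if (nrow(targets) == 0L) {
    stop("drug '", name, "' has no targets", call. = FALSE)
  }
  if (!all(c("gene", "effect") %in% names(targets))) {
    stop("targets need 'gene' and 'effect' columns", call. = FALSE)
  }
  targets$gene <- as.character(targets$gene)
  if (any(!nzchar(targets$gene))) stop("empty gene symbol", call. = FALSE)
  targets$effect <- parse_sign(targets$effect, "effect")
  if (is.null(targets$conflict)) targets$conflict <- FALSE
  dup <- duplicated(targets[, c("gene", "effect")])
  if (any(dup)) {
    stop("duplicate target(s) in drug '", name, "': ",
         paste(unique(targets$gene[dup]), collapse = ", "), call. = FALSE)
  }
  # the same gene may appear twice only as a flagged sign conflict
  two <- names(which(table(targets$gene) > 1L))
  if (length(two) && !all(targets$conflict[targets$gene %in% two])) {
    stop("gene(s) listed twice without conflict flag in drug '", name, "': ",
         paste(two, collapse = ", "), call. = FALSE)
  }
  rownames(targets) <- NULL
  structure(
    list(name = name, targets = targets[, c("gene", "effect", "conflict")],
         pk_ref = pk_ref),
    class = "drug_definition"
  )
}

#' @export
print.drug_definition <- function(x, ...) {
  cat("<drug_definition> ", x$name, if (!is.na(x$pk_ref)) paste0(" [pk: ", x$pk_ref, "]"),
      "\n", sep = "")
  eff <- ifelse(x$targets$effect > 0, "+1", "-1")
  flg <- ifelse(x$targets$conflict, "*", "")
  cat("  targets:", paste0(x$targets$gene, ":", eff, flg, collapse = " "), "\n")
  invisible(x)
}

#' Construct a disease definition from signed motive membership
#'
#' A disease is a collection of named motives (biological sub-processes), each
#' a set of proteins with a disease activation sign: `+1` means the protein is
#' abnormally active in the disease state, `-1` abnormally inactive.
#'
#' @param name Disease name.
#' @param motives Data frame with columns `motive`, `gene`, `sign`.
#' @param n_motives Required number of motives, `NULL` to accept any. The
#'   default disease model uses exactly 4.
#' @return An object of class `disease_definition`.
#' @export
disease_definition <- function(name, motives, n_motives = NULL) {
  motives <- as.data.frame(motives)
  if (!all(c("motive", "gene", "sign") %in% names(motives))) {
    stop("motives need 'motive', 'gene' and 'sign' columns", call. = FALSE)
  }
  motives$motive <- as.character(motives$motive)
  motives$gene <- as.character(motives$gene)
  motives$sign <- parse_sign(motives$sign, "disease sign")
  if (nrow(motives) == 0L) stop("disease definition has no members", call. = FALSE)
  counts <- table(motives$motive)
  if (any(counts == 0L)) stop("empty motive", call. = FALSE)
  if (!is.null(n_motives) && length(counts) != n_motives) {
    stop(sprintf("expected %d motives, found %d", n_motives, length(counts)),
         call. = FALSE)
  }
  # one sign per protein per motive
  dup <- duplicated(motives[, c("motive", "gene")])
  if (any(dup)) {
    stop("protein listed twice within a motive: ",
         paste(unique(motives$gene[dup]), collapse = ", "), call. = FALSE)
  }
  rownames(motives) <- NULL
  structure(list(name = name, motives = motives[, c("motive", "gene", "sign")]),
            class = "disease_definition")
}

#' @export
print.disease_definition <- function(x, ...) {
  cat("<disease_definition>", x$name, "\n")
  for (m in unique(x$motives$motive)) {
    sub <- x$motives[x$motives$motive == m, ]
    cat("  ", m, ": ", nrow(sub), " proteins\n", sep = "")
  }
  invisible(x)
}

#' Signed members of the disease protein set
#'
#' Returns the union of motive members as unique (gene, sign) pairs. A protein
#' assigned opposite signs in different motives contributes one entry per sign.
#'
#' @param disease A `disease_definition`.
#' @return Data frame with columns `gene`, `sign`.
#' @export
disease_members <- function(disease) {
  stopifnot(inherits(disease, "disease_definition"))
  m <- unique(disease$motives[, c("gene", "sign")])
  rownames(m) <- NULL
  m
}

#' Construct a comorbidity profile
#'
#' A patient profile couples a molecular definition (signed proteins perturbed
#' by the comorbid condition, applied as a baseline stimulus) with the
#' co-treatments typically administered for it.
#'
#' @param name One of [study_profile_names].
#' @param molecular_definition Data frame `gene`/`sign`; may be empty only for
#'   the `"none"` profile.
#' @param co_treatments Character vector of co-treatment drug names.
#' @return An object of class `comorbidity_profile`.
#' @export
comorbidity_profile <- function(name, molecular_definition = NULL,
                                co_treatments = character()) {
  if (!name %in% study_profile_names) {
    stop("unknown profile '", name, "'; expected one of: ",
         paste(study_profile_names, collapse = ", "), call. = FALSE)
  }
  if (is.null(molecular_definition)) {
    molecular_definition <- data.frame(gene = character(), sign = integer())
  }
  molecular_definition <- as.data.frame(molecular_definition)
  if (nrow(molecular_definition) == 0L && name != "none") {
    stop("profile '", name, "' needs a nonempty molecular definition", call. = FALSE)
  }
  if (nrow(molecular_definition) > 0L) {
    molecular_definition$gene <- as.character(molecular_definition$gene)
    molecular_definition$sign <- parse_sign(molecular_definition$sign)
    if (anyDuplicated(molecular_definition$gene)) {
      stop("duplicate protein in profile molecular definition", call. = FALSE)
    }
  }
  structure(list(name = name, molecular_definition = molecular_definition,
                 co_treatments = as.character(co_treatments)),
            class = "comorbidity_profile")
}

#' Construct a directed signed protein network
#'
#' @param edges Data frame with columns `source`, `target`, `sign` (`+1`/`-1`)
#'   and `weight` (positive real).
#' @param nodes Optional node universe; defaults to the union of endpoints.
#' @return An object of class `protein_network`.
#' @export
protein_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (!all(c("source", "target", "sign", "weight") %in% names(edges))) {
    stop("edges need 'source', 'target', 'sign', 'weight' columns", call. = FALSE)
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- parse_sign(edges$sign, "edge sign")
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
    stop("edge weights must be finite and positive", call. = FALSE)
  }
  if (any(edges$source == edges$target)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (anyDuplicated(edges[, c("source", "target")])) {
    stop("duplicate edges", call. = FALSE)
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  nodes <- as.character(nodes)
  if (!all(c(edges$source, edges$target) %in% nodes)) {
    stop("edge endpoints outside the node set", call. = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "protein_network")
}

#' @export
print.protein_network <- function(x, ...) {
  cat("<protein_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " signed edges\n", sep = "")
  invisible(x)
}

# ---- file dialects ---------------------------------------------------------

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Parse a drug target table
#'
#' Reads a tab-separated target table with columns `gene`, `protein_name`,
#' `effect` and one literature-reference column per drug (any column whose
#' name ends in `_ref`). A drug's target set is the rows carrying a reference
#' for that drug; `-` (or empty) reference cells exclude the row from that
#' drug. The shipped ADHD stimulant table uses this layout.
#'
#' @param path Path to the TSV file.
#' @param drugs Named character vector mapping drug name to its reference
#'   column. Default: every `*_ref` column, drug name taken from the prefix.
#' @return Named list of [drug_definition] objects.
#' @examples
#' tab <- system.file("extdata", "stimulant_targets.tsv", package = "virtrial")
#' drugs <- parse_drug_table(tab)
#' vapply(drugs, function(d) nrow(d$targets), integer(1))
#' @export
parse_drug_table <- function(path, drugs = NULL) {
  tab <- read_tsv_strict(path)
  if (nrow(tab) == 0L) stop("empty drug table", call. = FALSE)
  if (!all(c("gene", "effect") %in% names(tab))) {
    stop("drug table needs 'gene' and 'effect' columns", call. = FALSE)
  }
  if (is.null(drugs)) {
    ref_cols <- grep("_ref$", names(tab), value = TRUE)
    if (length(ref_cols) == 0L) stop("no *_ref drug columns found", call. = FALSE)
    drugs <- stats::setNames(ref_cols, sub("_ref$", "", ref_cols))
  }
  out <- lapply(names(drugs), function(dn) {
    col <- drugs[[dn]]
    if (!col %in% names(tab)) stop("missing column '", col, "'", call. = FALSE)
    ref <- trimws(as.character(tab[[col]]))
    keep <- !(ref %in% c("-", "", NA))
    if (!any(keep)) stop("drug '", dn, "' has no referenced targets", call. = FALSE)
    drug_definition(dn, data.frame(gene = tab$gene[keep],
                                   effect = tab$effect[keep]),
                    pk_ref = dn)
  })
  stats::setNames(out, names(drugs))
}

#' Write a drug target table
#'
#' Inverse of [parse_drug_table] for a set of drugs over a shared gene
#' universe: rows are the union of targets, `-` marks non-membership.
#'
#' @param drugs Named list of [drug_definition] objects.
#' @param path Output path.
#' @export
write_drug_table <- function(drugs, path) {
  stopifnot(length(drugs) >= 1L)
  genes <- unique(unlist(lapply(drugs, function(d) d$targets$gene)))
  tab <- data.frame(gene = genes, protein_name = genes, effect = NA_integer_,
                    check.names = FALSE)
  for (dn in names(drugs)) {
    d <- drugs[[dn]]
    ref <- rep("-", length(genes))
    idx <- match(d$targets$gene, genes)
    ref[idx] <- "ref"
    tab[[paste0(dn, "_ref")]] <- ref
    tab$effect[idx] <- d$targets$effect
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a disease definition table
#'
#' Reads a tab-separated motive table with columns `motive`, `gene`, `sign`.
#'
#' @param path Path to the TSV file.
#' @param name Disease name (default: file stem).
#' @param n_motives Required number of motive blocks (default 4, the standard
#'   disease model; `NULL` disables the check).
#' @return A [disease_definition].
#' @export
parse_disease_definition <- function(path, name = NULL, n_motives = 4L) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- read_tsv_strict(path)
  disease_definition(name, tab, n_motives = n_motives)
}

#' Write a disease definition table
#' @param disease A [disease_definition].
#' @param path Output path.
#' @export
write_disease_definition <- function(disease, path) {
  stopifnot(inherits(disease, "disease_definition"))
  utils::write.table(disease$motives, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a signed edge list
#'
#' Networks are stored as 4-column tab-separated edge lists
#' (`source`, `target`, `sign`, `weight`).
#'
#' @param path Path to the edge-list file.
#' @param nodes Optional node universe (isolated nodes are not representable
#'   in an edge list; pass them here).
#' @return `read_network`: a [protein_network]. `write_network`: `path`,
#'   invisibly.
#' @export
read_network <- function(path, nodes = NULL) {
  protein_network(read_tsv_strict(path), nodes = nodes)
}

#' @rdname read_network
#' @param network A [protein_network].
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "protein_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read comorbidity profiles from a YAML file
#'
#' Expects a top-level `profiles:` list of records with `name`,
#' `molecular_definition` (list of `{gene, sign}`) and `co_treatments`.
#'
#' @param path Path to the YAML file.
#' @return Named list of [comorbidity_profile] objects.
#' @export
read_comorbidity_profiles <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$profiles)) stop("no 'profiles' key", call. = FALSE)
  out <- lapply(doc$profiles, function(p) {
    md <- if (length(p$molecular_definition)) {
      do.call(rbind, lapply(p$molecular_definition, function(e) {
        data.frame(gene = e$gene, sign = e$sign)
      }))
    } else NULL
    comorbidity_profile(p$name, md, co_treatments = unlist(p$co_treatments))
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Write comorbidity profiles to YAML
#' @param profiles Named list of [comorbidity_profile] objects.
#' @param path Output path.
#' @export
write_comorbidity_profiles <- function(profiles, path) {
  doc <- list(profiles = lapply(profiles, function(p) {
    list(name = p$name,
         molecular_definition = if (nrow(p$molecular_definition)) {
           lapply(seq_len(nrow(p$molecular_definition)), function(i) {
             list(gene = p$molecular_definition$gene[i],
                  sign = p$molecular_definition$sign[i])
           })
         } else list(),
         co_treatments = as.list(p$co_treatments))
  }))
  names(doc$profiles) <- NULL
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Merge a primary drug with a co-treatment
#'
#' Forms the union of the two target sets. A protein targeted by both drugs
#' with the same sign appears once; a protein targeted with opposite signs is
#' retained twice with a `conflict` flag, and resolves to a net stimulus of
#' zero when signed intensities are summed at stimulus-construction time
#' (see [build_stimulus]). The operation is commutative and associative up to
#' row ordering.
#'
#' @param primary_drug,co_drug [drug_definition] objects over the same protein
#'   namespace.
#' @return A [drug_definition] named `"<primary>+<co>"`.
#' @export
combine_treatments <- function(primary_drug, co_drug) {
  stopifnot(inherits(primary_drug, "drug_definition"),
            inherits(co_drug, "drug_definition"))
  tg <- rbind(primary_drug$targets[, c("gene", "effect")],
              co_drug$targets[, c("gene", "effect")])
  tg <- unique(tg)
  conflict_genes <- names(which(table(tg$gene) > 1L))
  tg$conflict <- tg$gene %in% conflict_genes
  tg <- tg[order(tg$gene, tg$effect), ]
  drug_definition(paste0(primary_drug$name, "+", co_drug$name), tg,
                  pk_ref = primary_drug$pk_ref)
}
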