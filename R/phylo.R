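# Per-gene phylogenetic evidence: patristic distances from trees (or a
# Jukes-Cantor fallback from aligned sequences), per-gene representative
# distances to the bin group and the reference group, and the paired test
# that decides which group the candidate's genes are closer to.

#' Patristic distances from one leaf to all others
#'
#' Sums branch lengths along the tree path from `query_leaf` to every other
#' leaf. Missing branch lengths are treated as 0.
#'
#' @param tree Newick text, a file path, or an `ape::phylo` object.
#' @param query_leaf Leaf label that must be present in the tree.
#' @return Named numeric vector of distances to every other leaf.
#' @export
patristic_distances <- function(tree, query_leaf) {
  phy <- .as_phylo(tree)
  if (!query_leaf %in% phy$tip.label) {
    stop("query leaf '", query_leaf, "' not in tree")
  }
  if (is.null(phy$edge.length)) {
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  phy$edge.length[is.na(phy$edge.length)] <- 0
  d <- ape::cophenetic.phylo(phy)[query_leaf, ]
  d[names(d) != query_leaf]
}

.as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  stopifnot(is.character(tree), length(tree) == 1L)
  phy <- suppressWarnings(
    if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree))
  if (is.null(phy)) stop("malformed newick tree")
  phy
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' `-(3/4) * ln(1 - (4/3) p)` with `p` the mismatch proportion over columns
#' where neither sequence has a gap (`-`, `.`) or `N`. Saturated pairs
#' (`p >= 0.75`) return the sentinel 10.0.
#'
#' @param seq_a,seq_b Equal-length aligned nucleotide strings.
#' @return Non-negative distance (10.0 when saturated).
#' @export
fallback_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) {
    stop("aligned sequences differ in length (", length(a), " vs ", length(b), ")")
  }
  bad <- c("-", ".", "N")
  ok <- !(a %in% bad) & !(b %in% bad)
  if (!any(ok)) stop("no comparable (non-gap) columns")
  p <- mean(a[ok] != b[ok])
  if (p >= 0.75) return(10.0)
  -0.75 * log(1 - 4 * p / 3)
}

#' Per-gene representative distances to the bin and reference groups
#'
#' The representative distance to a group is the minimum over the gene's
#' distances to that group's homologs. An empty group means the gene could
#' not be aligned there: its distance is the sentinel 1 and the aligned
#' flag is FALSE.
#'
#' @param gene_id Identifier for the gene.
#' @param distances_to_bins,distances_to_refs Numeric vectors (possibly
#'   empty) of distances to each group's homologs.
#' @return List with `gene_id`, `d_bins`, `d_refs`, `aligned_bins`,
#'   `aligned_refs`.
#' @export
gene_rep_distance <- function(gene_id, distances_to_bins, distances_to_refs) {
  rep1 <- function(d) {
    if (!length(d)) list(d = 1, aligned = FALSE)
    else list(d = min(d), aligned = TRUE)
  }
  b <- rep1(distances_to_bins); r <- rep1(distances_to_refs)
  if ((b$aligned && b$d > 1) || (r$aligned && r$d > 1)) {
    warning("aligned distance for gene ", gene_id,
            " exceeds the unaligned sentinel 1; group comparison may be biased")
  }
  list(gene_id = gene_id, d_bins = b$d, d_refs = r$d,
       aligned_bins = b$aligned, aligned_refs = r$aligned)
}

#' Paired test of which group a BGC's genes are closer to
#'
#' Tests, over the paired per-gene representative distances, whether the
#' bin-group distances are smaller than the reference-group distances
#' (one-sided by default; `two_sided = TRUE` flips to a two-sided p with
#' the direction taken from the median difference). `"auto"` uses the
#' paired t-test when the differences pass a Shapiro-Wilk normality screen
#' at alpha 0.05, otherwise the Wilcoxon signed-rank test. Zero differences
#' are dropped before the signed-rank test; ties get average ranks.
#'
#' @param profiles List of gene profiles from [gene_rep_distance()].
#' @param method `"wilcoxon"`, `"t"`, or `"auto"`.
#' @param min_genes Minimum number of genes for a p-value; default 5 (the
#'   smallest n at which a one-sided exact signed-rank test can reach 0.05).
#' @param two_sided Report a two-sided p instead of the one-sided default.
#' @return List with `p_value` (NA when untestable), `direction`
#'   (`"bins-closer"`, `"refs-closer"`, or `"none"`), `method_used`,
#'   `n_genes`, and `reason` (non-NA when no p-value was produced).
#' @export
paired_group_test <- function(profiles, method = c("wilcoxon", "t", "auto"),
                              min_genes = 5L, two_sided = FALSE) {
  method <- match.arg(method)
  n <- length(profiles)
  d_bins <- vapply(profiles, `[[`, numeric(1L), "d_bins")
  d_refs <- vapply(profiles, `[[`, numeric(1L), "d_refs")
  if (n < min_genes) {
    return(list(p_value = NA_real_, direction = "none", method_used = NA_character_,
                n_genes = n, reason = sprintf("insufficient genes (%d < %d)", n, min_genes)))
  }
  diffs <- d_bins - d_refs
  if (all(diffs == 0)) {
    return(list(p_value = 1, direction = "none", method_used = method,
                n_genes = n, reason = NA_character_))
  }
  if (method == "auto") {
    nd <- diffs[diffs != 0]
    sw_ok <- length(unique(nd)) > 1L && length(nd) >= 3L &&
      tryCatch(stats::shapiro.test(nd)$p.value > 0.05, error = function(e) FALSE)
    method <- if (sw_ok) "t" else "wilcoxon"
  }
  alt <- if (two_sided) "two.sided" else "less"
  p <- if (method == "t") {
    stats::t.test(d_bins, d_refs, paired = TRUE, alternative = alt)$p.value
  } else {
    suppressWarnings(
      stats::wilcox.test(d_bins, d_refs, paired = TRUE, alternative = alt)$p.value
    )
  }
  direction <- if (stats::median(diffs) < 0) "bins-closer"
               else if (stats::median(diffs) > 0) "refs-closer" else "none"
  if (!two_sided && direction != "bins-closer") {
    # one-sided test was run in the bins-closer direction; a candidate whose
    # genes sit closer to the references can never be significant
    direction <- if (stats::median(diffs) > 0) "refs-closer" else "none"
  }
  list(p_value = p, direction = direction, method_used = method,
       n_genes = n, reason = NA_character_)
}

#' Final verdict for one candidate BGC
#'
#' A candidate is called horizontally transferred when it is a taxonomic
#' outlier, remains isolated from same-taxon reference BGCs, and its genes
#' are significantly closer to the bin group than to the reference group.
#'
#' @param outlier_flagged Logical: flagged by the outlier rule.
#' @param isolation Result of [isolation_test()].
#' @param test Result of [paired_group_test()].
#' @param alpha Significance level; default 0.05.
#' @return List with `verdict` (`"HTBGC"`, `"not-HTBGC"`, `"untestable"`),
#'   `p_value`, `direction`, and `low_confidence` (TRUE when the reference
#'   set was empty).
#' @export
call_htbgc <- function(outlier_flagged, isolation, test, alpha = 0.05) {
  low_conf <- isolation$n_references == 0L
  verdict <- if (!is.na(test$reason) && grepl("insufficient genes", test$reason)) {
    "untestable"
  } else if (isTRUE(outlier_flagged) && isTRUE(isolation$isolated) &&
             identical(test$direction, "bins-closer") &&
             !is.na(test$p_value) && test$p_value < alpha) {
    "HTBGC"
  } else {
    "not-HTBGC"
  }
  list(verdict = verdict, p_value = test$p_value, direction = test$direction,
       low_confidence = low_conf)
}
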