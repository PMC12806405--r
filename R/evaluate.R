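# Benchmark scoring against planted truth (precision/recall/F1, ROC AUC)
# and descriptive transfer-rate / donor-recipient analyses.

#' Confusion counts and precision/recall/F1 against a truth table
#'
#' TP: called HTBGC and in the truth set; FP: called but not in truth;
#' FN: in truth but not called. Precision and recall with a 0 numerator
#' and denominator are defined as 0 (conservative), and F1 is the harmonic
#' mean (0 when TP = 0).
#'
#' @param calls The calls data frame of an `htbgc` result (or the result
#'   itself).
#' @param truth Data frame with a `bgc_id` column (planted transfers), or a
#'   character vector of transferred bgc ids.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
confusion <- function(calls, truth) {
  if (inherits(calls, "htbgc")) calls <- calls$calls
  truth_ids <- if (is.data.frame(truth)) truth$bgc_id else as.character(truth)
  called <- calls$bgc_id[calls$verdict == "HTBGC"]
  tp <- length(intersect(called, truth_ids))
  fp <- length(setdiff(called, truth_ids))
  fn <- length(setdiff(truth_ids, called))
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (tp == 0L) 0 else 2 / (1 / precision + 1 / recall)
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}

#' ROC area under the curve
#'
#' Trapezoidal AUC over the full ROC sweep of a continuous score, with
#' score ties at the midpoint — computed as the equivalent normalized
#' Mann-Whitney statistic (0.5 credit per tied positive-negative pair).
#' The package's per-candidate confidence score is `-log10(p)` of the
#' paired test (0 for untestable candidates).
#'
#' @param scores Numeric confidence scores, larger = more positive.
#' @param labels Logical (or 0/1) truth labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative label")
  }
  r <- rank(scores)  # average ranks handle ties as 0.5 per tied pair
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Candidate confidence scores for ROC analysis
#'
#' `-log10(p_value)` per candidate; untestable candidates (no p) score 0.
#'
#' @param calls Calls data frame or `htbgc` result.
#' @return Named numeric vector keyed by bgc id.
#' @export
htbgc_scores <- function(calls) {
  if (inherits(calls, "htbgc")) calls <- calls$calls
  s <- ifelse(is.na(calls$p_value), 0, -log10(pmax(calls$p_value, 1e-300)))
  stats::setNames(s, calls$bgc_id)
}

.round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Horizontal-transfer rates by group
#'
#' Groups every BGC by recipient phylum, genus, product type, or a
#' coarse type class (RiPP vs non-RiPP), and reports per group the number
#' of HTBGC calls, the total BGC count, and the percentage
#' `100 * ht / total` rounded half-up to 2 decimals. Under genus grouping,
#' genera with zero HTBGCs are merged into `"Others"`.
#'
#' @param calls Calls data frame or `htbgc` result (HTBGC verdicts define
#'   the numerators).
#' @param all_bgcs Named list of all `bgc_record`s in the pool.
#' @param profiles Named list of taxonomy profiles for the BGC genomes.
#' @param group_by `"phylum"`, `"genus"`, `"type"`, or `"type-class"`.
#' @param ripp_types Product-type labels counted as RiPPs for
#'   `"type-class"` grouping.
#' @return Data frame with columns `group`, `ht_count`, `total_count`,
#'   `rate_percent`.
#' @export
transfer_rates <- function(calls, all_bgcs, profiles,
                           group_by = c("phylum", "genus", "type", "type-class"),
                           ripp_types = c("cyclic-lactone-autoinducer",
                                          "RRE-containing", "thiopeptide",
                                          "RiPP-like", "lanthipeptide",
                                          "lassopeptide", "sactipeptide",
                                          "thioamitides", "LAP", "ranthipeptide",
                                          "cyanobactin", "microviridin",
                                          "proteusin", "linaridin", "bottromycin",
                                          "glycocin", "lipolanthine", "epipeptide")) {
  group_by <- match.arg(group_by)
  if (inherits(calls, "htbgc")) calls <- calls$calls
  ht_ids <- calls$bgc_id[calls$verdict == "HTBGC"]
  group_of <- vapply(all_bgcs, function(b) {
    switch(group_by,
      phylum = {
        p <- profiles[[b$genome_id]]
        if (is.null(p)) TAX_UNKNOWN else p[["Phylum"]]
      },
      genus = {
        p <- profiles[[b$genome_id]]
        if (is.null(p)) TAX_UNKNOWN else p[["Genus"]]
      },
      type = b$product_types[1L],
      `type-class` = if (any(b$product_types %in% ripp_types)) "RiPP" else "non-RiPP")
  }, character(1L))
  ids <- vapply(all_bgcs, `[[`, character(1L), "bgc_id")
  tab <- data.frame(group = unname(group_of), bgc_id = unname(ids),
                    ht = unname(ids) %in% ht_ids, stringsAsFactors = FALSE)
  if (group_by == "genus") {
    with_ht <- unique(tab$group[tab$ht])
    tab$group[!(tab$group %in% with_ht)] <- "Others"
  }
  agg <- stats::aggregate(cbind(ht_count = ht, total_count = 1) ~ group,
                          data = tab, FUN = sum)
  agg$rate_percent <- .round_half_up(100 * agg$ht_count / agg$total_count, 2)
  agg[order(-agg$rate_percent, agg$group), , drop = FALSE]
}

#' Percentage as printed in rate tables
#'
#' `100 * count / total`, rounded half-up to 2 decimals.
#' @param count,total Nonnegative counts, `total > 0`.
#' @return The percentage.
#' @export
rate_percent <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  .round_half_up(100 * count / total, 2)
}

#' Contingency test for transfer-rate tables
#'
#' Pearson's chi-squared test without continuity correction, or Fisher's
#' exact test; `"auto"` switches to Fisher when any expected cell count is
#' below 5 (the conventional small-count rule).
#'
#' @param table A 2 x k matrix of nonnegative integer counts.
#' @param method `"auto"` (default), `"chi2"`, or `"fisher"`.
#' @return List with `method_used`, `statistic` (NA for Fisher), `p_value`.
#' @export
contingency_test <- function(table, method = c("auto", "chi2", "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table has a zero margin")
  }
  if (method == "auto") {
    expected <- outer(rowSums(table), colSums(table)) / sum(table)
    method <- if (any(expected < 5)) "fisher" else "chi2"
  }
  if (method == "chi2") {
    res <- stats::chisq.test(table, correct = FALSE)
    list(method_used = "chi2", statistic = unname(res$statistic),
         p_value = res$p.value)
  } else {
    res <- stats::fisher.test(table, workspace = 2e6)
    list(method_used = "fisher", statistic = NA_real_, p_value = res$p.value)
  }
}

#' Donor-recipient transfer matrix at a taxonomic rank
#'
#' Counts HTBGC calls per (donor taxon, recipient taxon) cell at the
#' chosen rank; donors (or recipients) without a classified label at that
#' rank are pooled under `"unclassified"`. The matrix is plot-ready (rows:
#' donors, columns: recipients).
#'
#' @param calls Calls data frame or `htbgc` result.
#' @param rank One of the seven rank names; default `"Phylum"`.
#' @return Square integer matrix over the union of observed taxa.
#' @export
donor_recipient_matrix <- function(calls, rank = "Phylum") {
  if (inherits(calls, "htbgc")) calls <- calls$calls
  rank_index(rank)  # validates
  ht <- calls[calls$verdict == "HTBGC", , drop = FALSE]
  lab <- function(lineage) {
    if (lineage == "unclassified") return("unclassified")
    p <- parse_lineage(lineage)
    if (p[[rank]] == TAX_UNKNOWN) "unclassified" else p[[rank]]
  }
  donors <- vapply(ht$donor, lab, character(1L), USE.NAMES = FALSE)
  recips <- vapply(ht$recipient, lab, character(1L), USE.NAMES = FALSE)
  taxa <- sort(unique(c(donors, recips, if (nrow(ht) == 0L) "unclassified")))
  m <- matrix(0L, length(taxa), length(taxa), dimnames = list(donor = taxa,
                                                              recipient = taxa))
  for (i in seq_along(donors)) {
    m[donors[i], recips[i]] <- m[donors[i], recips[i]] + 1L
  }
  m
}

#' Benchmark detection on synthetic communities with planted transfers
#'
#' For each seed, simulates a community under the supplied generator
#' settings, runs [detect_htbgc()], and scores against the planted truth.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param transfer_count Planted transfers per community; default 10.
#' @param ... Further arguments to [simulate_community()].
#' @param detect_args Named list of overrides for [detect_htbgc()].
#' @return List with `per_seed` (data frame seed/tp/fp/fn/precision/
#'   recall/f1) and `mean_precision`, `mean_recall`, `mean_f1`.
#' @export
evaluate_detection <- function(seeds, transfer_count = 10, ...,
                               detect_args = list()) {
  rows <- lapply(seeds, function(s) {
    comm <- simulate_community(transfer_count = transfer_count, seed = s, ...)
    res <- do.call(detect_htbgc, c(list(
      bgcs = comm$bgcs, profiles = comm$profiles,
      reference_bgcs = comm$reference_bgcs,
      reference_profiles = comm$reference_profiles), detect_args))
    cf <- confusion(res, comm$truth)
    data.frame(seed = s, tp = cf$tp, fp = cf$fp, fn = cf$fn,
               precision = cf$precision, recall = cf$recall, f1 = cf$f1)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       mean_precision = mean(per_seed$precision),
       mean_recall = mean(per_seed$recall),
       mean_f1 = mean(per_seed$f1))
}

#' F1 robustness across community scales
#'
#' Runs the planted-transfer benchmark at several community sizes and
#' compares the per-seed F1 distributions with a Kruskal-Wallis test —
#' the analysis shape used to check that detection quality does not
#' depend on dataset scale.
#'
#' @param n_genomes_levels Community sizes to compare.
#' @param seeds Seeds per level.
#' @param transfer_count Planted transfers; default 4.
#' @param ... Further [simulate_community()] arguments.
#' @return List with `f1_table` (level, seed, f1) and `kruskal_p`.
#' @export
f1_across_scales <- function(n_genomes_levels = c(8, 10, 12), seeds = 1:5,
                             transfer_count = 4, ...) {
  rows <- list()
  for (n in n_genomes_levels) {
    ev <- evaluate_detection(seeds, transfer_count = transfer_count,
                             n_genomes = n, ...)
    rows[[as.character(n)]] <- data.frame(n_genomes = n,
                                          seed = ev$per_seed$seed,
                                          f1 = ev$per_seed$f1)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  p <- if (length(unique(tab$f1)) > 1L) {
    stats::kruskal.test(f1 ~ factor(n_genomes), data = tab)$p.value
  } else NA_real_
  list(f1_table = tab, kruskal_p = p)
}
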