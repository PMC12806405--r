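# End-to-end detection: dereplication -> GCF clustering -> taxonomic
# outlier flagging -> reference isolation -> paired per-gene phylogenetic
# test -> tabular calls.

#' Dereplicate genomes from a pairwise ANI table
#'
#' Genomes joined by ANI at or above `threshold` form redundancy groups
#' (connected components); one representative survives per group — the
#' largest genome by supplied total length, ties (and the no-lengths case)
#' broken by lexicographically smallest id.
#'
#' @param ani Data frame with columns `genome_a`, `genome_b`, `ani`
#'   (percent), e.g. from [read_fastani()].
#' @param genomes Character vector of all genome ids (components are
#'   computed over these; genomes absent from `ani` are their own group).
#' @param threshold ANI percent at/above which two genomes are redundant;
#'   default 99.
#' @param genome_lengths Optional named numeric vector of total genome
#'   lengths.
#' @return Character vector of representative genome ids.
#' @export
dereplicate <- function(ani, genomes, threshold = 99, genome_lengths = NULL) {
  if (nrow(ani) && (any(ani$ani < 0) || any(ani$ani > 100))) {
    stop("ANI values must lie in [0, 100]")
  }
  keep <- ani[ani$ani >= threshold &
                ani$genome_a %in% genomes & ani$genome_b %in% genomes, ,
              drop = FALSE]
  g <- igraph::graph_from_data_frame(keep[, c("genome_a", "genome_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = genomes))
  comp <- igraph::components(g)$membership
  reps <- vapply(split(names(comp), comp), function(m) {
    if (!is.null(genome_lengths)) {
      len <- genome_lengths[m]
      len[is.na(len)] <- 0
      m <- m[len == max(len)]
    }
    min(m)
  }, character(1L))
  sort(unname(reps))
}

#' Read a fastANI output table
#'
#' Five whitespace/tab-separated columns: query path, reference path, ANI,
#' fragment counts. Genome ids are the file base names without extension.
#'
#' @param path Path to fastANI output.
#' @return Data frame with columns `genome_a`, `genome_b`, `ani`.
#' @export
read_fastani <- function(path) {
  tab <- utils::read.table(path, sep = "", header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("fastANI table needs >= 3 columns")
  strip <- function(x) sub("\\.(fa|fna|fasta)(\\.gz)?$", "", basename(as.character(x)))
  data.frame(genome_a = strip(tab[[1L]]), genome_b = strip(tab[[2L]]),
             ani = as.numeric(tab[[3L]]), stringsAsFactors = FALSE)
}

#' Infer the donor taxonomy of a transferred BGC
#'
#' The donor is summarised as the lowest common lineage of the GCF's
#' non-outlier member genomes; when even Domain is not shared the donor is
#' `"unclassified"`.
#'
#' @param donor_genomes Character vector of non-outlier member genome ids.
#' @param profiles Named list of taxonomy profiles.
#' @return A taxonomy profile, or the string `"unclassified"`.
#' @export
infer_donor <- function(donor_genomes, profiles) {
  if (!length(donor_genomes)) return("unclassified")
  lin <- common_lineage(profiles[donor_genomes])
  if (lin[["Domain"]] == TAX_UNKNOWN) "unclassified" else lin
}

# Per-gene representative distances of a candidate against the bin-group
# and reference-group BGCs, via the alignment-free route: two genes are
# comparable when their BGCs share at least one domain label and the gene
# slot exists at equal length (sequences are pre-aligned / equal length by
# construction); otherwise the gene is unaligned for that group.
.gene_profiles_from_seqs <- function(candidate, bin_bgcs, ref_bgcs) {
  comparable <- function(other) {
    length(intersect(bgc_domains(candidate), bgc_domains(other))) > 0L
  }
  bin_ok <- Filter(comparable, bin_bgcs)
  ref_ok <- Filter(comparable, ref_bgcs)
  lapply(seq_len(nrow(candidate$genes)), function(k) {
    q <- candidate$genes$seq[k]
    slot_dists <- function(group) {
      d <- vapply(group, function(b) {
        if (nrow(b$genes) < k) return(NA_real_)
        s <- b$genes$seq[k]
        if (!nzchar(s) || !nzchar(q) || nchar(s) != nchar(q)) return(NA_real_)
        fallback_distance(q, s)
      }, numeric(1L))
      d[!is.na(d)]
    }
    gene_rep_distance(candidate$genes$gene_id[k],
                      slot_dists(bin_ok), slot_dists(ref_ok))
  })
}

# Tree route: per-gene newick trees with leaves "genome_id|gene_id".
.gene_profiles_from_trees <- function(candidate, trees, bin_genomes, ref_genomes) {
  lapply(seq_len(nrow(candidate$genes)), function(k) {
    gid <- candidate$genes$gene_id[k]
    tr <- trees[[gid]]
    if (is.null(tr)) return(gene_rep_distance(gid, numeric(0), numeric(0)))
    leaf <- paste0(candidate$genome_id, "|", gid)
    d <- tryCatch(patristic_distances(tr, leaf), error = function(e) NULL)
    if (is.null(d)) return(gene_rep_distance(gid, numeric(0), numeric(0)))
    leaf_genome <- sub("\\|.*$", "", names(d))
    gene_rep_distance(gid, unname(d[leaf_genome %in% bin_genomes]),
                      unname(d[leaf_genome %in% ref_genomes]))
  })
}

#' Detect horizontally transferred BGCs
#'
#' Runs the full decision engine over one sample's BGCs: (optional)
#' ANI dereplication, GCF clustering at `cutoff`, per-family taxonomic
#' outlier flagging, isolation against same-species/genus reference BGCs,
#' and the paired per-gene phylogenetic-distance test, producing one call
#' per candidate. Deterministic given its inputs.
#'
#' @param bgcs Named list of `bgc_record`s (the sample's BGCs).
#' @param profiles Named list of taxonomy profiles covering the BGC genomes.
#' @param reference_bgcs Named list of reference-genome `bgc_record`s.
#' @param reference_profiles Named list of reference taxonomy profiles.
#' @param gene_trees Optional named list of per-gene trees (newick text or
#'   `phylo`), keyed by candidate gene id, leaves `genome_id|gene_id`; when
#'   absent, distances fall back to Jukes-Cantor on stored gene sequences.
#' @param edges Optional precomputed similarity edges (see
#'   [read_bigscape_network()]).
#' @param ani Optional ANI table for dereplication (see [read_fastani()]).
#' @param ani_threshold Dereplication threshold, percent; default 99.
#' @param genome_lengths Optional named lengths for dereplication
#'   representative choice.
#' @param cutoff GCF distance cutoff; default 0.3.
#' @param alpha Significance level for the paired test; default 0.05.
#' @param rule Outlier rule, `"mean"` (default), `"z"`, or `"both"`.
#' @param test_method `"wilcoxon"` (default), `"t"`, or `"auto"`.
#' @param min_genes Minimum genes for a testable candidate; default 5.
#' @param min_mags Minimum genomes required to attempt detection (samples
#'   below it yield zero candidates with a note); default 0 here — the
#'   command-line tool applies the conventional per-sample floor of 20.
#' @param pair_mean,sd_type Passed to [find_outliers()].
#' @param two_sided Use a two-sided paired test; default FALSE.
#' @return An object of class `htbgc`; see [print.htbgc()],
#'   [summary.htbgc()], [as.data.frame.htbgc()], [write_report()].
#' @export
detect_htbgc <- function(bgcs, profiles,
                         reference_bgcs = list(), reference_profiles = list(),
                         gene_trees = NULL, edges = NULL,
                         ani = NULL, ani_threshold = 99, genome_lengths = NULL,
                         cutoff = 0.3, alpha = 0.05,
                         rule = c("mean", "z", "both"),
                         test_method = c("wilcoxon", "t", "auto"),
                         min_genes = 5L, min_mags = 0L,
                         pair_mean = "unordered", sd_type = "sample",
                         two_sided = FALSE) {
  rule <- match.arg(rule)
  test_method <- match.arg(test_method)
  stopifnot(length(bgcs) >= 1L)
  log_counts <- list(input_bgcs = length(bgcs),
                     input_genomes = length(unique(
                       vapply(bgcs, `[[`, character(1L), "genome_id"))))

  if (!is.null(ani)) {
    reps <- dereplicate(ani, unique(vapply(bgcs, `[[`, character(1L), "genome_id")),
                        threshold = ani_threshold, genome_lengths = genome_lengths)
    bgcs <- Filter(function(b) b$genome_id %in% reps, bgcs)
    log_counts$genomes_after_dereplication <- length(reps)
    if (!length(bgcs)) stop("no BGCs left after dereplication")
  }
  genome_of <- vapply(bgcs, `[[`, character(1L), "genome_id")
  if (length(unique(genome_of)) < min_mags) {
    res <- structure(list(calls = .empty_calls(), partition = NULL,
                          outlier_reports = list(), profiles = profiles,
                          note = sprintf("sample has %d genomes (< min_mags = %d); skipped",
                                         length(unique(genome_of)), min_mags),
                          params = list(cutoff = cutoff, alpha = alpha, rule = rule),
                          log = log_counts),
                     class = "htbgc")
    return(res)
  }

  partition <- cluster_gcfs(bgcs, cutoff = cutoff, edges = edges)
  log_counts$gcfs <- length(partition$families)

  outlier_reports <- list()
  calls <- list()
  for (fam in names(partition$families)) {
    members <- partition$families[[fam]]
    member_genomes <- unique(unname(genome_of[members]))
    rep_ <- find_outliers(member_genomes, profiles, rule = rule,
                          sd_type = sd_type, pair_mean = pair_mean)
    outlier_reports[[fam]] <- rep_
    if (!length(rep_$outliers)) next
    donor_genomes <- setdiff(member_genomes, rep_$outliers)
    for (og in rep_$outliers) {
      for (cand_id in members[genome_of[members] == og]) {
        calls[[cand_id]] <- tryCatch(
          .evaluate_candidate(bgcs[[cand_id]], fam, rep_, partition, bgcs,
                              genome_of, donor_genomes, profiles,
                              reference_bgcs, reference_profiles, gene_trees,
                              cutoff, alpha, test_method, min_genes, two_sided),
          error = function(e) {
            .call_row(bgcs[[cand_id]], fam, rep_, verdict = "untestable",
                      p_value = NA_real_, direction = "none",
                      donor = "unclassified", profiles = profiles,
                      low_confidence = TRUE, n_similar = NA_integer_,
                      nearest = NA_real_, reason = conditionMessage(e))
          })
      }
    }
  }
  calls_df <- if (length(calls)) {
    do.call(rbind, c(unname(calls), list(make.row.names = FALSE)))
  } else .empty_calls()
  calls_df <- calls_df[order(calls_df$bgc_id), , drop = FALSE]
  rownames(calls_df) <- NULL
  log_counts$candidates <- nrow(calls_df)
  log_counts$htbgc_calls <- sum(calls_df$verdict == "HTBGC")

  structure(list(calls = calls_df, partition = partition,
                 outlier_reports = outlier_reports, profiles = profiles,
                 note = NA_character_,
                 params = list(cutoff = cutoff, alpha = alpha, rule = rule,
                               test_method = test_method, min_genes = min_genes,
                               pair_mean = pair_mean, sd_type = sd_type,
                               two_sided = two_sided),
                 log = log_counts),
            class = "htbgc")
}

.evaluate_candidate <- function(candidate, fam, rep_, partition, bgcs,
                                genome_of, donor_genomes, profiles,
                                reference_bgcs, reference_profiles, gene_trees,
                                cutoff, alpha, test_method, min_genes, two_sided) {
  prof <- profiles[[candidate$genome_id]]
  refset <- select_reference_set(prof, reference_bgcs, reference_profiles)
  iso <- isolation_test(candidate, refset, cutoff = cutoff)

  members <- partition$families[[fam]]
  bin_ids <- members[members != candidate$bgc_id &
                       genome_of[members] != candidate$genome_id]
  bin_bgcs <- bgcs[bin_ids]

  gene_profiles <- if (!is.null(gene_trees)) {
    .gene_profiles_from_trees(candidate, gene_trees,
                              bin_genomes = unique(unname(genome_of[bin_ids])),
                              ref_genomes = unique(vapply(refset, `[[`,
                                                          character(1L), "genome_id")))
  } else {
    .gene_profiles_from_seqs(candidate, bin_bgcs, refset)
  }
  test <- paired_group_test(gene_profiles, method = test_method,
                            min_genes = min_genes, two_sided = two_sided)
  verdict <- call_htbgc(TRUE, iso, test, alpha = alpha)

  # isolation gate: a candidate clustering with its own taxon's reference
  # BGCs is vertically explained regardless of the test
  donor <- infer_donor(donor_genomes, profiles)
  genus <- prof[["Genus"]]
  n_similar <- sum(vapply(bgcs[setdiff(members, candidate$bgc_id)], function(b) {
    p <- profiles[[b$genome_id]]
    !is.null(p) && genus != TAX_UNKNOWN && p[["Genus"]] == genus
  }, logical(1L)))

  .call_row(candidate, fam, rep_, verdict = verdict$verdict,
            p_value = verdict$p_value, direction = verdict$direction,
            donor = donor, profiles = profiles,
            low_confidence = verdict$low_confidence, n_similar = n_similar,
            nearest = iso$nearest_distance,
            reason = if (!is.na(test$reason)) test$reason
                     else if (!iso$isolated) "not isolated from same-taxon references"
                     else NA_character_)
}

.call_row <- function(candidate, fam, rep_, verdict, p_value, direction,
                      donor, profiles, low_confidence, n_similar, nearest,
                      reason) {
  data.frame(
    bgc_id = candidate$bgc_id,
    genome_id = candidate$genome_id,
    gcf_id = fam,
    verdict = verdict,
    outlier_mean_distance = unname(rep_$per_genome_mean[candidate$genome_id]),
    p_value = p_value,
    direction = direction,
    bgc_length = candidate$length,
    product_types = paste(candidate$product_types, collapse = ";"),
    recipient = format_lineage(profiles[[candidate$genome_id]]),
    donor = if (is.character(donor) && length(donor) == 1L && donor == "unclassified")
      "unclassified" else format_lineage(donor),
    same_genus_similar_bgcs = n_similar,
    nearest_reference_distance = nearest,
    low_confidence = low_confidence,
    reason = reason,
    stringsAsFactors = FALSE)
}

.empty_calls <- function() {
  data.frame(bgc_id = character(0), genome_id = character(0),
             gcf_id = character(0), verdict = character(0),
             outlier_mean_distance = numeric(0), p_value = numeric(0),
             direction = character(0), bgc_length = integer(0),
             product_types = character(0), recipient = character(0),
             donor = character(0), same_genus_similar_bgcs = integer(0),
             nearest_reference_distance = numeric(0),
             low_confidence = logical(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.htbgc <- function(x, ...) {
  cat("Horizontally transferred BGC detection\n")
  cat("  BGCs: ", x$log$input_bgcs, " in ", x$log$input_genomes,
      " genomes; GCFs: ", x$log$gcfs %||% 0L, "\n", sep = "")
  cat("  candidates: ", nrow(x$calls), "; HTBGC calls: ",
      sum(x$calls$verdict == "HTBGC"), "\n", sep = "")
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' @export
summary.htbgc <- function(object, ...) {
  cat("Call verdicts:\n")
  print(table(factor(object$calls$verdict,
                     levels = c("HTBGC", "not-HTBGC", "untestable"))))
  ht <- object$calls[object$calls$verdict == "HTBGC", , drop = FALSE]
  if (nrow(ht)) {
    cat("\nHTBGC calls:\n")
    print(ht[, c("bgc_id", "genome_id", "gcf_id", "p_value",
                 "outlier_mean_distance", "product_types")], row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.htbgc <- function(x, ...) x$calls

#' Write the per-candidate report table
#'
#' One tab-separated row per candidate with the verdict and all evidence
#' columns; byte-identical across runs on identical inputs.
#'
#' @param x An `htbgc` result.
#' @param path Output path.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "htbgc"))
  utils::write.table(x$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run detection from a configuration list or YAML file
#'
#' Thin orchestration wrapper over [detect_htbgc()] for file-based inputs:
#' reads the BGC table, lineage table, and optionally a reference manifest
#' (+ reference BGC table), ANI table, and external network edges, then
#' runs detection and (optionally) writes the report.
#'
#' @param config Named list (or path to a YAML file) with entries
#'   `bgc_tsv`, `lineage_tsv`, and optionally `reference_manifest`,
#'   `reference_bgc_tsv`, `ani_tsv`, `network_tsv`, `out`, plus any of
#'   `cutoff`, `alpha`, `rule`, `test_method`, `min_genes`, `min_mags`.
#' @return The `htbgc` result, invisibly when a report is written.
#' @export
run_detection <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$bgc_tsv), !is.null(config$lineage_tsv))
  bgcs <- read_bgc_tsv(config$bgc_tsv)
  profiles <- read_lineage_tsv(config$lineage_tsv)
  ref_bgcs <- list(); ref_profiles <- list()
  if (!is.null(config$reference_manifest)) {
    man <- read_reference_manifest(config$reference_manifest)
    ref_profiles <- attr(man, "profiles")
    if (!is.null(config$reference_bgc_tsv)) {
      ref_bgcs <- read_bgc_tsv(config$reference_bgc_tsv)
    }
  }
  ani <- if (!is.null(config$ani_tsv)) read_fastani(config$ani_tsv) else NULL
  edges <- if (!is.null(config$network_tsv)) read_bigscape_network(config$network_tsv) else NULL
  res <- detect_htbgc(
    bgcs, profiles, reference_bgcs = ref_bgcs, reference_profiles = ref_profiles,
    edges = edges, ani = ani,
    ani_threshold = config$ani_threshold %||% 99,
    cutoff = config$cutoff %||% 0.3, alpha = config$alpha %||% 0.05,
    rule = config$rule %||% "mean",
    test_method = config$test_method %||% "wilcoxon",
    min_genes = config$min_genes %||% 5L,
    min_mags = config$min_mags %||% 0L)
  if (!is.null(config$out)) {
    write_report(res, config$out)
    return(invisible(res))
  }
  res
}
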