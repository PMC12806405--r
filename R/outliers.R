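# Taxonomic outlier detection within a GCF. Each member genome gets a mean
# rank-distance to the other members; a genome far above the family-wide
# mean (or with a large Z-score) is a horizontal-transfer candidate.

#' Mean taxonomic distance of one genome to the rest of a GCF
#'
#' `(1/(n-1)) * sum_j D_ij` over the other member genomes. The 999 sentinel
#' for fully disjoint classifications participates like any other value.
#'
#' @param genome_id Genome whose mean is wanted.
#' @param member_genomes Character vector of all member genome ids
#'   (including `genome_id`), length >= 2.
#' @param profiles Named list of taxonomy profiles covering all members.
#' @return The mean distance.
#' @export
mean_genetic_distance <- function(genome_id, member_genomes, profiles) {
  others <- setdiff(member_genomes, genome_id)
  if (!length(others)) stop("insufficient members: GCF has a single genome")
  mean(vapply(others, function(g) {
    taxonomic_distance(profiles[[genome_id]], profiles[[g]])
  }, numeric(1L)))
}

#' Overall mean pairwise taxonomic distance of a GCF
#'
#' Mean of `D_ij` over the `n(n-1)/2` unordered genome pairs
#' (`pair_mean = "unordered"`, the default). `pair_mean = "printed"` instead
#' divides the upper-triangle sum by `n(n-1)`, halving the value and so
#' doubling the stringency of the mean outlier rule.
#'
#' @param member_genomes Character vector of member genome ids, length >= 2.
#' @param profiles Named list of taxonomy profiles.
#' @param pair_mean `"unordered"` or `"printed"` (see above).
#' @return The overall mean distance.
#' @export
overall_mean_distance <- function(member_genomes, profiles,
                                  pair_mean = c("unordered", "printed")) {
  pair_mean <- match.arg(pair_mean)
  n <- length(member_genomes)
  if (n < 2L) stop("insufficient members: GCF has a single genome")
  pairs <- utils::combn(n, 2L)
  s <- sum(vapply(seq_len(ncol(pairs)), function(k) {
    taxonomic_distance(profiles[[member_genomes[pairs[1L, k]]]],
                       profiles[[member_genomes[pairs[2L, k]]]])
  }, numeric(1L)))
  if (pair_mean == "unordered") s / ncol(pairs) else s / (n * (n - 1))
}

#' Flag taxonomic outlier genomes within a GCF
#'
#' The mean rule flags genome i when its mean distance exceeds twice the
#' family-wide mean (`D_i > 2 * D_all`). The z rule flags i when
#' `(D_i - mu)/sigma > 2`, with `mu`, `sigma` the mean and standard
#' deviation of all members' mean distances. `"both"` flags the union.
#'
#' @param member_genomes Character vector of member genome ids.
#' @param profiles Named list of taxonomy profiles.
#' @param rule `"mean"`, `"z"`, or `"both"`; default `"mean"`.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   for the z rule's sigma.
#' @param pair_mean Passed to [overall_mean_distance()].
#' @return An `outlier_report`: list with `per_genome_mean`, `overall_mean`,
#'   `z_scores`, `outliers` (character vector), `rule`, and `skipped`
#'   (reason string when the GCF was too small, else `NA`).
#' @export
find_outliers <- function(member_genomes, profiles,
                          rule = c("mean", "z", "both"),
                          sd_type = c("sample", "population"),
                          pair_mean = "unordered") {
  rule <- match.arg(rule)
  sd_type <- match.arg(sd_type)
  member_genomes <- unique(member_genomes)
  n <- length(member_genomes)
  if (n < 3L) {
    return(structure(list(
      per_genome_mean = stats::setNames(numeric(0), character(0)),
      overall_mean = NA_real_, z_scores = NULL,
      outliers = character(0), rule = rule,
      skipped = sprintf("GCF has %d genome(s); outlier detection needs >= 3", n)
    ), class = "outlier_report"))
  }
  d_i <- vapply(member_genomes, mean_genetic_distance, numeric(1L),
                member_genomes = member_genomes, profiles = profiles)
  d_all <- overall_mean_distance(member_genomes, profiles, pair_mean = pair_mean)
  mu <- mean(d_i)
  sigma <- if (sd_type == "sample") stats::sd(d_i) else {
    sqrt(mean((d_i - mu)^2))
  }
  z <- if (sigma > 0) (d_i - mu) / sigma else stats::setNames(rep(0, n), names(d_i))
  mean_out <- names(d_i)[d_i > 2 * d_all]
  z_out <- if (sigma > 0) names(z)[z > 2] else character(0)
  out <- switch(rule, mean = mean_out, z = z_out,
                both = union(mean_out, z_out))
  structure(list(per_genome_mean = d_i, overall_mean = d_all, z_scores = z,
                 outliers = sort(out), rule = rule, skipped = NA_character_),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  if (!is.na(x$skipped)) {
    cat("<outlier report> skipped:", x$skipped, "\n")
    return(invisible(x))
  }
  cat("<outlier report> rule=", x$rule, " D_all=",
      format(x$overall_mean, digits = 4), "\n", sep = "")
  cat("  outliers:", if (length(x$outliers)) paste(x$outliers, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
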