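# Reference-genome isolation check: an outlier BGC is re-clustered with the
# BGCs of reference genomes from its own species/genus; a genuinely
# transferred cluster stays in a singleton family.

#' Read a reference-genome manifest
#'
#' Tab-separated columns `genome_id`, `lineage`, `path` (path to the
#' genome's BGC table in either supported dialect; may be empty when the
#' records are supplied separately). Header optional.
#'
#' @param path Manifest TSV path.
#' @return Data frame with columns `genome_id`, `lineage`, `path` plus a
#'   `profiles` attribute (named list of taxonomy profiles).
#' @export
read_reference_manifest <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", colClasses = "character",
                           fill = TRUE, blank.lines.skip = TRUE)
  if (ncol(tab) < 2L) stop("reference manifest needs columns genome_id, lineage[, path]")
  if (tolower(tab[1L, 1L]) %in% c("genome_id", "genome")) tab <- tab[-1L, , drop = FALSE]
  if (ncol(tab) < 3L) tab[[3L]] <- ""
  names(tab)[1:3] <- c("genome_id", "lineage", "path")
  profs <- lapply(seq_len(nrow(tab)),
                  function(i) parse_lineage(tab$lineage[i], genome_id = tab$genome_id[i]))
  names(profs) <- tab$genome_id
  attr(tab, "profiles") <- profs
  tab
}

#' Select the reference BGCs relevant to an outlier
#'
#' Returns reference BGCs whose genome matches the outlier's genome at
#' Species level, plus those matching at Genus level (type-strain
#' surrogates, marked in the `genus_only` attribute). A reference lacking a
#' species label but sharing the genus is included via the genus filter.
#'
#' @param outlier_profile Taxonomy profile of the outlier's genome.
#' @param reference_bgcs Named list of `bgc_record`s from reference genomes.
#' @param reference_profiles Named list of taxonomy profiles keyed by
#'   reference genome id.
#' @return Named list of `bgc_record`s (possibly empty) with a logical
#'   `genus_only` attribute parallel to the list.
#' @export
select_reference_set <- function(outlier_profile, reference_bgcs,
                                 reference_profiles) {
  if (!length(reference_bgcs)) return(structure(list(), genus_only = logical(0)))
  g_ids <- vapply(reference_bgcs, `[[`, character(1L), "genome_id")
  sp <- outlier_profile[["Species"]]
  ge <- outlier_profile[["Genus"]]
  match_species <- vapply(g_ids, function(g) {
    p <- reference_profiles[[g]]
    !is.null(p) && sp != TAX_UNKNOWN && p[["Species"]] == sp
  }, logical(1L))
  match_genus <- vapply(g_ids, function(g) {
    p <- reference_profiles[[g]]
    !is.null(p) && ge != TAX_UNKNOWN && p[["Genus"]] == ge
  }, logical(1L))
  keep <- match_species | match_genus
  structure(reference_bgcs[keep],
            genus_only = unname(match_genus[keep] & !match_species[keep]))
}

#' Isolation test against same-taxon reference BGCs
#'
#' Clusters the outlier together with the selected reference BGCs at the
#' GCF cutoff; the outlier is isolated when its family is a singleton.
#' An empty reference set is isolated by construction and flagged low
#' confidence downstream; its nearest distance is `NA`.
#'
#' @param outlier A `bgc_record`.
#' @param reference_bgcs Named list of reference `bgc_record`s.
#' @param cutoff Clustering cutoff in `(0, 1)`; default 0.3.
#' @return List with `isolated` (logical), `nearest_distance` (numeric or
#'   `NA`), and `n_references`.
#' @export
isolation_test <- function(outlier, reference_bgcs, cutoff = 0.3) {
  stopifnot(cutoff > 0, cutoff < 1)
  if (!length(reference_bgcs)) {
    return(list(isolated = TRUE, nearest_distance = NA_real_, n_references = 0L))
  }
  all_bgcs <- c(list(outlier), unname(reference_bgcs))
  names(all_bgcs) <- vapply(all_bgcs, `[[`, character(1L), "bgc_id")
  part <- cluster_gcfs(all_bgcs, cutoff = cutoff)
  fam <- part$membership[[outlier$bgc_id]]
  nearest <- min(vapply(reference_bgcs, bgc_distance, numeric(1L), a = outlier))
  list(isolated = length(part$families[[fam]]) == 1L,
       nearest_distance = nearest,
       n_references = length(reference_bgcs))
}
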