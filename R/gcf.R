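# Gene cluster family (GCF) networks: a domain-content distance between
# BGCs, single-linkage partitioning at a cutoff, and ingestion of
# externally computed similarity networks.

#' Domain-content distance between two BGCs
#'
#' Jaccard distance over the union of per-gene domain labels:
#' `1 - |A intersect B| / |A union B|`. Deterministic and symmetric; a
#' lightweight, dependency-free stand-in for composite BGC similarity
#' indices, interchangeable with an external network via
#' [read_bigscape_network()].
#'
#' @param a,b `bgc_record` objects with at least one domain label between them.
#' @return Distance in `[0, 1]`.
#' @export
bgc_distance <- function(a, b) {
  da <- bgc_domains(a); db <- bgc_domains(b)
  if (!length(da) && !length(db)) {
    stop("both BGCs (", a$bgc_id, ", ", b$bgc_id,
         ") have empty domain sets; unusable for clustering")
  }
  1 - length(intersect(da, db)) / length(union(da, db))
}

.pairwise_edges <- function(bgcs) {
  ids <- vapply(bgcs, `[[`, character(1L), "bgc_id")
  n <- length(bgcs)
  if (n < 2L) {
    return(data.frame(a = character(0), b = character(0), distance = numeric(0)))
  }
  doms <- lapply(bgcs, bgc_domains)
  empty <- !vapply(doms, length, integer(1L))
  if (any(empty)) {
    stop("BGC record(s) with empty domain set: ",
         paste(ids[empty], collapse = ", "))
  }
  pairs <- utils::combn(n, 2L)
  d <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    1 - length(intersect(doms[[i]], doms[[j]])) / length(union(doms[[i]], doms[[j]]))
  }, numeric(1L))
  data.frame(a = ids[pairs[1L, ]], b = ids[pairs[2L, ]], distance = d,
             stringsAsFactors = FALSE)
}

#' Cluster BGCs into gene cluster families
#'
#' Single-linkage partition: families are the connected components of the
#' graph whose edges are BGC pairs at distance at most `cutoff`. Singletons
#' form their own family. Family ids are assigned deterministically by
#' sorting components on their lexicographically smallest member id.
#'
#' @param bgcs Named list of `bgc_record` objects (length >= 1).
#' @param cutoff Distance threshold in `[0, 1]`; default 0.3.
#' @param edges Optional precomputed edge data frame (`a`, `b`, `distance`),
#'   e.g. from [read_bigscape_network()]; when supplied, pairwise distances
#'   are not recomputed and BGCs absent from the edge list become singletons.
#' @return A `gcf_partition`: list with `families` (named list of bgc_id
#'   vectors), `membership` (named vector bgc_id -> family_id), `edges`,
#'   and `cutoff`.
#' @export
cluster_gcfs <- function(bgcs, cutoff = 0.3, edges = NULL) {
  stopifnot(length(bgcs) >= 1L)
  ids <- vapply(bgcs, `[[`, character(1L), "bgc_id")
  if (is.null(edges)) edges <- .pairwise_edges(bgcs)
  keep <- edges[edges$distance <= cutoff &
                  edges$a %in% ids & edges$b %in% ids, , drop = FALSE]
  g <- igraph::graph_from_data_frame(keep[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  fams <- split(names(comp), comp)
  fams <- fams[order(vapply(fams, function(m) min(m), character(1L)))]
  names(fams) <- sprintf("GCF_%04d", seq_along(fams))
  fams <- lapply(fams, function(m) sort(m))
  membership <- stats::setNames(rep(names(fams), lengths(fams)),
                                unlist(fams, use.names = FALSE))
  structure(list(families = fams, membership = membership,
                 edges = edges, cutoff = cutoff),
            class = "gcf_partition")
}

#' @export
print.gcf_partition <- function(x, ...) {
  cat("<GCF partition> ", length(x$membership), " BGCs in ",
      length(x$families), " families (cutoff ", x$cutoff, ")\n", sep = "")
  sizes <- lengths(x$families)
  cat("  family sizes: ", paste(utils::head(sort(sizes, decreasing = TRUE), 10),
                                collapse = " "),
      if (length(sizes) > 10) " ...", "\n", sep = "")
  invisible(x)
}

#' Read an externally computed BGC similarity network
#'
#' Accepts the tab-separated network dialect with columns
#' `Clustername 1`, `Clustername 2` and `Raw distance`; extra columns are
#' ignored.
#'
#' @param path Path to the network TSV.
#' @return Data frame with columns `a`, `b`, `distance`.
#' @export
read_bigscape_network <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  need <- c("Clustername 1", "Clustername 2", "Raw distance")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("network TSV missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  data.frame(a = tab[["Clustername 1"]], b = tab[["Clustername 2"]],
             distance = as.numeric(tab[["Raw distance"]]),
             stringsAsFactors = FALSE)
}

#' Write a GCF partition as a membership table
#'
#' Columns `family_id`, `bgc_id`, `genome_id`, tab-separated.
#' @param partition A `gcf_partition`.
#' @param bgcs The records that were clustered (for genome ids).
#' @param path Output path.
#' @export
write_gcf_tsv <- function(partition, bgcs, path) {
  g_of <- vapply(bgcs, `[[`, character(1L), "genome_id")
  names(g_of) <- vapply(bgcs, `[[`, character(1L), "bgc_id")
  tab <- data.frame(family_id = unname(partition$membership),
                    bgc_id = names(partition$membership),
                    genome_id = unname(g_of[names(partition$membership)]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$family_id, tab$bgc_id), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
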