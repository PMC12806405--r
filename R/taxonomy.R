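# Seven-rank taxonomy handling and the exponential rank-distance used to
# score how taxonomically far apart two BGC-carrying genomes are.

#' Taxonomic ranks, most general first
#'
#' The seven ranks used throughout the package, ordered Domain -> Species.
#' @export
TAX_RANKS <- c("Domain", "Phylum", "Class", "Order", "Family", "Genus", "Species")

.RANK_PREFIXES <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Marker for an unclassified rank
#' @export
TAX_UNKNOWN <- "unknown"

#' Parse a seven-rank lineage string
#'
#' Accepts either the GTDB/kraken2-style prefixed dialect
#' (`"d__Bacteria;p__Bacteroidota;..."`) or a plain semicolon-separated
#' seven-field dialect. Empty or missing fields become `"unknown"`.
#'
#' @param text A single lineage string. `""` or `NA` yields an all-unknown
#'   profile.
#' @param genome_id Optional genome identifier attached as an attribute.
#' @return A named character vector of length 7 (names `TAX_RANKS`).
#' @examples
#' parse_lineage("d__Bacteria;p__Bacteroidota;c__;o__;f__;g__;s__")
#' @export
parse_lineage <- function(text, genome_id = NULL) {
  stopifnot(length(text) == 1L)
  prof <- rep(TAX_UNKNOWN, 7L)
  names(prof) <- TAX_RANKS
  if (!is.na(text) && nzchar(trimws(text))) {
    fields <- trimws(strsplit(text, ";", fixed = TRUE)[[1L]])
    if (length(fields) > 7L) {
      stop("lineage has ", length(fields), " fields (max 7): ", text)
    }
    prefixed <- grepl("^[dpcofgs]__", fields)
    if (any(prefixed)) {
      for (k in seq_along(fields)) {
        f <- fields[k]
        if (!nzchar(f)) next
        pref <- substr(f, 1L, 3L)
        slot <- match(pref, .RANK_PREFIXES)
        if (is.na(slot)) {
          stop("malformed rank prefix in field ", k, ": '", f, "'")
        }
        if (slot != k) {
          stop("rank prefix '", pref, "' out of order at field ", k,
               " (expected '", .RANK_PREFIXES[k], "')")
        }
        label <- trimws(substr(f, 4L, nchar(f)))
        if (nzchar(label)) prof[slot] <- label
      }
    } else {
      for (k in seq_along(fields)) {
        if (nzchar(fields[k])) prof[k] <- fields[k]
      }
    }
  }
  if (!is.null(genome_id)) attr(prof, "genome_id") <- genome_id
  prof
}

#' Read a lineage table
#'
#' Two tab-separated columns, `genome_id` and `lineage`; a header line is
#' detected and skipped. Both lineage dialects are accepted.
#'
#' @param path Path to a TSV file.
#' @return Named list of taxonomy profiles keyed by genome id.
#' @export
read_lineage_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", colClasses = "character",
                           blank.lines.skip = TRUE)
  if (ncol(tab) < 2L) stop("lineage TSV needs two columns: genome_id, lineage")
  if (nrow(tab) > 0L &&
      tolower(tab[1L, 1L]) %in% c("genome_id", "genome", "bin", "bin_id")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(tab)),
                function(i) parse_lineage(tab[i, 2L], genome_id = tab[i, 1L]))
  names(out) <- tab[[1L]]
  out
}

#' Index of a taxonomic rank
#'
#' Domain is 0 (least specific) through Species at 6 (most specific).
#'
#' @param rank One of `TAX_RANKS`.
#' @return Integer in 0..6.
#' @export
rank_index <- function(rank) {
  i <- match(rank, TAX_RANKS)
  if (any(is.na(i))) stop("unknown rank name: ", paste(rank[is.na(i)], collapse = ", "))
  i - 1L
}

#' Deepest rank at which two profiles agree
#'
#' Checks ranks from Species up to Domain and returns the most specific rank
#' where both labels are equal and neither is `"unknown"`. An `"unknown"`
#' label never matches, including another `"unknown"`.
#'
#' @param a,b Taxonomy profiles from [parse_lineage()].
#' @return A rank name, or `NA_character_` if no rank matches.
#' @export
deepest_shared_rank <- function(a, b) {
  stopifnot(length(a) == 7L, length(b) == 7L)
  for (k in 7:1) {
    if (a[[k]] != TAX_UNKNOWN && b[[k]] != TAX_UNKNOWN && a[[k]] == b[[k]]) {
      return(TAX_RANKS[k])
    }
  }
  NA_character_
}

#' Exponential taxonomic distance between two genomes
#'
#' `2^(7 - index(t))` where `t` is the deepest shared rank (so same species
#' scores 2, sharing only Domain scores 128), and the sentinel 999 when the
#' two classifications disjoint at every rank.
#'
#' @param a,b Taxonomy profiles.
#' @return A number in `{2, 4, 8, 16, 32, 64, 128, 999}`.
#' @export
taxonomic_distance <- function(a, b) {
  t <- deepest_shared_rank(a, b)
  if (is.na(t)) return(999)
  2^(7 - rank_index(t))
}

#' Pairwise taxonomic distance matrix
#'
#' @param profiles Named list of taxonomy profiles.
#' @return Symmetric numeric matrix with genome ids as dimnames.
#' @export
taxonomic_distance_matrix <- function(profiles) {
  n <- length(profiles)
  ids <- names(profiles)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- taxonomic_distance(profiles[[i]], profiles[[j]])
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

#' Lowest common lineage of a set of profiles
#'
#' Keeps each rank's label, from Domain downward, while all profiles agree on
#' a known label; ranks below the first disagreement (or unknown) become
#' `"unknown"`. Used to summarise the taxonomy of a donor clade.
#'
#' @param profiles List of taxonomy profiles (length >= 1).
#' @return A taxonomy profile; all-unknown when even Domain is not shared.
#' @export
common_lineage <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  out <- rep(TAX_UNKNOWN, 7L)
  names(out) <- TAX_RANKS
  for (k in 1:7) {
    labs <- vapply(profiles, function(p) p[[k]], character(1L))
    if (any(labs == TAX_UNKNOWN) || length(unique(labs)) != 1L) break
    out[k] <- labs[1L]
  }
  out
}

#' Format a profile back into the prefixed lineage dialect
#' @param profile A taxonomy profile.
#' @return A single `d__...;p__...;...` string; unknown ranks are left empty.
#' @export
format_lineage <- function(profile) {
  labs <- ifelse(profile == TAX_UNKNOWN, "", profile)
  paste0(.RANK_PREFIXES, labs, collapse = ";")
}
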