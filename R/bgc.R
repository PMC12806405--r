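# BGC records and their on-disk dialects: a plain per-gene TSV and
# antiSMASH-style region GenBank files.

#' Construct a BGC record
#'
#' A record describes one biosynthetic gene cluster: its genomic location,
#' product type(s), and the ordered genes with nucleotide sequences and
#' domain/function labels. Coordinates are 1-based inclusive.
#'
#' @param bgc_id,genome_id,contig_id Identifiers.
#' @param start,end Nucleotide coordinates, `end >= start`.
#' @param product_types Character vector of product-type labels.
#' @param genes Data frame with columns `gene_id`, `seq`, `domains`
#'   (semicolon-joined domain labels; may be empty strings).
#' @return An object of class `bgc_record`.
#' @export
new_bgc <- function(bgc_id, genome_id, contig_id, start, end,
                    product_types, genes) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || end < start) {
    stop("invalid coordinates for ", bgc_id, ": start=", start, " end=", end)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "seq", "domains")
  if (!all(need %in% names(genes))) {
    stop("genes table for ", bgc_id, " missing column(s): ",
         paste(setdiff(need, names(genes)), collapse = ", "))
  }
  if (nrow(genes) < 1L) stop("BGC ", bgc_id, " has no genes")
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id within BGC ", bgc_id)
  }
  structure(list(
    bgc_id = as.character(bgc_id),
    genome_id = as.character(genome_id),
    contig_id = as.character(contig_id),
    start = start, end = end,
    length = end - start + 1L,
    product_types = as.character(product_types),
    genes = genes[, need]
  ), class = "bgc_record")
}

#' @export
print.bgc_record <- function(x, ...) {
  cat("<BGC ", x$bgc_id, "> genome=", x$genome_id, " contig=", x$contig_id,
      " ", x$start, "..", x$end, " (", x$length, " nt)\n", sep = "")
  cat("  products: ", paste(x$product_types, collapse = ", "), "\n", sep = "")
  cat("  genes: ", nrow(x$genes), "\n", sep = "")
  invisible(x)
}

#' Union of domain labels across a record's genes
#' @param bgc A `bgc_record`.
#' @return Character vector (possibly empty) of unique domain labels.
#' @export
bgc_domains <- function(bgc) {
  d <- unlist(strsplit(bgc$genes$domains, ";", fixed = TRUE), use.names = FALSE)
  unique(d[nzchar(d)])
}

.revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
         }, character(1L), USE.NAMES = FALSE))
}

.BGC_TSV_COLS <- c("bgc_id", "genome_id", "contig_id", "start", "end",
                   "product_types", "gene_id", "gene_seq", "domains")

#' Read the plain per-gene BGC table
#'
#' One row per gene; columns `bgc_id, genome_id, contig_id, start, end,
#' product_types, gene_id, gene_seq, domains` with `;`-joined multi-value
#' fields. The inverse of [write_bgc_tsv()].
#'
#' @param path Path to a TSV file with a header line.
#' @return Named list of `bgc_record` objects, keyed by `bgc_id`.
#' @export
read_bgc_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", colClasses = "character")
  missing <- setdiff(.BGC_TSV_COLS, names(tab))
  if (length(missing)) {
    stop("BGC TSV missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(structure(list(), names = character(0)))
  out <- lapply(split(tab, factor(tab$bgc_id, levels = unique(tab$bgc_id))),
                function(g) {
    new_bgc(g$bgc_id[1L], g$genome_id[1L], g$contig_id[1L],
            g$start[1L], g$end[1L],
            product_types = strsplit(g$product_types[1L], ";", fixed = TRUE)[[1L]],
            genes = data.frame(gene_id = g$gene_id, seq = g$gene_seq,
                               domains = g$domains, stringsAsFactors = FALSE))
  })
  out[unique(tab$bgc_id)]
}

#' Write BGC records to the plain per-gene table
#'
#' @param bgcs List of `bgc_record` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bgc_tsv <- function(bgcs, path) {
  rows <- lapply(bgcs, function(b) {
    data.frame(bgc_id = b$bgc_id, genome_id = b$genome_id,
               contig_id = b$contig_id, start = b$start, end = b$end,
               product_types = paste(b$product_types, collapse = ";"),
               gene_id = b$genes$gene_id, gene_seq = b$genes$seq,
               domains = b$genes$domains, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    as.data.frame(stats::setNames(rep(list(character(0)), length(.BGC_TSV_COLS)),
                                  .BGC_TSV_COLS))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read antiSMASH-style region GenBank files
#'
#' Parses `region` (or `protocluster`) features for product types and CDS
#' features for genes from a GenBank flat file. Minus-strand CDS sequences
#' are stored reverse-complemented so downstream alignment-free comparisons
#' are orientation-invariant. Coordinates are GenBank 1-based inclusive.
#' Domain labels are taken from `gene_functions`/`gene_kind`/`product`
#' qualifiers when present.
#'
#' @param path Path to a GenBank file (one or more LOCUS blocks).
#' @param genome_id Genome identifier to attach; defaults to the file name
#'   without extension.
#' @return Named list of `bgc_record` objects (possibly empty, with a
#'   warning, when no region feature is found).
#' @export
read_antismash_regions <- function(path, genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(gbk|gb|gbff|genbank)$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines))) {
    stop("not a GenBank file (no LOCUS line): ", path)
  }
  starts <- grep("^LOCUS", lines)
  bounds <- c(starts, length(lines) + 1L)
  out <- list()
  for (b in seq_along(starts)) {
    block <- lines[bounds[b]:(bounds[b + 1L] - 1L)]
    rec <- .parse_genbank_block(block, genome_id, region_index = b)
    if (!is.null(rec)) out[[rec$bgc_id]] <- rec
  }
  if (!length(out)) warning("no region feature found in ", path)
  out
}

# One LOCUS..// block -> bgc_record or NULL (no region feature).
.parse_genbank_block <- function(block, genome_id, region_index) {
  locus <- strsplit(trimws(block[1L]), "[[:space:]]+")[[1L]]
  contig_id <- if (length(locus) >= 2L) locus[2L] else paste0("contig", region_index)

  feat_start <- grep("^FEATURES", block)
  origin_start <- grep("^ORIGIN", block)
  if (!length(feat_start)) stop("GenBank block missing FEATURES table")

  feat_end <- if (length(origin_start)) origin_start[1L] - 1L else length(block)
  feats <- block[(feat_start[1L] + 1L):feat_end]

  seq <- ""
  if (length(origin_start)) {
    seq_lines <- block[(origin_start[1L] + 1L):length(block)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }

  # split the feature table into (key, location, qualifier-lines) entries
  is_key <- grepl("^ {5}[A-Za-z_']", feats)
  idx <- which(is_key)
  entries <- list()
  for (i in seq_along(idx)) {
    to <- if (i < length(idx)) idx[i + 1L] - 1L else length(feats)
    chunk <- feats[idx[i]:to]
    key <- strsplit(trimws(chunk[1L]), "[[:space:]]+")[[1L]]
    entries[[i]] <- list(key = key[1L],
                         loc = paste(key[-1L], collapse = ""),
                         quals = .parse_qualifiers(chunk[-1L]))
  }
  keys <- vapply(entries, `[[`, character(1L), "key")

  region_i <- which(keys %in% c("region", "protocluster"))
  if (!length(region_i)) return(NULL)
  region <- entries[[region_i[1L]]]
  rloc <- .parse_location(region$loc)
  products <- region$quals[names(region$quals) == "product"]
  if (!length(products)) products <- "unknown"

  cds_i <- which(keys == "CDS")
  if (!length(cds_i)) stop("region without CDS features in block for ", genome_id)
  genes <- do.call(rbind, lapply(seq_along(cds_i), function(k) {
    e <- entries[[cds_i[k]]]
    loc <- .parse_location(e$loc)
    gid <- .qual1(e$quals, "locus_tag") %||% .qual1(e$quals, "gene") %||%
      .qual1(e$quals, "protein_id") %||% sprintf("cds%03d", k)
    gseq <- ""
    if (nzchar(seq) && loc$end <= nchar(seq)) {
      gseq <- substr(seq, loc$start, loc$end)
      if (loc$strand < 0L) gseq <- .revcomp(gseq)
    }
    doms <- unique(c(e$quals[names(e$quals) == "gene_functions"],
                     e$quals[names(e$quals) == "gene_kind"],
                     e$quals[names(e$quals) == "product"]))
    data.frame(gene_id = gid, seq = gseq,
               domains = paste(doms, collapse = ";"),
               start = loc$start, stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$start), c("gene_id", "seq", "domains")]
  new_bgc(sprintf("%s_region%03d", genome_id, region_index),
          genome_id, contig_id, rloc$start, rloc$end,
          product_types = unname(products), genes = genes)
}

.parse_qualifiers <- function(lines) {
  lines <- trimws(lines)
  qstart <- grepl("^/", lines)
  # continuation lines are folded into the preceding qualifier
  vals <- character(0); keysv <- character(0); cur <- 0L
  for (ln in lines) {
    if (grepl("^/", ln)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0L) {
        keysv <- c(keysv, substr(ln, 2L, eq - 1L))
        vals <- c(vals, substr(ln, eq + 1L, nchar(ln)))
      } else {
        keysv <- c(keysv, substr(ln, 2L, nchar(ln)))
        vals <- c(vals, "")
      }
      cur <- length(vals)
    } else if (cur > 0L) {
      vals[cur] <- paste(vals[cur], ln)
    }
  }
  vals <- gsub("^\"|\"$", "", vals)
  names(vals) <- keysv
  vals
}

.parse_location <- function(loc) {
  strand <- if (grepl("complement", loc, fixed = TRUE)) -1L else 1L
  nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
  if (!length(nums)) stop("unparseable feature location: ", loc)
  list(start = min(nums), end = max(nums), strand = strand)
}

.qual1 <- function(quals, key) {
  if (key %in% names(quals)) quals[[key]] else NULL
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
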