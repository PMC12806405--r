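# Taxonomy-structured synthetic communities with planted BGC transfers.
# Annotation-level simulation: genomes are bundles of taxonomy + BGC
# records whose gene sequences diverge hierarchically along the taxonomy,
# so taxonomic distance and sequence distance correlate. Planted transfers
# copy a donor BGC into a distant genome with point mutations, with full
# truth bookkeeping for benchmarking.

#' Default per-rank cumulative divergence (substitution probability)
#'
#' Probability that a lineage accumulated a substitution at a site since
#' the ancestor at each rank, species to domain. Strictly increasing
#' toward the root so sequence distance tracks taxonomic distance.
#' @export
DEFAULT_RANK_DIVERGENCE <- c(Species = 0.001, Genus = 0.01, Family = 0.03,
                             Order = 0.06, Class = 0.10, Phylum = 0.15,
                             Domain = 0.25)

#' Point-mutate a nucleotide sequence
#'
#' Each position is independently substituted with probability `rate` to a
#' uniformly chosen *different* base. Non-ACGT characters are preserved
#' untouched; their count triggers a warning.
#'
#' @param seq A nucleotide string.
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @param seed Optional integer seed (set locally when given).
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  acgt <- chars %in% c("A", "C", "G", "T")
  n_other <- sum(!acgt)
  if (n_other > 0L) {
    warning(n_other, " non-ACGT character(s) left untouched")
  }
  hit <- which(acgt & stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.PRODUCT_CYCLE <- c("cyclic-lactone-autoinducer", "RRE-containing",
                    "thiopeptide", "arylpolyene", "RiPP-like", "NRPS",
                    "T3PKS", "lanthipeptide", "betalactone", "terpene")

#' Simulate a taxonomy-structured community with BGCs
#'
#' Builds `n_phyla` phyla (one class/order/family/genus each, a single
#' shared domain), splits each phylum's genomes into `species_per_genus`
#' species, and gives every phylum `families_per_phylum` native BGC
#' families carried by all of its genomes. Gene sequences evolve from a
#' per-family ancestor: species ancestors diverge at the genus-level rate,
#' genome copies at the species-level rate, so same-species copies are
#' nearly identical and cross-phylum families share nothing. Each BGC
#' family has its own per-gene domain labels, so family copies cluster
#' together and distinct families are dissimilar. One same-lineage
#' reference genome per species carries the genus's native families at
#' `strain_rate` divergence. Optionally plants transfers (see
#' [inject_transfers()]).
#'
#' @param n_genomes Number of genome bins (>= 4); default 10.
#' @param n_phyla Number of phyla; default 2.
#' @param species_per_genus Species groups per phylum; default 2.
#' @param families_per_phylum Native BGC families per phylum; default 5.
#' @param genes_per_bgc Genes per BGC; default 8.
#' @param gene_length Gene length in nucleotides; default 600.
#' @param rank_divergence Named cumulative divergence per rank, species to
#'   domain, strictly increasing toward the root.
#' @param strain_rate Reference-strain divergence from the species
#'   ancestor; default 0.005.
#' @param transfer_count Planted transfers; default 0.
#' @param mutation_rate Per-site mutation applied to transferred copies;
#'   default 0.02.
#' @param cross_phylum_only Restrict transfers to cross-phylum
#'   recipients; default TRUE.
#' @param seed Integer seed; the community is fully reproducible from it.
#' @return A `synthetic_community`: list with `profiles`, `bgcs`,
#'   `bgc_meta` (bgc_id/genome_id/family_id/vertical), `reference_bgcs`,
#'   `reference_profiles`, `truth` (bgc_id/donor_genome/recipient_genome),
#'   `params`, `seed`.
#' @export
simulate_community <- function(n_genomes = 10, n_phyla = 2,
                               species_per_genus = 2,
                               families_per_phylum = 5,
                               genes_per_bgc = 8, gene_length = 600,
                               rank_divergence = DEFAULT_RANK_DIVERGENCE,
                               strain_rate = 0.005,
                               transfer_count = 0, mutation_rate = 0.02,
                               cross_phylum_only = TRUE, seed = 1) {
  if (n_genomes < 4) stop("n_genomes must be >= 4")
  if (genes_per_bgc < 1 || gene_length < 1) stop("need >= 1 gene of >= 1 nt")
  if (any(rank_divergence < 0) || any(diff(rank_divergence) <= 0)) {
    stop("rank_divergence must be nonnegative and strictly increasing species -> domain")
  }
  if (n_phyla < 1 || n_phyla > n_genomes) stop("invalid n_phyla")
  set.seed(seed)

  genome_ids <- sprintf("bin%02d", seq_len(n_genomes))
  phylum_of <- rep(seq_len(n_phyla), length.out = n_genomes)

  profiles <- list()
  species_of <- character(n_genomes)
  for (p in seq_len(n_phyla)) {
    members <- which(phylum_of == p)
    k <- max(1L, min(species_per_genus, length(members)))
    sp_grp <- rep(seq_len(k), length.out = length(members))
    sp_grp <- sort(sp_grp)  # contiguous species groups
    for (m in seq_along(members)) {
      i <- members[m]
      sp <- sprintf("Species%02d_%d", p, sp_grp[m])
      species_of[i] <- sp
      profiles[[genome_ids[i]]] <- parse_lineage(paste(
        "Bacteria", sprintf("Phylum%02d", p), sprintf("Class%02d", p),
        sprintf("Order%02d", p), sprintf("Family%02d", p),
        sprintf("Genus%02d", p), sp, sep = ";"), genome_id = genome_ids[i])
    }
  }

  delta_sp <- rank_divergence[["Species"]]
  delta_genus <- rank_divergence[["Genus"]] - delta_sp

  bgcs <- list()
  ref_bgcs <- list()
  ref_profiles <- list()
  meta <- list()
  prod_i <- 0L

  for (p in seq_len(n_phyla)) {
    members <- genome_ids[phylum_of == p]
    phy_species <- unique(species_of[phylum_of == p])
    # one reference strain per species, same lineage as its MAGs
    for (sp in phy_species) {
      rid <- paste0("ref_", sp)
      ref_profiles[[rid]] <- parse_lineage(
        format_lineage(profiles[[members[species_of[phylum_of == p] == sp][1L]]]),
        genome_id = rid)
    }
    for (f in seq_len(families_per_phylum)) {
      fam <- sprintf("fam%02d_%02d", p, f)
      prod_i <- prod_i + 1L
      product <- .PRODUCT_CYCLE[(prod_i - 1L) %% length(.PRODUCT_CYCLE) + 1L]
      ancestor <- vapply(seq_len(genes_per_bgc), function(k) .random_seq(gene_length),
                         character(1L))
      sp_anc <- lapply(phy_species, function(sp) {
        vapply(ancestor, mutate_sequence, character(1L), rate = delta_genus,
               USE.NAMES = FALSE)
      })
      names(sp_anc) <- phy_species
      doms <- sprintf("%s_dom%02d", fam, seq_len(genes_per_bgc))
      make_copy <- function(owner, rate, sp) {
        bid <- sprintf("%s_%s", owner, fam)
        seqs <- vapply(sp_anc[[sp]], mutate_sequence, character(1L), rate = rate,
                       USE.NAMES = FALSE)
        start <- 1000L + (f - 1L) * (genes_per_bgc * gene_length + 200L)
        new_bgc(bid, owner, "ctg1", start,
                start + genes_per_bgc * gene_length - 1L,
                product_types = product,
                genes = data.frame(
                  gene_id = sprintf("%s_g%02d", bid, seq_len(genes_per_bgc)),
                  seq = seqs, domains = doms, stringsAsFactors = FALSE))
      }
      for (g in members) {
        b <- make_copy(g, delta_sp, species_of[genome_ids == g])
        bgcs[[b$bgc_id]] <- b
        meta[[b$bgc_id]] <- data.frame(bgc_id = b$bgc_id, genome_id = g,
                                       family_id = fam, vertical = TRUE,
                                       stringsAsFactors = FALSE)
      }
      for (sp in phy_species) {
        rid <- paste0("ref_", sp)
        rb <- make_copy(rid, strain_rate, sp)
        ref_bgcs[[rb$bgc_id]] <- rb
      }
    }
  }

  comm <- structure(list(
    profiles = profiles, bgcs = bgcs,
    bgc_meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
    reference_bgcs = ref_bgcs, reference_profiles = ref_profiles,
    truth = data.frame(bgc_id = character(0), donor_genome = character(0),
                       recipient_genome = character(0), stringsAsFactors = FALSE),
    params = list(n_genomes = n_genomes, n_phyla = n_phyla,
                  species_per_genus = species_per_genus,
                  families_per_phylum = families_per_phylum,
                  genes_per_bgc = genes_per_bgc, gene_length = gene_length,
                  rank_divergence = rank_divergence, strain_rate = strain_rate,
                  mutation_rate = mutation_rate,
                  cross_phylum_only = cross_phylum_only),
    seed = seed
  ), class = "synthetic_community")

  if (transfer_count > 0) {
    comm <- inject_transfers(comm, transfer_count, mutation_rate = mutation_rate,
                             cross_phylum_only = cross_phylum_only)
  }
  comm
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("<synthetic community> ", length(x$profiles), " genomes, ",
      length(x$bgcs), " BGCs (", nrow(x$truth), " transferred), ",
      length(x$reference_bgcs), " reference BGCs\n", sep = "")
  invisible(x)
}

#' Plant horizontal transfers into a synthetic community
#'
#' Copies `transfer_count` donor BGCs into other genomes (cross-phylum
#' recipients when `cross_phylum_only`), mutating every gene at
#' `mutation_rate`. Transferred copies get fresh ids and keep their domain
#' labels unchanged (transfer moves gene content; only sequences decay).
#' By default donors are drawn from distinct BGC families so planted
#' events do not share a family.
#'
#' @param community A `synthetic_community`.
#' @param transfer_count Number of transfers.
#' @param mutation_rate Per-site mutation of the transferred copy; default 0.02.
#' @param cross_phylum_only Recipients must be from another phylum; default TRUE.
#' @param distinct_families Draw donors from distinct families; default TRUE.
#' @param seed Optional integer seed.
#' @return The community with recipients' BGC lists and the truth table updated.
#' @export
inject_transfers <- function(community, transfer_count, mutation_rate = 0.02,
                             cross_phylum_only = TRUE,
                             distinct_families = TRUE, seed = NULL) {
  stopifnot(inherits(community, "synthetic_community"), transfer_count >= 1)
  if (!is.null(seed)) set.seed(seed)
  meta <- community$bgc_meta
  pool <- meta[meta$vertical, , drop = FALSE]
  phylum_label <- vapply(community$profiles, function(p) p[["Phylum"]], character(1L))
  if (cross_phylum_only && length(unique(phylum_label)) < 2L) {
    stop("cross-phylum transfers requested but the community has a single phylum")
  }
  n_avail <- if (distinct_families) length(unique(pool$family_id)) else nrow(pool)
  if (transfer_count > n_avail) {
    stop("transfer_count (", transfer_count, ") exceeds available donor ",
         if (distinct_families) "families" else "BGCs", " (", n_avail, ")")
  }
  donors <- if (distinct_families) {
    fams <- sample(unique(pool$family_id), transfer_count)
    vapply(fams, function(f) {
      rows <- pool$bgc_id[pool$family_id == f]
      rows[sample.int(length(rows), 1L)]
    }, character(1L), USE.NAMES = FALSE)
  } else {
    sample(pool$bgc_id, transfer_count)
  }
  for (i in seq_along(donors)) {
    donor <- community$bgcs[[donors[i]]]
    donor_genome <- donor$genome_id
    cands <- names(community$profiles)
    cands <- cands[cands != donor_genome]
    if (cross_phylum_only) {
      cands <- cands[phylum_label[cands] != phylum_label[donor_genome]]
    }
    recipient <- if (length(cands) == 1L) cands else sample(cands, 1L)
    fam <- meta$family_id[meta$bgc_id == donor$bgc_id]
    new_id <- sprintf("hgt%02d_%s_%s", nrow(community$truth) + 1L, recipient, fam)
    genes <- donor$genes
    genes$seq <- vapply(genes$seq, mutate_sequence, character(1L),
                        rate = mutation_rate, USE.NAMES = FALSE)
    genes$gene_id <- sprintf("%s_g%02d", new_id, seq_len(nrow(genes)))
    nb <- new_bgc(new_id, recipient, "ctg_hgt", 1L,
                  sum(nchar(genes$seq)), donor$product_types, genes)
    community$bgcs[[new_id]] <- nb
    community$bgc_meta <- rbind(community$bgc_meta,
                                data.frame(bgc_id = new_id, genome_id = recipient,
                                           family_id = fam, vertical = FALSE,
                                           stringsAsFactors = FALSE))
    community$truth <- rbind(community$truth,
                             data.frame(bgc_id = new_id, donor_genome = donor_genome,
                                        recipient_genome = recipient,
                                        stringsAsFactors = FALSE))
  }
  community
}

#' Write a synthetic community to plain-text files
#'
#' Emits the per-gene BGC table (`bgcs.tsv`), lineage table
#' (`lineages.tsv`), reference manifest (`reference_manifest.tsv`) and
#' reference BGC table (`reference_bgcs.tsv`), the truth table
#' (`truth.tsv`), and optionally one aligned FASTA per family gene slot
#' under `genes/` (sequences are generated equal length, so the alignment
#' is the identity).
#'
#' @param community A `synthetic_community`.
#' @param dir Output directory (created if needed).
#' @param genes_fasta Also write per-gene FASTA alignments; default FALSE.
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir, genes_fasta = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bgc_tsv(community$bgcs, file.path(dir, "bgcs.tsv"))
  write_bgc_tsv(community$reference_bgcs, file.path(dir, "reference_bgcs.tsv"))
  lin <- data.frame(genome_id = names(community$profiles),
                    lineage = vapply(community$profiles, format_lineage, character(1L)),
                    stringsAsFactors = FALSE)
  utils::write.table(lin, file.path(dir, "lineages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  man <- data.frame(genome_id = names(community$reference_profiles),
                    lineage = vapply(community$reference_profiles, format_lineage,
                                     character(1L)),
                    path = "reference_bgcs.tsv", stringsAsFactors = FALSE)
  utils::write.table(man, file.path(dir, "reference_manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(community$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (genes_fasta) {
    gdir <- file.path(dir, "genes")
    dir.create(gdir, showWarnings = FALSE)
    all_bgcs <- c(community$bgcs, community$reference_bgcs)
    fam_of <- c(stats::setNames(community$bgc_meta$family_id, community$bgc_meta$bgc_id),
                stats::setNames(sub("^.*_(fam[0-9]+_[0-9]+)$", "\\1",
                                    names(community$reference_bgcs)),
                                names(community$reference_bgcs)))
    for (fam in unique(community$bgc_meta$family_id)) {
      members <- names(fam_of)[fam_of == fam]
      n_genes <- nrow(all_bgcs[[members[1L]]]$genes)
      for (k in seq_len(n_genes)) {
        lines <- unlist(lapply(members, function(b) {
          rec <- all_bgcs[[b]]
          c(sprintf(">%s|%s", rec$genome_id, rec$genes$gene_id[k]),
            rec$genes$seq[k])
        }))
        writeLines(lines, file.path(gdir, sprintf("%s_g%02d.fasta", fam, k)))
      }
    }
  }
  invisible(dir)
}
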