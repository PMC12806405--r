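# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. Oracles deliberately use a different algorithm
# than the package code they check.

# taxonomic distance by testing all seven ranks independently
oracle_tax_distance <- function(a, b) {
  match_at <- which(a != TAX_UNKNOWN & b != TAX_UNKNOWN & a == b)
  if (!length(match_at)) return(999)
  2^(7 - (max(match_at) - 1))
}

# random seven-rank profile; small per-rank label pools so matches occur
random_profile <- function(p_unknown = 0.25, pool = 3L) {
  labs <- vapply(seq_len(7L), function(k) {
    sprintf("%s%d", substr(TAX_RANKS[k], 1, 1), sample.int(pool, 1L))
  }, character(1L))
  unk <- stats::runif(7L) < p_unknown
  labs[unk] <- TAX_UNKNOWN
  stats::setNames(labs, TAX_RANKS)
}

profile_from <- function(...) {
  labs <- c(...)
  stopifnot(length(labs) == 7L)
  stats::setNames(labs, TAX_RANKS)
}

# outlier rules evaluated directly on a distance matrix
oracle_outliers <- function(D, rule = c("mean", "z"), sd_type = "sample") {
  rule <- match.arg(rule)
  n <- nrow(D)
  d_i <- rowSums(D) / (n - 1)
  if (rule == "mean") {
    d_all <- sum(D[upper.tri(D)]) / choose(n, 2)
    which(d_i > 2 * d_all)
  } else {
    mu <- mean(d_i)
    sigma <- if (sd_type == "sample") stats::sd(d_i) else sqrt(mean((d_i - mu)^2))
    if (sigma == 0) integer(0) else which((d_i - mu) / sigma > 2)
  }
}

# one-sided (less) paired signed-rank p by enumerating all sign assignments
enum_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  stopifnot(m >= 1L, m <= 16L)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  total <- 2^m
  count <- 0L
  for (mask in 0:(total - 1L)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(m - 1L)), 1L) == 1L
    if (sum(r[signs]) <= v_obs) count <- count + 1L
  }
  count / total
}

# AUC by exhaustive positive-negative pair counting with 0.5 per tie
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# two-sided Fisher 2x2 p by hypergeometric enumeration over fixed margins
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# quick BGC with one gene per domain label
make_bgc <- function(bgc_id, genome_id, domains, seqs = NULL, start = 1L,
                     product = "RiPP-like") {
  n <- length(domains)
  if (is.null(seqs)) seqs <- strrep("ACGT", 25L)
  seqs <- rep_len(seqs, n)
  new_bgc(bgc_id, genome_id, "ctg1", start,
          start + sum(nchar(seqs)) - 1L, product,
          genes = data.frame(gene_id = sprintf("%s_g%d", bgc_id, seq_len(n)),
                             seq = seqs, domains = domains,
                             stringsAsFactors = FALSE))
}

fake_calls <- function(ids, verdicts, p = 0.01, donor = "unclassified",
                       recipient = NULL) {
  if (is.null(recipient)) recipient <- full_lineage("r")
  data.frame(bgc_id = ids, verdict = verdicts,
             p_value = rep_len(p, length(ids)),
             donor = rep_len(donor, length(ids)),
             recipient = rep_len(recipient, length(ids)),
             stringsAsFactors = FALSE)
}

full_lineage <- function(tag) {
  paste0("Bacteria;Phy_", tag, ";Cla_", tag, ";Ord_", tag, ";Fam_", tag,
         ";Gen_", tag, ";Spe_", tag)
}
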