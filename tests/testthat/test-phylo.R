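test_that("patristic distances are path sums of branch lengths", {
  d <- patristic_distances("((A:0.1,B:0.2):0.3,C:0.4);", "A")
  expect_equal(d[["B"]], 0.3)
  expect_equal(d[["C"]], 0.8)

  star <- patristic_distances("(A:0,B:0,C:0);", "B")
  expect_true(all(star == 0))

  expect_equal(patristic_distances("(A:0.5,B:0.5);", "A")[["B"]], 1.0)

  expect_error(patristic_distances("(A:0.5,B:0.5);", "Z"), "not in tree")
  expect_error(patristic_distances("((A:0.1,B:0.2", "A"), ".")
})

test_that("patristic distances agree with graph shortest paths on random trees", {
  set.seed(51)
  for (i in 1:10) {
    phy <- ape::rtree(sample(5:12, 1))
    g <- igraph::graph_from_data_frame(
      data.frame(from = phy$edge[, 1], to = phy$edge[, 2]), directed = FALSE)
    tip_ids <- match(seq_along(phy$tip.label), as.integer(igraph::V(g)$name))
    sp <- igraph::distances(g, weights = phy$edge.length)[tip_ids, tip_ids]
    dimnames(sp) <- list(phy$tip.label, phy$tip.label)
    q <- sample(phy$tip.label, 1)
    d <- patristic_distances(phy, q)
    expect_equal(d, sp[q, names(d)], tolerance = 1e-10)
    # symmetry and triangle inequality on sampled triples
    trip <- sample(phy$tip.label, 3)
    expect_lte(sp[trip[1], trip[3]],
               sp[trip[1], trip[2]] + sp[trip[2], trip[3]] + 1e-12)
  }
})

test_that("Jukes-Cantor fallback matches the closed form and saturates", {
  s <- strrep("ACGT", 25)                       # 100 nt
  expect_equal(fallback_distance(s, s), 0)

  s2 <- paste0("GGGGGGGGGG", substr(s, 11, 100))  # 10 mismatches? verify below
  p <- mean(strsplit(s, "")[[1]] != strsplit(s2, "")[[1]])
  expect_equal(fallback_distance(s, s2), -0.75 * log(1 - 4 * p / 3))

  # p = 0.1 over 100 columns -> 0.10732
  x <- strrep("A", 100)
  y <- paste0(strrep("C", 10), strrep("A", 90))
  expect_equal(fallback_distance(x, y), 0.10732, tolerance = 1e-4)

  # saturation cap
  y2 <- paste0(strrep("C", 80), strrep("A", 20))
  expect_equal(fallback_distance(x, y2), 10.0)

  expect_error(fallback_distance("ACGT", "ACG"), "length")
  expect_error(fallback_distance("--NN", "AC-G"), "comparable")

  # gaps excluded from the mismatch proportion
  expect_equal(fallback_distance("AC-T", "ACGT"), 0)
})

test_that("Jukes-Cantor fallback agrees with an established implementation", {
  set.seed(61)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    b <- mutate_sequence(a, 0.1)
    m <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
    rownames(m) <- c("a", "b")
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "JC69"))
    expect_equal(fallback_distance(a, b), ref, tolerance = 1e-9)
  }
})

test_that("representative gene distance is the group minimum with sentinel 1", {
  g <- gene_rep_distance("g1", c(0.12, 0.30), c(0.45, 0.60))
  expect_equal(g$d_bins, 0.12)
  expect_equal(g$d_refs, 0.45)
  expect_true(g$aligned_bins && g$aligned_refs)

  g2 <- gene_rep_distance("g2", c(0.2), numeric(0))
  expect_equal(g2$d_refs, 1)
  expect_false(g2$aligned_refs)

  g3 <- gene_rep_distance("g3", numeric(0), numeric(0))
  expect_equal(c(g3$d_bins, g3$d_refs), c(1, 1))

  expect_warning(gene_rep_distance("g4", c(1.4, 2.0), c(0.1)), "sentinel")
})

test_that("paired test reaches the exact signed-rank tail for uniform signs", {
  profs <- lapply(1:12, function(k) {
    gene_rep_distance(paste0("g", k), 0.01 * k, 0.5 + 0.02 * k)
  })
  res <- paired_group_test(profs, method = "wilcoxon")
  expect_equal(res$p_value, 1 / 4096)
  expect_equal(res$direction, "bins-closer")

  flat <- lapply(1:8, function(k) gene_rep_distance(paste0("g", k), 0.3, 0.3))
  rflat <- paired_group_test(flat)
  expect_equal(rflat$p_value, 1)
  expect_equal(rflat$direction, "none")

  few <- lapply(1:4, function(k) gene_rep_distance(paste0("g", k), 0.1, 0.9))
  rfew <- paired_group_test(few)
  expect_true(is.na(rfew$p_value))
  expect_match(rfew$reason, "insufficient genes")
})

test_that("paired test agrees with sign-assignment enumeration for n <= 12", {
  set.seed(71)
  for (n in c(5, 8, 10, 12)) {
    for (rep_i in 1:5) {
      d_bins <- runif(n)
      d_refs <- runif(n)
      profs <- lapply(seq_len(n), function(k) {
        gene_rep_distance(paste0("g", k), d_bins[k], d_refs[k])
      })
      p_pkg <- paired_group_test(profs, method = "wilcoxon")$p_value
      p_enum <- enum_signed_rank_p(d_bins, d_refs)
      expect_equal(p_pkg, p_enum, tolerance = 1e-12)
    }
  }
})

test_that("auto method screens differences for normality", {
  set.seed(81)
  d <- rnorm(20, mean = -0.3, sd = 0.05)
  profs <- lapply(seq_along(d), function(k) {
    gene_rep_distance(paste0("g", k), 0.5 + d[k], 0.5)
  })
  res <- paired_group_test(profs, method = "auto")
  expect_equal(res$method_used, "t")
  expect_lt(res$p_value, 0.001)

  skewed <- c(rep(-0.001, 15), -0.2, -0.3, -0.4, -0.5, -0.6)
  profs2 <- lapply(seq_along(skewed), function(k) {
    gene_rep_distance(paste0("g", k), 0.9 + skewed[k], 0.9)
  })
  expect_equal(paired_group_test(profs2, method = "auto")$method_used, "wilcoxon")
})

test_that("the verdict is the conjunction of outlier, isolation, and test", {
  iso_yes <- list(isolated = TRUE, nearest_distance = 0.9, n_references = 3L)
  iso_no <- list(isolated = FALSE, nearest_distance = 0.1, n_references = 3L)
  iso_empty <- list(isolated = TRUE, nearest_distance = NA_real_, n_references = 0L)
  sig <- list(p_value = 2e-4, direction = "bins-closer", method_used = "wilcoxon",
              n_genes = 12, reason = NA_character_)
  refs_closer <- modifyList(sig, list(direction = "refs-closer"))
  untest <- list(p_value = NA_real_, direction = "none", method_used = NA,
                 n_genes = 3, reason = "insufficient genes (3 < 5)")

  expect_equal(call_htbgc(TRUE, iso_yes, sig)$verdict, "HTBGC")
  expect_equal(call_htbgc(TRUE, iso_yes, refs_closer)$verdict, "not-HTBGC")
  expect_equal(call_htbgc(TRUE, iso_no, sig)$verdict, "not-HTBGC")
  expect_equal(call_htbgc(FALSE, iso_yes, sig)$verdict, "not-HTBGC")
  expect_equal(call_htbgc(TRUE, iso_yes, untest)$verdict, "untestable")
  expect_true(call_htbgc(TRUE, iso_empty, sig)$low_confidence)
  # alpha boundary is strict
  at_alpha <- modifyList(sig, list(p_value = 0.05))
  expect_equal(call_htbgc(TRUE, iso_yes, at_alpha, alpha = 0.05)$verdict, "not-HTBGC")
})
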