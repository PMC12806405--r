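test_that("domain-Jaccard distance matches hand-computed values", {
  a <- make_bgc("a", "g1", c("A", "B", "C", "D"))
  b <- make_bgc("b", "g2", c("A", "B"))
  expect_equal(bgc_distance(a, b), 0.5)           # 1 - 2/4
  expect_equal(bgc_distance(a, a), 0)
  expect_equal(bgc_distance(a, make_bgc("c", "g3", c("X", "Y"))), 1)
  expect_equal(bgc_distance(a, b), bgc_distance(b, a))

  e1 <- make_bgc("e1", "g4", "")
  e2 <- make_bgc("e2", "g5", "")
  expect_error(bgc_distance(e1, e2), "empty domain sets")
})

test_that("single-linkage clustering partitions BGCs at the cutoff", {
  trio <- list(a = make_bgc("a", "g1", c("X", "Y")),
               b = make_bgc("b", "g2", c("X", "Y")),
               c = make_bgc("c", "g3", c("X", "Y")))
  p <- cluster_gcfs(trio)
  expect_length(p$families, 1L)
  expect_setequal(p$families[[1]], c("a", "b", "c"))

  two <- list(a = make_bgc("a", "g1", c("A", "B", "C", "D")),
              b = make_bgc("b", "g2", c("A", "B")))
  p2 <- cluster_gcfs(two, cutoff = 0.3)
  expect_length(p2$families, 2L)

  # transitivity: A-B and B-C close, A-C far, still one family
  chain <- list(A = make_bgc("A", "g1", c("d1", "d2", "d3", "d4", "d5")),
                B = make_bgc("B", "g2", c("d1", "d2", "d3", "d4", "d6")),
                C = make_bgc("C", "g3", c("d1", "d2", "d3", "d6", "d7")))
  expect_lte(bgc_distance(chain$A, chain$B), 0.34)
  expect_gt(bgc_distance(chain$A, chain$C), 0.34)
  p3 <- cluster_gcfs(chain, cutoff = 0.34)
  expect_length(p3$families, 1L)
})

test_that("partition is valid and invariant to input order", {
  set.seed(21)
  pool <- lapply(1:12, function(i) {
    make_bgc(sprintf("b%02d", i), sprintf("g%02d", i),
             sprintf("dom%d", sample.int(8, 4)))
  })
  names(pool) <- vapply(pool, `[[`, character(1), "bgc_id")
  p <- cluster_gcfs(pool, cutoff = 0.5)
  ids <- unlist(p$families, use.names = FALSE)
  expect_setequal(ids, names(pool))          # covers every BGC
  expect_false(anyDuplicated(ids) > 0)       # families disjoint
  # edges within cutoff connect members of the same family
  close_e <- p$edges[p$edges$distance <= 0.5, ]
  expect_true(all(p$membership[close_e$a] == p$membership[close_e$b]))

  shuffled <- pool[sample(length(pool))]
  p2 <- cluster_gcfs(shuffled, cutoff = 0.5)
  expect_identical(p$families, p2$families)
})

test_that("external similarity networks are read and usable for clustering", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Clustername 1\tClustername 2\tRaw distance\tJaccard index",
               "a\tb\t0.10\t0.9",
               "b\tc\t0.80\t0.2"), tf)
  e <- read_bigscape_network(tf)
  expect_equal(nrow(e), 2L)
  expect_equal(e$distance, c(0.10, 0.80))

  bgcs <- list(a = make_bgc("a", "g1", "X"), b = make_bgc("b", "g2", "Y"),
               c = make_bgc("c", "g3", "Z"))
  p <- cluster_gcfs(bgcs, cutoff = 0.3, edges = e)
  expect_equal(unname(p$membership["a"]), unname(p$membership["b"]))
  expect_false(p$membership[["c"]] == p$membership[["a"]])

  writeLines("Clustername 1\tClustername 2\tRaw distance", tf)
  expect_equal(nrow(read_bigscape_network(tf)), 0L)

  writeLines(c("Clustername 1\tClustername 2\tOther", "a\tb\t1"), tf)
  expect_error(read_bigscape_network(tf), "Raw distance")
})

test_that("per-genome and overall mean distances follow the printed formulas", {
  profs <- c(lapply(1:4, function(i) parse_lineage(full_lineage("s"))),
             list(parse_lineage("Bacteria;POther;C;O;F;G;S")))
  names(profs) <- paste0("g", 1:5)

  expect_equal(mean_genetic_distance("g1", paste0("g", 1:4), profs), 2)
  expect_equal(mean_genetic_distance("g5", paste0("g", 1:5), profs), 128)
  expect_equal(mean_genetic_distance("g1", paste0("g", 1:5), profs),
               mean(c(2, 2, 2, 128)))          # 33.5
  expect_error(mean_genetic_distance("g1", "g1", profs), "insufficient")

  expect_equal(overall_mean_distance(paste0("g", 1:5), profs),
               (6 * 2 + 4 * 128) / 10)         # 52.4 over all 10 pairs
  expect_equal(overall_mean_distance(paste0("g", 1:4), profs), 2)

  two <- list(x = parse_lineage("Archaea;1;2;3;4;5;6"),
              y = parse_lineage("Bacteria;a;b;c;d;e;f"))
  expect_equal(overall_mean_distance(c("x", "y"), two), 999)

  # the literal printed normalization halves the unordered-pair mean
  expect_equal(overall_mean_distance(paste0("g", 1:5), profs, pair_mean = "printed"),
               52.4 / 2)
})

test_that("outlier rules flag the cross-phylum genome in the worked case", {
  profs <- c(lapply(1:4, function(i) parse_lineage(full_lineage("s"))),
             list(parse_lineage("Bacteria;POther;C;O;F;G;S")))
  names(profs) <- paste0("g", 1:5)

  rep_ <- find_outliers(paste0("g", 1:5), profs, rule = "mean")
  expect_equal(rep_$outliers, "g5")
  expect_equal(unname(rep_$per_genome_mean["g5"]), 128)
  expect_equal(rep_$overall_mean, 52.4)
  expect_gt(unname(rep_$per_genome_mean["g5"]), 2 * rep_$overall_mean)

  same <- stats::setNames(lapply(1:5, function(i) parse_lineage(full_lineage("s"))),
                          paste0("g", 1:5))
  expect_length(find_outliers(names(same), same)$outliers, 0L)

  unrelated <- list(a = parse_lineage("Archaea;1;1;1;1;1;1"),
                    b = parse_lineage("Bacteria;2;2;2;2;2;2"),
                    c = parse_lineage("Eukaryota;3;3;3;3;3;3"))
  expect_length(find_outliers(names(unrelated), unrelated)$outliers, 0L)
})

test_that("small families are skipped and zero variance yields no z outliers", {
  profs <- list(a = parse_lineage(full_lineage("s")),
                b = parse_lineage(full_lineage("s")))
  r <- find_outliers(names(profs), profs)
  expect_length(r$outliers, 0L)
  expect_match(r$skipped, "needs >= 3")

  same <- stats::setNames(lapply(1:4, function(i) parse_lineage(full_lineage("q"))),
                          paste0("g", 1:4))
  rz <- find_outliers(names(same), same, rule = "z")
  expect_length(rz$outliers, 0L)
})

test_that("flagged outliers avoid the majority species in random families", {
  set.seed(31)
  for (rep_i in 1:60) {
    n <- sample(6:12, 1L)
    n_maj <- ceiling(2 * n / 3)
    maj <- parse_lineage(full_lineage("maj"))
    profs <- c(replicate(n_maj, maj, simplify = FALSE),
               replicate(n - n_maj, random_profile(p_unknown = 0), simplify = FALSE))
    names(profs) <- sprintf("g%02d", seq_len(n))
    for (rule in c("mean", "z")) {
      out <- find_outliers(names(profs), profs, rule = rule)$outliers
      expect_length(intersect(out, sprintf("g%02d", seq_len(n_maj))), 0L)
    }
  }
})

test_that("partition membership table round-trips through the TSV writer", {
  bgcs <- list(a = make_bgc("a", "g1", "X"), b = make_bgc("b", "g1", "X"),
               c = make_bgc("c", "g2", "Y"))
  p <- cluster_gcfs(bgcs)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_gcf_tsv(p, bgcs, tf)
  tab <- read.delim(tf)
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$genome_id[tab$family_id == tab$family_id[tab$bgc_id == "a"]],
                  "g1")
})
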