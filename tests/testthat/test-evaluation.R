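test_that("confusion counts and F1 follow the harmonic-mean formula", {
  calls <- fake_calls(paste0("b", 1:5), rep("HTBGC", 5))
  perfect <- confusion(calls, paste0("b", 1:5))
  expect_equal(perfect$f1, 1)

  mixed <- confusion(fake_calls(c("b1", "b2"), c("HTBGC", "HTBGC")),
                     c("b1", "b3"))
  expect_equal(mixed$tp, 1); expect_equal(mixed$fp, 1); expect_equal(mixed$fn, 1)
  expect_equal(mixed$precision, 0.5)
  expect_equal(mixed$recall, 0.5)
  expect_equal(mixed$f1, 0.5)

  nocall <- confusion(fake_calls("b9", "not-HTBGC"), c("b1", "b2", "b3"))
  expect_equal(nocall$precision, 0)   # 0/0 convention
  expect_equal(nocall$f1, 0)
})

test_that("F1 bounds and zero cases hold on random confusion draws", {
  set.seed(111)
  for (i in 1:50) {
    n <- 30
    truth <- sample(paste0("b", 1:n), 8)
    verd <- sample(c("HTBGC", "not-HTBGC"), n, TRUE)
    cf <- confusion(fake_calls(paste0("b", 1:n), verd), truth)
    expect_lte(cf$f1, min(2 * cf$precision, 2 * cf$recall) + 1e-12)
    expect_identical(cf$f1 == 0, cf$tp == 0)
  }
})

test_that("AUC matches the printed conventions and the pair-counting oracle", {
  expect_equal(roc_auc(c(5, 4, 1, 0.5), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(2, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(TRUE, FALSE, TRUE)), 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "one positive and one negative")

  set.seed(121)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    scores <- round(runif(n), 1)          # force some ties
    labels <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("AUC equals the established ROC implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(131)
  scores <- c(rnorm(20, 1), rnorm(20))
  labels <- rep(c(TRUE, FALSE), each = 20)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("confidence scores are -log10(p) with untestable candidates at 0", {
  calls <- fake_calls(c("a", "b", "c"), c("HTBGC", "not-HTBGC", "untestable"),
                      p = c(1e-3, 0.2, NA))
  s <- htbgc_scores(calls)
  expect_equal(unname(s), c(3, -log10(0.2), 0))
})

test_that("transfer-rate tables reproduce printed percentages and conserve counts", {
  expect_equal(rate_percent(3, 112), 2.68)
  expect_equal(rate_percent(30, 7732), 0.39)
  expect_equal(rate_percent(0, 500), 0)

  set.seed(141)
  genera <- c("Megamonas", "Butyrivibrio", "Blautia", "Bacteroides")
  phyla <- c("Bacillota", "Bacteroidota")
  bgcs <- list(); profiles <- list()
  for (i in 1:40) {
    g <- sprintf("bin%02d", i)
    genus <- sample(genera, 1); phylum <- sample(phyla, 1)
    profiles[[g]] <- parse_lineage(paste("Bacteria", phylum, "C", "O", "F",
                                         genus, paste0(genus, " sp"), sep = ";"))
    b <- make_bgc(sprintf("b%02d", i), g, sprintf("d%d", sample(1:9, 3)),
                  product = sample(c("cyclic-lactone-autoinducer", "NRPS",
                                     "arylpolyene"), 1))
    bgcs[[b$bgc_id]] <- b
  }
  ht_ids <- c("b01", "b05", "b11")
  calls <- fake_calls(ht_ids, rep("HTBGC", 3))
  for (grp in c("phylum", "genus", "type", "type-class")) {
    tab <- transfer_rates(calls, bgcs, profiles, group_by = grp)
    expect_equal(sum(tab$total_count), length(bgcs))
    expect_equal(sum(tab$ht_count), length(ht_ids))
    expect_equal(tab$rate_percent,
                 floor(100 * 100 * tab$ht_count / tab$total_count + 0.5) / 100)
  }
  gen <- transfer_rates(calls, bgcs, profiles, group_by = "genus")
  ht_genera <- unique(vapply(ht_ids, function(b) {
    profiles[[bgcs[[b]]$genome_id]][["Genus"]]
  }, character(1)))
  expect_setequal(setdiff(gen$group, ht_genera), "Others")

  cls <- transfer_rates(calls, bgcs, profiles, group_by = "type-class")
  expect_setequal(cls$group, c("RiPP", "non-RiPP"))
})

test_that("contingency tests match their oracles and switch per expected counts", {
  even <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(contingency_test(even, "fisher")$p_value, 1)

  diag_ <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(contingency_test(diag_, "fisher")$p_value,
               oracle_fisher_2x2(diag_), tolerance = 1e-12)

  set.seed(151)
  for (i in 1:20) {
    tab <- matrix(sample(5:60, 4, TRUE), 2)
    res <- suppressWarnings(contingency_test(tab, "chi2"))
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
    f <- contingency_test(tab, "fisher")
    expect_equal(f$p_value, oracle_fisher_2x2(tab), tolerance = 1e-9)
  }

  small <- matrix(c(2, 50, 1, 60), 2)     # expected cell < 5 -> Fisher
  expect_equal(contingency_test(small, "auto")$method_used, "fisher")
  big <- matrix(c(30, 40, 50, 60), 2)
  expect_equal(contingency_test(big, "auto")$method_used, "chi2")

  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE), "chi2"),
               "zero margin")
  expect_error(contingency_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("donor-recipient matrices count calls at the chosen rank", {
  donor <- format_lineage(parse_lineage("Bacteria;Bacillota;C;O;F;G;S"))
  recip <- "d__Bacteria;p__Bacteroidota;c__;o__;f__;g__;s__"
  calls <- fake_calls(paste0("b", 1:4),
                      c("HTBGC", "HTBGC", "HTBGC", "HTBGC"),
                      donor = c(donor, donor, donor, "unclassified"),
                      recipient = recip)
  m <- donor_recipient_matrix(calls, rank = "Phylum")
  expect_equal(m["Bacillota", "Bacteroidota"], 3L)
  expect_equal(m["unclassified", "Bacteroidota"], 1L)

  empty <- donor_recipient_matrix(fake_calls("x", "not-HTBGC"))
  expect_true(all(empty == 0L))
})

test_that("F1 is stable across community scales (analysis-shape harness)", {
  out <- f1_across_scales(n_genomes_levels = c(8, 10), seeds = 1:3,
                          transfer_count = 2, families_per_phylum = 3,
                          genes_per_bgc = 6, gene_length = 300)
  expect_equal(nrow(out$f1_table), 6L)
  expect_true(is.na(out$kruskal_p) || (out$kruskal_p >= 0 && out$kruskal_p <= 1))
})
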