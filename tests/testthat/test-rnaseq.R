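test_that("read assignment follows the four-group rules", {
  expect_equal(assign_read(score_h = 90, nm_h = 1, mlen_h = 180), "human_only")
  expect_equal(assign_read(score_m = 90, nm_m = 1, mlen_m = 180), "mouse_only")
  expect_equal(assign_read(), "unaligned")
  expect_equal(assign_read(90, 1, 180, 90, 1, 180), "common")
  expect_equal(assign_read(90, 1, 180, 80, 1, 180), "human_only")
  expect_equal(assign_read(80, 1, 180, 90, 1, 180), "mouse_only")
  # score tie -> fewer mismatches wins
  expect_equal(assign_read(90, 1, 180, 90, 3, 180), "human_only")
  # score and mismatch tie -> longer match wins
  expect_equal(assign_read(90, 2, 150, 90, 2, 190), "mouse_only")
})

test_that("score tolerance widens the tie band", {
  expect_equal(assign_read(90, 1, 180, 87, 1, 180, tolerance = 5), "common")
  expect_equal(assign_read(90, 1, 180, 87, 2, 180, tolerance = 5), "human_only")
  expect_equal(assign_read(90, 1, 180, 80, 1, 180, tolerance = 5), "human_only")
  expect_error(assign_read(90, 1, -5, 90, 1, 180), "negative")
})

test_that("assignment recovers true origin on unambiguous synthetic pairs", {
  rp <- simulate_read_pairs(n_human = 200, n_mouse = 200, n_ambiguous = 50,
                            score_margin = 3, seed = 6)
  got <- assign_reads(rp, tolerance = 0)
  expect_true(all(got[rp$true_origin == "human"] == "human_only"))
  expect_true(all(got[rp$true_origin == "mouse"] == "mouse_only"))
  expect_true(all(got[rp$true_origin == "ambiguous"] == "common"))
})

test_that("quantification retains human-only and common pairs", {
  asn <- c("human_only", "mouse_only", "common", "unaligned", "human_only")
  expect_equal(retained_for_quantification(asn),
               c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_false(any(retained_for_quantification(rep("mouse_only", 5))))
  rp <- simulate_read_pairs(n_human = 300, n_mouse = 100, n_ambiguous = 100,
                            score_margin = 5, seed = 7)
  kept <- retained_for_quantification(assign_reads(rp))
  expect_equal(mean(kept), (300 + 100) / 500)
})

test_that("FPKM is counts per kilobase per million assigned reads", {
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(0, 1000, 1e6), 0)
  set.seed(10)
  counts <- rpois(20, 50); len <- sample(500:5000, 20)
  expect_equal(fpkm(counts, len, 2e6), fpkm(counts, len, 1e6) / 2)
})

test_that("BH adjustment matches hand examples and the brute-force oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(adj <= 1) && all(adj >= p - 1e-15))
    expect_equal(bh_adjust(adj) >= adj - 1e-12, rep(TRUE, length(adj)))
  }
})

test_that("DE filter applies the three criteria with strict inequalities", {
  genes <- data.frame(
    gene_id = c("BRINP3", "FOXP1", "edge", "lowfpkm", "notsig"),
    log2fc = c(log2(52.6), log2(0.005), 1.0, 3, 3),
    mean_fpkm = c(12, 8, 10, 0.5, 10),
    padj = c(3.8e-6, 9.0e-7, 1e-4, 1e-4, 0.2),
    stringsAsFactors = FALSE)
  out <- de_filter(genes)
  expect_equal(out$call,
               c("up", "down", "unchanged", "unchanged", "unchanged"))
})

test_that("DE filter computes padj from raw p and is permutation-stable", {
  set.seed(19)
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:30),
    log2fc = rnorm(30, 0, 2),
    mean_fpkm = runif(30, 0, 10),
    pvalue = runif(30)^2,
    stringsAsFactors = FALSE)
  out <- de_filter(genes)
  expect_equal(out$padj, bh_adjust(genes$pvalue))
  perm <- sample(30)
  out_perm <- de_filter(genes[perm, ])
  expect_equal(out_perm$call, out$call[perm])
})

test_that("responder grouping splits CR/MCR from the rest, disjointly", {
  models <- c("WT-16", "Rh-18", "RBD2", "RBD1", "BT-29", "G401")
  cats <- c("MCR", "CR", "MCR", "PR", "PR", "PD")
  g <- responder_grouping(models, cats)
  expect_setequal(g$good, c("WT-16", "Rh-18", "RBD2"))
  expect_setequal(g$poor, c("RBD1", "BT-29", "G401"))
  expect_length(intersect(g$good, g$poor), 0)
  expect_error(responder_grouping(models, rep("PD", 6)), "non-empty")
})

test_that("read-summary TSV reader fills alignment flags from missing metrics", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("read_id\tscore_h\tnm_h\tmlen_h\tscore_m\tnm_m\tmlen_m",
               "r1\t90\t1\t180\t\t\t",
               "r2\t90\t1\t180\t90\t1\t180"), path)
  df <- read_pair_summary(path)
  expect_equal(df$aligned_h, c(TRUE, TRUE))
  expect_equal(df$aligned_m, c(FALSE, TRUE))
  expect_equal(assign_reads(df), c("human_only", "common"))
})
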