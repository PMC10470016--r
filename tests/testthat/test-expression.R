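test_that("TPM normalizes each sample to one million", {
  one <- matrix(c(7, 950), 1, 2, dimnames = list("t1", c("s1", "s2")))
  expect_equal(unname(compute_tpm(one, lengths = 500)[1, ]), c(1e6, 1e6))

  # equal counts, lengths 1000 and 2000 -> TPM ratio 2:1
  two <- matrix(c(100, 100), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- compute_tpm(two, lengths = c(1000, 2000))
  expect_equal(tpm["a", 1] / tpm["b", 1], 2)
  expect_equal(unname(colSums(tpm)), 1e6)

  set.seed(3)
  m <- matrix(rpois(60, 50), 10, 6,
              dimnames = list(sprintf("t%d", 1:10), sprintf("s%d", 1:6)))
  len <- sample(200:2000, 10)
  tpm <- compute_tpm(m, lengths = len)
  expect_equal(unname(colSums(tpm)), rep(1e6, 6), tolerance = 1e-6)

  # permuting transcripts permutes outputs identically
  p <- sample(10)
  expect_equal(compute_tpm(m[p, ], lengths = len[p]), tpm[p, ])
})

test_that("FPKM follows the count/length/library-size formula", {
  m <- matrix(c(10, 999990), 2, 1, dimnames = list(c("a", "b"), "s1"))
  fpkm <- compute_fpkm(m, lengths = c(1000, 1000))
  expect_equal(fpkm["a", 1], 10)  # 10 * 1e9 / (1000 * 1e6)

  set.seed(4)
  m <- matrix(rpois(40, 100) + 1, 8, 5)
  rownames(m) <- sprintf("t%d", 1:8)
  len <- sample(300:3000, 8)
  f1 <- compute_fpkm(m, lengths = len)
  expect_equal(compute_fpkm(2 * m, lengths = len) / f1,
               matrix(1, 8, 5), ignore_attr = TRUE)
  # FPKM and TPM rank transcripts identically within a sample
  t1 <- compute_tpm(m, lengths = len)
  for (j in 1:5) expect_equal(order(f1[, j]), order(t1[, j]))
})

test_that("low-expression filter keeps transcripts reaching FPKM 1 anywhere", {
  f <- rbind(low = c(0.9, 0.9, 0.9), edge = c(1.0, 0, 0), hi = c(5, 2, 0.1))
  expect_setequal(filter_low_expression(f), c("edge", "hi"))

  set.seed(5)
  r <- matrix(runif(200, 0, 3), 40, 5,
              dimnames = list(sprintf("t%d", 1:40), NULL))
  expected <- character(0)
  for (i in 1:40)  # independent row scan
    if (any(r[i, ] >= 1)) expected <- c(expected, rownames(r)[i])
  expect_equal(filter_low_expression(r), expected)
})

test_that("differential expression labels follow the strict thresholds", {
  groups <- rep(c("A", "C"), each = 3)
  same <- matrix(rep(c(4, 5, 6), 2), 3, 6, byrow = FALSE)
  same <- rbind(t1 = c(4, 5, 6, 4, 5, 6))
  de <- differential_expression(same, groups)
  expect_equal(de$log2fc, 0)
  expect_equal(de$direction, "ns")

  # mean fold change exactly 2 on the pseudo-counted scale -> lfc = 1 -> ns
  edge <- rbind(t1 = c(6.9, 7, 7.1, 2.9, 3, 3.1))
  de <- differential_expression(edge, groups)
  expect_equal(de$log2fc, 1)
  expect_equal(de$direction, "ns")

  # swapping the group labels negates the fold change and swaps directions
  set.seed(6)
  m <- matrix(runif(60, 0, 100), 10, 6)
  rownames(m) <- sprintf("t%d", 1:10)
  d1 <- differential_expression(m, groups, p_cut = 0.5)
  d2 <- differential_expression(m, groups, treatment = "C", control = "A",
                                p_cut = 0.5)
  expect_equal(d1$log2fc, -d2$log2fc)
  swap <- c(up = "down", down = "up", ns = "ns")
  expect_equal(unname(swap[d1$direction]), d2$direction)

  expect_error(differential_expression(m[, 1:3], c("A", "C", "C")),
               "2 samples per group")
})

test_that("row-wise Welch p-values agree with stats::t.test", {
  set.seed(8)
  m <- matrix(rnbinom(80, mu = 200, size = 10), 10, 8)
  rownames(m) <- sprintf("t%d", 1:10)
  groups <- rep(c("A", "C"), each = 4)
  de <- differential_expression(m, groups)
  for (i in c(1, 4, 9)) {
    x <- log2(m[i, groups == "A"] + 1)
    y <- log2(m[i, groups == "C"] + 1)
    expect_equal(de$p[i], stats::t.test(x, y)$p.value)
  }
})

test_that("zero within-group variance in both groups yields p = 1", {
  m <- rbind(flat = c(5, 5, 5, 9, 9, 9), ok = c(1, 2, 3, 9, 7, 8))
  expect_warning(
    de <- differential_expression(m, rep(c("A", "C"), each = 3)),
    "zero within-group variance")
  expect_equal(de$p[de$transcript_id == "flat"], 1)
})

test_that("the DE caller is roughly calibrated under the null at n = 10", {
  cfg <- simulation_config(seed = 13, n_mrna = 1000, n_lncrna = 1000,
                           n_samples_per_group = 10, de_fraction = 0,
                           n_planted_triads = 0)
  ann <- generate_annotation(cfg)
  cc <- generate_counts(ann, cfg)
  de <- differential_expression(compute_fpkm(cc$expr), cc$expr$groups)
  # expected 0.001; allow generous Monte-Carlo + model-mismatch slack
  expect_lt(mean(de$p < 0.001), 0.005)
  expect_equal(sum(cc$truth$de), 0)
})

test_that("planted DE is recovered with monotone sensitivity in effect size", {
  sens_at <- function(lfc) {
    cfg <- simulation_config(seed = 17, n_mrna = 150, n_lncrna = 150,
                             n_samples_per_group = 5, de_fraction = 0.2,
                             lfc_location = lfc, nb_dispersion = 0.1,
                             n_planted_triads = 0)
    ann <- generate_annotation(cfg)
    cc <- generate_counts(ann, cfg)
    de <- differential_expression(compute_fpkm(cc$expr), cc$expr$groups)
    truth_de <- cc$truth$direction != "ns"
    called <- de$direction != "ns"
    fdr <- if (sum(called) == 0) 0 else sum(called & !truth_de) / sum(called)
    c(sens = sum(called & truth_de) / sum(truth_de), fdr = fdr)
  }
  r1 <- sens_at(1); r2 <- sens_at(2); r3 <- sens_at(4)
  expect_gt(r2[["sens"]], 0.5)
  expect_lte(r1[["sens"]], r2[["sens"]])
  expect_lte(r2[["sens"]], r3[["sens"]])
  expect_lt(r2[["fdr"]], 0.1)
})

test_that("sample diagnostics match brute-force correlation and order PCs", {
  set.seed(9)
  m <- matrix(rnbinom(300, mu = 100, size = 5), 50, 6)
  rownames(m) <- sprintf("t%d", 1:50)
  colnames(m) <- sprintf("s%d", 1:6)
  diag_ <- sample_diagnostics(m)
  lf <- log2(m + 1)
  for (i in 1:6) for (j in 1:6) {  # independent pairwise formula
    x <- lf[, i]; y <- lf[, j]
    r_manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(diag_$r[i, j], r_manual)
  }
  dup <- cbind(m, m[, 1])
  r2 <- sample_diagnostics(dup)$r2
  expect_equal(r2[1, 7], 1)
  shares <- diag_$pca$variance_share
  expect_true(all(diff(shares) <= 1e-12))
})

test_that("DE summaries add up within and across strata", {
  de <- data.frame(direction = c("up", "up", "down", "ns", "up", "down"))
  cls <- c("lncRNA", "lncRNA", "lncRNA", "mRNA", "mRNA", "mRNA")
  status <- c("known", "novel", "known", "known", "novel", "novel")
  s <- summarize_de(de, cls, status)
  expect_equal(s$total, s$up + s$down)
  lnc <- s[s$class == "lncRNA" & s$status == "all", ]
  expect_equal(lnc$up, 2); expect_equal(lnc$down, 1); expect_equal(lnc$total, 3)
  grand <- s[s$class == "all", ]
  expect_equal(grand$total, 5)

  empty <- summarize_de(data.frame(direction = character(0)))
  expect_true(all(empty$total == 0))
})

test_that("2^-ddCt reproduces closed-form and spreadsheet-style computation", {
  groups <- c("A", "A", "C", "C")
  ct <- rbind(ref = c(20, 21, 20, 21), tgt = c(20, 21, 20, 21))
  expect_equal(unname(ddct(ct, "ref", groups)["tgt", ]), rep(1, 4))

  # ddCt of -1 doubles relative expression
  ct2 <- rbind(ref = c(20, 20, 20, 20), tgt = c(24, 24, 25, 25))
  expect_equal(unname(ddct(ct2, "ref", groups)["tgt", ]), c(2, 2, 1, 1))

  set.seed(10)
  ct3 <- matrix(runif(12, 18, 30), 3, 4,
                dimnames = list(c("ref", "g1", "g2"), NULL))
  out <- ddct(ct3, "ref", groups)
  for (g in c("g1", "g2")) {   # step-by-step recomputation
    dct <- ct3[g, ] - ct3["ref", ]
    dd <- dct - mean(dct[groups == "C"])
    expect_equal(unname(out[g, ]), unname(2^(-dd)))
  }
  expect_error(ddct(ct3, "absent", groups), "not present")
})
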