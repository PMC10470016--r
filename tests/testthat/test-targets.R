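test_that("cis windows are asymmetric and oriented by the lncRNA strand", {
  lnc <- rec("L", 100000, 101000, "+")
  paired <- cis_targets(lnc, rec("G1", 94000, 95000))   # 5 kb upstream
  expect_equal(nrow(paired), 1)
  expect_equal(paired$distance, -5000)

  expect_equal(nrow(cis_targets(lnc, rec("G2", 84000, 85000))), 0) # 15 kb up
  down15 <- cis_targets(lnc, rec("G3", 116000, 117000))            # 15 kb down
  expect_equal(nrow(down15), 1)
  expect_equal(down15$distance, 15000)

  # minus strand: upstream lies at higher coordinates
  lncm <- rec("Lm", 100000, 101000, "-")
  expect_equal(nrow(cis_targets(lncm, rec("G4", 84000, 85000))), 1)  # 15kb 3'
  expect_equal(nrow(cis_targets(lncm, rec("G5", 116000, 117000))), 0) # 15kb 5'
  expect_equal(cis_targets(lncm, rec("G6", 106000, 107000))$distance, -5000)

  # overlap reports distance 0
  expect_equal(cis_targets(lnc, rec("G7", 100500, 102000))$distance, 0)
  expect_error(cis_targets(rec("L", 1, 2, "*"), rec("G", 5, 6)), "strand")
})

test_that("cis pairing equals the brute-force interval scan at random", {
  set.seed(21)
  lnc <- do.call(rbind, lapply(1:20, function(i) {
    s <- sample(1:5e5, 1)
    rec(paste0("L", i), s, s + sample(200:3000, 1), sample(c("+", "-"), 1))
  }))
  genes <- do.call(rbind, lapply(1:200, function(i) {
    s <- sample(1:5e5, 1)
    rec(paste0("G", i), s, s + sample(200:8000, 1), sample(c("+", "-"), 1))
  }))
  got <- cis_targets(lnc, genes)
  expect_setequal(paste(got$lncrna_id, got$gene_id), brute_cis(lnc, genes))

  # enlarging the windows never removes pairs
  wider <- cis_targets(lnc, genes, up_window = 15000, down_window = 30000)
  expect_true(all(paste(got$lncrna_id, got$gene_id) %in%
                  paste(wider$lncrna_id, wider$gene_id)))
})

test_that("duplex energy scores contiguous Watson-Crick helices", {
  # perfect 30-nt GC-rich duplex: sum of 29 published stack terms << -30
  set.seed(22)
  s <- paste(sample(c("G", "C", "A", "U"), 30, TRUE, prob = c(.4, .4, .1, .1)),
             collapse = "")
  e <- duplex_energy(s, revcomp_rna(s))
  stacks <- c(AA = -0.93, UU = -0.93, AU = -1.10, UA = -1.33, CU = -2.08,
              AG = -2.08, CA = -2.11, UG = -2.11, GU = -2.24, AC = -2.24,
              GA = -2.35, UC = -2.35, CG = -2.36, GG = -3.26, CC = -3.26,
              GC = -3.42)
  steps <- substring(s, 1:29, 2:30)
  expect_equal(e, sum(stacks[steps]), ignore_attr = TRUE)
  expect_lt(e, -30)

  expect_equal(duplex_energy("AAAA", "AAAA"), 0)
  expect_equal(duplex_energy("ACGUACGU", "ACGUACGU"),
               duplex_energy("ACGUACGU", "ACGUACGU"))
  expect_error(duplex_energy("ACGX", "ACGU"), "non-nucleotide")

  # symmetry on random sequences
  for (i in 1:20) {
    a <- random_rna(25); b <- random_rna(25)
    expect_equal(duplex_energy(a, b), duplex_energy(b, a))
  }

  # brute-force oracle: enumerate every antiparallel pairing frame and
  # every contiguous complementary run within it
  brute_energy <- function(a, b) {
    av <- strsplit(chartr("T", "U", a), "")[[1]]
    bv <- strsplit(chartr("T", "U", b), "")[[1]]
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    best <- 0
    for (i in seq_along(av)) for (j in seq_along(bv)) {
      # helix starting at pair (i, j), extending (i+1, j-1), ...
      e <- 0
      k <- 0
      while (i + k <= length(av) && j - k >= 1 &&
             av[i + k] == comp[[bv[j - k]]]) {
        if (k > 0) {
          e <- e + stacks[[paste0(av[i + k - 1], av[i + k])]]
          best <- min(best, e)
        }
        k <- k + 1
      }
    }
    best
  }
  set.seed(23)
  for (i in 1:15) {
    a <- random_rna(15); b <- random_rna(15)
    expect_equal(duplex_energy(a, b), brute_energy(a, b))
  }
})

test_that("trans targets need energy < -30 outside the cis window", {
  lnc <- rec("L", 100000, 101000, "+")
  far <- rec("G", 400000, 401000, "+")
  near <- rec("N", 103000, 104000, "+")
  set.seed(24)
  probe <- paste(sample(c("G", "C"), 40, TRUE), collapse = "")
  seqs <- c(L = probe, G = chartr("ACGU", "UGCA",
                                  paste(rev(strsplit(probe, "")[[1]]),
                                        collapse = "")),
            N = chartr("ACGU", "UGCA",
                       paste(rev(strsplit(probe, "")[[1]]), collapse = "")))
  tt <- trans_targets(lnc, rbind(far, near), sequences = seqs)
  expect_equal(tt$gene_id, "G")   # the cis-window copy is excluded
  expect_lt(tt$energy, -30)

  # boundary: exactly -30 is excluded (strict <)
  en <- data.frame(lncrna_id = "L", gene_id = "G", energy = -30)
  expect_equal(nrow(trans_targets(lnc, far, energies = en)), 0)
  en$energy <- -30.01
  expect_equal(nrow(trans_targets(lnc, far, energies = en)), 1)

  # no (l, g) pair is both cis and trans on synthetic data
  study <- small_study(seed = 3)
  tx <- study$ann$transcripts
  lncs <- tx[tx$biotype == "lncRNA", ][1:8, ]
  genes <- tx[tx$biotype == "mRNA", ][1:15, ]
  en_all <- expand.grid(lncrna_id = lncs$transcript_id,
                        gene_id = genes$transcript_id,
                        stringsAsFactors = FALSE)
  en_all$energy <- -100
  trans <- trans_targets(lncs, genes, energies = en_all)
  cis <- cis_targets(lncs, genes)
  expect_length(intersect(paste(trans$lncrna_id, trans$gene_id),
                          paste(cis$lncrna_id, cis$gene_id)), 0)
})

test_that("coexpression targets require both signed coefficients >= 0.6", {
  x <- rbind(l1 = c(1, 2, 3, 4, 5, 6))
  same <- rbind(g1 = c(2, 4, 6, 8, 10, 12))
  anti <- rbind(g2 = c(6, 5, 4, 3, 2, 1))
  hit <- coexpression_targets(x, same)
  expect_equal(hit$gene_id, "g1")
  expect_equal(hit$r_pearson, 1)
  expect_equal(hit$r_spearman, 1)
  expect_equal(nrow(coexpression_targets(x, anti)), 0)
  expect_equal(nrow(coexpression_targets(x, anti, unsigned = TRUE)), 1)

  set.seed(25)
  lm_ <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("l", 1:10), NULL))
  gm <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("g", 1:10), NULL))
  got <- coexpression_targets(lm_, gm)
  expected <- character(0)
  for (i in 1:10) for (j in 1:10) {  # direct formula oracle
    rp <- cor(lm_[i, ], gm[j, ])
    rs <- cor(rank(lm_[i, ]), rank(gm[j, ]))
    if (rp >= 0.6 && rs >= 0.6)
      expected <- c(expected, paste(rownames(lm_)[i], rownames(gm)[j]))
  }
  expect_setequal(paste(got$lncrna_id, got$gene_id), expected)

  flat <- rbind(l1 = rep(2, 6))
  expect_warning(out <- coexpression_targets(flat, same), "zero-variance")
  expect_equal(nrow(out), 0)
})

test_that("overlap classes follow the containment-by-strand grid", {
  gene <- rec("G", 1000, 5000, "+")
  expect_equal(classify_overlap(rec("L", 2000, 3000, "+"), gene), "overlap")
  expect_equal(classify_overlap(rec("L", 2000, 3000, "-"), gene),
               "anti-overlap")
  expect_equal(classify_overlap(rec("L", 4500, 6000, "+"), gene),
               "incomplete")
  # lncRNA straddling the gene 3' end on the opposite strand
  expect_equal(classify_overlap(rec("L", 4500, 6000, "-"), gene),
               "anti-incomplete")
  expect_equal(classify_overlap(rec("L", 6000, 7000, "+"), gene), "none")
  expect_equal(classify_overlap(rec("L", 1, 2, "+", "chr2"), gene), "none")

  # exhaustive toy enumeration against an independent truth table
  spans <- list(inside = c(2000, 3000), covers = c(500, 6000),
                left = c(500, 1500), right = c(4500, 6000),
                away = c(9000, 9500))
  for (nm in names(spans)) for (st in c("+", "-")) {
    l <- rec("L", spans[[nm]][1], spans[[nm]][2], st)
    same <- st == "+"
    expected <- if (nm == "away") "none"
    else if (nm %in% c("inside", "covers")) {
      if (same) "overlap" else "anti-overlap"
    } else {
      if (same) "incomplete" else "anti-incomplete"
    }
    expect_equal(classify_overlap(l, gene), expected)
  }
})

test_that("synthetic cis placement yields at least as many pairs as lncRNAs", {
  cfg <- simulation_config(seed = 31, n_mrna = 40, n_lncrna = 30,
                           cis_fraction = 1, overlap_fraction = 0,
                           n_planted_triads = 0)
  ann <- generate_annotation(cfg)
  tx <- ann$transcripts
  lncs <- tx[tx$biotype == "lncRNA", ]
  genes <- tx[tx$biotype == "mRNA", ]
  pairs <- cis_targets(lncs, genes)
  expect_gte(nrow(pairs), length(unique(pairs$lncrna_id)))
  expect_setequal(unique(pairs$lncrna_id), lncs$transcript_id)
})
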