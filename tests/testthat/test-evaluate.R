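# Z-scores, metagene profiles, lambda, confusion metrics, binned PR and
# the CpG analyses.

test_that("Z-scoring normalises to mean 0 / sd 1 and is affine-invariant", {
  tr <- manual_track(c(rep(NA, 10), rep(c(0, 1), 50), rep(NA, 10)))
  z <- zscore_track(tr)
  zd <- z$scores[!is.na(z$scores)]
  expect_setequal(round(zd, 10), round(c(-1, 1) * sqrt(99 / 100), 10))
  withr::with_seed(3, {
    y <- runif(500)
    t1 <- manual_track(y)
    t2 <- manual_track(3.7 * y - 2)          # affine transform
    z1 <- zscore_track(t1)$scores
    z2 <- zscore_track(t2)$scores
    expect_lt(max(abs(z1 - z2)), 1e-10)
    expect_lt(abs(mean(z1)), 1e-6)
    expect_lt(abs(stats::sd(z1) - 1), 1e-6)
  })
  expect_error(zscore_track(manual_track(rep(0.5, 100))), "constant")
  expect_error(zscore_track(manual_track(c(NA, 0.5, NA))), "at least 2")
})

test_that("metagene rows average correctly and respect strand", {
  z <- structure(manual_track(rep(2, 500)), class = c("zscore_track",
                                                      "prediction_track"))
  p1 <- metagene_profile(z, make_gss("chrT", 250), half_width = 100)
  expect_equal(unique(p1$S), 2)
  expect_length(p1$S, 201L)
  # rows v and -v cancel
  z2 <- manual_track(c(seq(-1, 1, length.out = 300), seq(1, -1,
                                                         length.out = 300)))
  p2 <- metagene_profile(z2, make_gss("chrT", c(150, 449)), half_width = 50)
  expect_lt(max(abs(p2$S)), 0.05)
  # a minus-strand row is reversed
  zr <- manual_track(seq(0, 1, length.out = 401))
  pf <- metagene_profile(zr, make_gss("chrT", 200, "+"), half_width = 100)
  pm <- metagene_profile(zr, make_gss("chrT", 200, "-"), half_width = 100)
  expect_equal(pm$S, rev(pf$S))
  # edge GSS are excluded and reported
  expect_error(metagene_profile(zr, make_gss("chrT", 5), half_width = 100),
               "edge")
})

test_that("profiles are invariant under a reverse-complement flip of the data", {
  withr::with_seed(11, y <- runif(2000))
  gss <- make_gss("chrT", c(500, 1200), c("+", "-"))
  p <- metagene_profile(manual_track(y), gss, half_width = 200)
  # mirror the track and remap coordinates/strands
  y2 <- rev(y)
  gss2 <- make_gss("chrT", 2000 - 1 - gss$position, c("-", "+"))
  p2 <- metagene_profile(manual_track(y2), gss2, half_width = 200)
  expect_equal(p2$S, p$S)
})

test_that("lambda equals the brute-force pipeline on random data", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      y <- runif(3000)
      pos <- sample(600:2400, 8)
      strands <- sample(c("+", "-"), 8, TRUE)
      lam <- evaluate_lambda(manual_track(y),
                             make_gss("chrT", pos, strands),
                             r = 400, half_width = 500)
      want <- brute_force_lambda(y, pos, strands, hw = 500, r = 400)
      expect_lt(abs(lam$lambda - want), 1e-10)
    }
  })
})

test_that("lambda handles null and indicator metagene curves", {
  prof <- structure(list(matrix = NULL, offsets = -5000:5000,
                         S = rep(0, 10001), n_gss_used = 1L,
                         n_excluded = 0L, half_width = 5000L),
                    class = "metagene_profile")
  expect_equal(lambda_score(prof)$lambda, 0)
  # window is offsets -200..199: 399 of its 400 entries inside the peak
  prof$S <- as.numeric(abs(-5000:5000) < 200)
  expect_equal(lambda_score(prof, r = 400)$lambda, 399 / 400)
  expect_error(lambda_score(prof, r = 401), "even")
  expect_error(lambda_score(prof, r = 20000), "exceeds")
})

test_that("confusion metrics match hand-computed counts and flag degeneracy", {
  y <- c(rep(1, 50), rep(0, 100))
  sc <- c(rep(1, 45), rep(0, 5), rep(1, 10), rep(0, 90))
  cm <- confusion_metrics(y, sc)
  expect_equal(c(cm$TP, cm$FN, cm$FP, cm$TN), c(45, 5, 10, 90))
  expect_equal(cm$Sn, 0.9)
  expect_equal(cm$Sp, 0.9)
  mcc_oracle <- (45 * 90 - 10 * 5) /
    sqrt((45 + 10) * (45 + 5) * (90 + 10) * (90 + 5))
  expect_equal(cm$MCC, mcc_oracle)
  # perfect predictor
  cmp <- confusion_metrics(y, y)
  expect_equal(c(cmp$Sn, cmp$Sp, cmp$MCC), c(1, 1, 1))
  # all-negative predictor: Sn = 0, MCC flagged undefined
  cma <- confusion_metrics(y, rep(0, 150))
  expect_equal(cma$Sn, 0)
  expect_true(is.na(cma$MCC))
  expect_true(all(c("MCC", "precision") %in% cma$undefined))
  expect_error(confusion_metrics(numeric(0), numeric(0)), "empty")
})

test_that("MCC stays within [-1, 1] whenever defined", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      y <- rbinom(60, 1, runif(1, 0.2, 0.8))
      sc <- runif(60)
      cm <- confusion_metrics(y, sc, threshold = runif(1))
      if (!is.na(cm$MCC)) expect_true(cm$MCC >= -1 && cm$MCC <= 1)
    }
  })
})

test_that("binned precision-recall matches exhaustive enumeration", {
  # 6 bins of 600 bp; GSS in bins 2 and 5
  scores <- rep(NA_real_, 3600)
  scores[300 + 0:5 * 600] <- c(0.1, 0.9, 0.2, 0.3, 0.8, 0.4)
  tr <- manual_track(scores)
  gss <- make_gss("chrT", c(700, 2500))
  pr <- binned_precision_recall(tr, gss, bin_width = 600,
                                thresholds = c(0, 0.5, 0.95))
  # t = 0: all 6 bins called, 2 true -> precision 1/3, recall 1
  expect_equal(pr$precision[1], 2 / 6)
  expect_equal(pr$recall[1], 1)
  # t = 0.5: bins 2 and 5 called, both true
  expect_equal(pr$precision[2], 1)
  expect_equal(pr$recall[2], 1)
  # t above the maximum: nothing called, precision undefined
  expect_equal(pr$n_called[3], 0)
  expect_true(is.na(pr$precision[3]))
  expect_equal(pr$recall[3], 0)
})

test_that("CpG counting includes overlapping dinucleotide starts", {
  pad <- paste(rep("A", 295), collapse = "")
  expect_equal(cpg_count(paste0("CGCG", pad)), 2L)
  expect_equal(cpg_count(paste(rep("A", 299), collapse = "")), 0L)
  withr::with_seed(41, {
    s <- paste(sample(c("A", "C", "G", "T"), 299, TRUE), collapse = "")
    ch <- strsplit(s, "")[[1]]
    oracle <- 0L
    for (i in 1:298) if (ch[i] == "C" && ch[i + 1] == "G")
      oracle <- oracle + 1L
    expect_equal(cpg_count(s), oracle)
  })
})

test_that("CpG classes split at the count-distribution quantiles", {
  # synthetic GSS whose windows have strictly increasing CpG counts
  width <- 299L
  n <- 100L
  seqs <- vapply(seq_len(n), function(i) {
    body <- c(rep("CG", i), rep("AT", (width + 1) %/% 2))
    substr(paste(body, collapse = ""), 1, width)
  }, character(1))
  genome <- structure(
    c(chr1 = paste(c(seqs, paste(rep("A", 200), collapse = "")),
                   collapse = "")), class = "gss_genome")
  pos <- (seq_len(n) - 1L) * width + 149L
  gss <- make_gss("chr1", pos)
  cc <- cpg_classes(gss, genome)
  expect_equal(nrow(cc$gss), n)
  expect_true(all(table(cc$gss$cpg_class) > 0))
  expect_lt(cc$bounds[["lower"]], cc$bounds[["upper"]])
  expect_true(all(cc$gss$cpg_count[cc$gss$cpg_class == "low"] <
                    cc$bounds[["lower"]]))
  expect_true(all(cc$gss$cpg_count[cc$gss$cpg_class == "high"] >=
                    cc$bounds[["upper"]]))
  # permuting GSS order leaves per-GSS assignments unchanged
  perm <- withr::with_seed(2, sample(n))
  cc2 <- cpg_classes(gss[perm, ], genome)
  merged <- merge(cc$gss, cc2$gss, by = "position")
  expect_identical(merged$cpg_class.x, merged$cpg_class.y)
})

test_that("CpG-enriched GSS dominate the high class", {
  b <- tiny_bundle(seed = 15L, n_chroms = 1L, chrom_length = 60000L,
                   n_gss = 10L, cpg_enrichment = 6)
  depleted <- tiny_bundle(seed = 16L, n_chroms = 1L, chrom_length = 60000L,
                          n_gss = 10L, cpg_enrichment = 1)
  names(depleted$genome) <- "chr2"
  depleted$gss$chrom <- "chr2"
  genome <- structure(c(b$genome, depleted$genome), class = "gss_genome")
  gss <- rbind(b$gss, depleted$gss)
  cc <- cpg_classes(gss, genome)
  high_set <- cc$gss[cc$gss$cpg_class == "high", ]
  expect_gt(mean(high_set$chrom == "chr1"), 0.8)
})

test_that("the sliding CpG track equals per-window recounts", {
  withr::with_seed(51, {
    s <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  })
  tr <- cpg_baseline_track(s, chrom = "chrT")
  expect_equal(sum(!is.na(tr$scores)), 800L - 298L)
  starts <- c(0L, 7L, 250L, 501L)
  direct <- cpg_count(substring(s, starts + 1, starts + 299))
  expect_equal(tr$scores[starts + 150L], as.numeric(direct))
  # degenerate all-A chromosome: constant zero counts, Z-score refuses
  tra <- cpg_baseline_track(paste(rep("A", 400), collapse = ""))
  expect_true(all(tra$scores[!is.na(tra$scores)] == 0))
  expect_error(zscore_track(tra), "constant")
})
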