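# Window extraction, one-hot encoding, negative sampling and dataset
# assembly.

test_that("one-hot encoding follows the A,T,C,G unit-vector convention", {
  m <- one_hot(paste(rep("A", 299), collapse = ""))
  expect_equal(m[, 1], c(A = 1, T = 0, C = 0, G = 0))
  s <- paste(c("N", sample(c("A", "C", "G", "T"), 298, TRUE)), collapse = "")
  m2 <- one_hot(s)
  expect_equal(unname(m2[, 1]), rep(0, 4))            # N column is zero
  expect_equal(unname(colSums(m2)), c(0, rep(1, 298)))
  expect_error(one_hot("ACGT"), "length")
  expect_error(one_hot(paste(rep("Q", 299), collapse = "")), "outside")
})

test_that("decoding inverts encoding", {
  withr::with_seed(1, {
    for (i in 1:5) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), 299, TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
      expect_identical(decode_one_hot(one_hot(s)), s)
    }
  })
})

test_that("positive windows are centred, boundary-checked and oriented", {
  seqs <- paste(random_dna(1, width = 700), collapse = "")
  genome <- structure(c(chr1 = seqs), class = "gss_genome")
  gss <- data.frame(chrom = "chr1", position = c(149L, 400L, 100L, 650L),
                    strand = c("+", "-", "+", "+"),
                    gene_name = letters[1:4], tx_class = "mRNA",
                    accession = NA)
  expect_warning(pw <- extract_positive_windows(genome, gss), "end")
  expect_equal(nrow(pw$windows), 2L)                  # 100 and 650 skipped
  expect_equal(pw$windows$start[1], 0L)               # boundary case
  expect_equal(pw$windows$end[1], 299L)
  # minus-strand sequence equals an independent reverse complement
  fwd_slice <- substring(seqs, 400 - 149 + 1, 400 + 149 + 1)
  expect_identical(pw$seqs[2], oracle_revcomp(fwd_slice))
  expect_true(all(pw$windows$label == 1L))
})

test_that("N-heavy positive windows are dropped", {
  s <- paste(c(rep("N", 200), random_dna(1, 500)), collapse = "")
  genome <- structure(c(chr1 = s), class = "gss_genome")
  gss <- data.frame(chrom = "chr1", position = c(160L, 450L), strand = "+",
                    gene_name = "x", tx_class = "mRNA", accession = NA)
  expect_warning(pw <- extract_positive_windows(genome, gss), "N dropped")
  expect_equal(nrow(pw$windows), 1L)
})

test_that("negative sampling returns the exact count with no GSS overlap", {
  b <- tiny_bundle(seed = 2L)
  neg <- sample_negative_windows(b$genome, b$gss, count = 400L, seed = 9L)
  expect_equal(nrow(neg$windows), 400L)
  expect_true(all(neg$windows$label == 0L))
  # exhaustive overlap check
  for (ch in unique(neg$windows$chrom)) {
    gp <- b$gss$position[b$gss$chrom == ch]
    w <- neg$windows[neg$windows$chrom == ch, ]
    hits <- outer(w$start, gp, function(s, p) p >= s & p < s + 299)
    expect_false(any(hits))
  }
  # determinism
  neg2 <- sample_negative_windows(b$genome, b$gss, count = 400L, seed = 9L)
  expect_identical(neg, neg2)
})

test_that("negative sampling works on a GSS-free genome", {
  genome <- structure(c(chr1 = paste(random_dna(1, 5000), collapse = "")),
                      class = "gss_genome")
  empty <- data.frame(chrom = character(0), position = integer(0),
                      strand = character(0))
  neg <- sample_negative_windows(genome, empty, count = 50L, seed = 1L)
  expect_equal(nrow(neg$windows), 50L)
  expect_true(all(neg$windows$start >= 0 &
                    neg$windows$start + 299 <= 5000))
})

test_that("datasets keep the exact Q ratio, holdout and stratification", {
  b <- tiny_bundle(seed = 4L, n_chroms = 3L, chrom_length = 30000L,
                   n_gss = 8L)
  ds <- build_dataset(b$genome, b$gss, Q = 10, holdout_chroms = "chr3",
                      seed = 21L)
  P <- sum(ds$y == 1)
  expect_equal(P, 16L)                       # 2 usable chromosomes x 8 GSS
  expect_equal(sum(ds$y == 0), 10L * P)
  expect_false(any(ds$windows$chrom == "chr3"))
  # each partition's negative count within one sample of Q x positives
  for (sp in c("train", "validation", "test")) {
    part <- ds$windows$label[ds$windows$split == sp]
    expect_lte(abs(sum(part == 0) - 10 * sum(part == 1)), 1)
  }
  expect_equal(dim(ds$X), c(4L, 299L, 11L * P))
  # determinism: identical object for the same seed
  ds2 <- build_dataset(b$genome, b$gss, Q = 10, holdout_chroms = "chr3",
                       seed = 21L)
  expect_identical(ds, ds2)
  expect_error(build_dataset(b$genome, b$gss, Q = 0.5), "Q must be >= 1")
})

test_that("sample sets survive a save/load round trip with sidecars", {
  b <- tiny_bundle(seed = 6L)
  ds <- build_dataset(b$genome, b$gss, Q = 2, seed = 3L)
  f <- withr::local_tempfile(fileext = ".rds")
  save_sample_set(ds, f)
  expect_identical(load_sample_set(f), ds)
  expect_true(file.exists(paste0(f, ".bed")))
  expect_true(file.exists(paste0(f, ".json")))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$Q, 2)
  expect_equal(meta$n, length(ds$y))
})

test_that("dataset size arithmetic matches its definition", {
  d <- dataset_dimensions(100, 10)
  expect_equal(d$n_negative, 1000)
  expect_equal(d$n_total, 1100)
  expect_equal(d$negative_bases, 1000 * 299)
})
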