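# FASTA / refGene / BED reading and GSS extraction.

write_temp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("FASTA reading uppercases and maps ambiguity codes to N", {
  f <- write_temp_fasta(c(">chrA desc", "acgtn", ">chrB", "ACGR", "tt"))
  g <- read_genome_fasta(f)
  expect_named(g, c("chrA", "chrB"))
  expect_identical(unname(unclass(g)), c("ACGTN", "ACGNTT"))
  expect_identical(unname(nchar(g)), c(5L, 6L))
})

test_that("FASTA reading rejects empty and malformed input", {
  f0 <- withr::local_tempfile(fileext = ".fa")
  file.create(f0)
  expect_error(read_genome_fasta(f0), "empty")
  f1 <- write_temp_fasta(c("ACGT", ">chr1", "ACGT"))
  expect_error(read_genome_fasta(f1), "line 1")
  expect_error(read_genome_fasta(file.path(tempdir(), "nope.fa")),
               "not found")
})

test_that("synthetic genomes round-trip through FASTA", {
  b <- tiny_bundle(seed = 3L, n_chroms = 3L, chrom_length = 15000L,
                   n_gss = 2L)
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(b$genome, f)
  back <- read_genome_fasta(f)
  expect_identical(unclass(back), unclass(b$genome))
})

make_refgene_lines <- function(with_bin = TRUE) {
  row <- function(name, chrom, strand, s, e, sym) {
    base <- c(name, chrom, strand, s, e, s, e, "1",
              paste0(s, ","), paste0(e, ","), "0", sym, "cmpl", "cmpl", "0,")
    if (with_bin) base <- c("585", base)
    paste(base, collapse = "\t")
  }
  c(row("NM_000546", "chr1", "+", 100, 500, "TP53"),
    row("NR_003287", "chr1", "-", 900, 1500, "RNA45S5"),
    row("XM_011545", "chr2", "+", 250, 700, "DEMO"))
}

test_that("refGene parsing handles both dialects and gzip", {
  f16 <- withr::local_tempfile(fileext = ".txt")
  writeLines(make_refgene_lines(TRUE), f16)
  f15 <- withr::local_tempfile(fileext = ".txt")
  writeLines(make_refgene_lines(FALSE), f15)
  fgz <- withr::local_tempfile(fileext = ".txt.gz")
  con <- gzfile(fgz, "w"); writeLines(make_refgene_lines(TRUE), con); close(con)

  r16 <- read_refgene(f16)
  expect_identical(r16$name, c("NM_000546", "NR_003287", "XM_011545"))
  expect_identical(r16$txStart, c(100L, 900L, 250L))
  expect_identical(r16$txEnd, c(500L, 1500L, 700L))
  expect_identical(read_refgene(f15), r16)
  expect_identical(read_refgene(fgz), r16)
})

test_that("refGene parsing reports bad column counts and strands", {
  fbad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a\tb\tc"), fbad)
  expect_error(read_refgene(fbad), "columns")
  fstrand <- withr::local_tempfile(fileext = ".txt")
  writeLines(sub("\\t\\+\\t", "\t.\t", make_refgene_lines(TRUE)[1]), fstrand)
  expect_error(read_refgene(fstrand), "strand")
})

test_that("GSS extraction applies the strand conventions and deduplicates", {
  rows <- data.frame(
    name = c("NM_1", "NM_2", "NR_3", "NM_4"),
    chrom = c("chr1", "chr1", "chr1", "chr1"),
    strand = c("+", "+", "-", "-"),
    txStart = c(1000L, 1000L, 300L, 250L),
    txEnd = c(2000L, 2500L, 2000L, 2000L),
    name2 = c("g1", "g1", "g2", "g3"))
  gss <- extract_gss(rows)
  # two "+" isoforms share txStart -> one record; "-" GSS at txEnd - 1
  expect_equal(nrow(gss), 2L)
  expect_equal(gss$position[gss$strand == "+"], 1000L)
  expect_equal(gss$position[gss$strand == "-"], 1999L)
  expect_identical(gss$tx_class, c("mRNA", "ncRNA"))
  # strand partition
  expect_equal(sum(gss$strand == "+") + sum(gss$strand == "-"), nrow(gss))
  # idempotent under re-extraction
  rewrapped <- data.frame(name = gss$accession, chrom = gss$chrom,
                          strand = gss$strand, txStart = gss$position,
                          txEnd = gss$position + 1L, name2 = gss$gene_name)
  rewrapped$txStart[rewrapped$strand == "-"] <- 0L
  rewrapped$txEnd[rewrapped$strand == "-"] <-
    gss$position[gss$strand == "-"] + 1L
  expect_equal(nrow(extract_gss(rewrapped)), nrow(gss))
})

test_that("out-of-bounds GSS are dropped with a warning, not an error", {
  genome <- structure(c(chr1 = paste(rep("A", 500), collapse = "")),
                      class = "gss_genome")
  rows <- data.frame(name = c("NM_1", "NM_2"), chrom = "chr1",
                     strand = "+", txStart = c(100L, 900L),
                     txEnd = c(300L, 950L), name2 = c("a", "b"))
  expect_warning(gss <- extract_gss(rows, genome), "dropped")
  expect_equal(nrow(gss), 1L)
})

test_that("accession prefixes decide the transcript class", {
  expect_identical(tx_class_from_accession(c("NM_1", "XM_2", "NR_3", "XR_4")),
                   c("mRNA", "mRNA", "ncRNA", "ncRNA"))
  expect_warning(cls <- tx_class_from_accession("ENST0001"), "ncRNA")
  expect_identical(cls, "ncRNA")
})

test_that("GSS records round-trip through BED", {
  b <- tiny_bundle(seed = 5L)
  f <- withr::local_tempfile(fileext = ".bed")
  write_gss_bed(b$gss, f)
  back <- read_gss_bed(f)
  key <- function(d) d[order(d$chrom, d$position, d$strand),
                       c("chrom", "position", "strand")]
  expect_equal(key(back), key(b$gss), ignore_attr = TRUE)
})
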