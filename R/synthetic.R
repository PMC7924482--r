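# Seeded synthetic genomes with planted GSS: i.i.d. background sequence,
# promoter-like consensus motifs written (with substitution noise) at fixed
# offsets around each planted GSS, and a first-order CpG-enrichment chain
# in the +/-149 bp neighbourhood so CpG-based baselines have a real signal.
# Desk-scale stand-in for real genome + refGene inputs; every output is
# reproducible from the seed.

#' Specification of a synthetic genome
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_gss Planted GSS per chromosome.
#' @param base_freqs Background base frequencies (named A,C,G,T; uniform by
#'   default).
#' @param motif Consensus motif written near each GSS (default an 8-mer).
#' @param motif_offsets Offsets of motif copies relative to the GSS, in
#'   transcript orientation (default -30 and 0).
#' @param substitution_prob Per-position probability that a planted motif
#'   base is replaced by a random different base (default 0.15).
#' @param cpg_enrichment Factor multiplying the C->G transition probability
#'   within +/- 149 bp of each GSS (default 3; 1 disables enrichment).
#' @param minus_fraction Fraction of GSS planted on the minus strand
#'   (default 0.5).
#' @param gss_margin Minimum distance of a GSS from chromosome ends
#'   (default 5150, so 10-kb metagene windows always fit).
#' @param gss_spacing Minimum distance between GSS (default 1000).
#' @param seed Integer seed.
#' @return A `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(n_chroms = 1L, chrom_length = 100000L,
                                  n_gss = 10L,
                                  base_freqs = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                                  motif = "TACGTCAG",
                                  motif_offsets = c(-30L, 0L),
                                  substitution_prob = 0.15,
                                  cpg_enrichment = 3,
                                  minus_fraction = 0.5,
                                  gss_margin = 5150L,
                                  gss_spacing = 1000L,
                                  seed = 1L) {
  stopifnot(all(sort(names(base_freqs)) == c("A", "C", "G", "T")),
            abs(sum(base_freqs) - 1) < 1e-8,
            substitution_prob >= 0, substitution_prob <= 1,
            minus_fraction >= 0, minus_fraction <= 1,
            cpg_enrichment > 0, nchar(motif) >= 1,
            grepl("^[ACGT]+$", motif))
  usable <- chrom_length - 2 * gss_margin - (n_gss - 1) * gss_spacing
  if (usable < 0)
    stop("infeasible spacing: ", n_gss, " GSS with spacing ", gss_spacing,
         " and margin ", gss_margin, " do not fit in ", chrom_length, " bp")
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_gss = as.integer(n_gss), base_freqs = base_freqs,
                 motif = motif, motif_offsets = as.integer(motif_offsets),
                 substitution_prob = substitution_prob,
                 cpg_enrichment = cpg_enrichment,
                 minus_fraction = minus_fraction,
                 gss_margin = as.integer(gss_margin),
                 gss_spacing = as.integer(gss_spacing),
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

# n positions in [lo, hi] with pairwise spacing >= gap, uniform over the
# feasible set: draw sorted uniforms on the shrunk interval, then re-expand.
spaced_positions <- function(n, lo, hi, gap) {
  slack <- (hi - lo) - (n - 1L) * gap
  u <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  lo + u + (seq_len(n) - 1L) * gap
}

mutate_motif <- function(motif, sub_prob) {
  b <- strsplit(motif, "")[[1]]
  hit <- stats::runif(length(b)) < sub_prob
  if (any(hit))
    b[hit] <- vapply(b[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
  paste(b, collapse = "")
}

# First-order chain boosting the C->G transition by `factor` inside a
# region; with factor = 1 this reduces exactly to the i.i.d. background.
cpg_enriched_chars <- function(n, freqs, factor, prev = "") {
  bases <- c("A", "C", "G", "T")
  p0 <- freqs[bases]
  pG <- min(unname(p0["G"]) * factor, 0.9)
  pafterC <- c(p0[c("A", "C")] * (1 - pG) / (1 - p0[["G"]]),
               G = pG,
               p0["T"] * (1 - pG) / (1 - p0[["G"]]))
  pafterC <- pafterC[bases]
  cum0 <- cumsum(p0); cumC <- cumsum(pafterC)
  u <- stats::runif(n)
  out <- character(n)
  for (i in seq_len(n)) {
    cm <- if (prev == "C") cumC else cum0
    prev <- out[i] <- bases[findInterval(u[i], cm) + 1L]
  }
  out
}

#' Generate a synthetic genome with planted GSS
#'
#' Samples background sequence from the spec's base frequencies, rewrites
#' the +/-149 bp neighbourhood of each planted GSS with the CpG-enriched
#' chain, then writes motif copies (with substitution noise) at the stated
#' offsets — reverse-complemented and mirrored for minus-strand GSS so the
#' motif reads the same in transcript orientation.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return A list: `genome` (named character vector, class `gss_genome`),
#'   `gss` (GSS data.frame), `truth` (data.frame of every planted motif
#'   instance: `chrom`, `gss_position`, `strand`, `offset`, `motif_start`,
#'   `planted`), `spec`.
#' @export
generate_synthetic_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  withr::with_seed(spec$seed, {
    bases <- c("A", "C", "G", "T")
    freqs <- spec$base_freqs[bases]
    mlen <- nchar(spec$motif)
    genome <- character(spec$n_chroms)
    names(genome) <- paste0("chr", seq_len(spec$n_chroms))
    gss_rows <- list(); truth_rows <- list()
    for (ci in seq_len(spec$n_chroms)) {
      chrom <- names(genome)[ci]
      chars <- sample(bases, spec$chrom_length, replace = TRUE, prob = freqs)
      pos <- spaced_positions(spec$n_gss, spec$gss_margin,
                              spec$chrom_length - 1L - spec$gss_margin,
                              spec$gss_spacing)
      strand <- ifelse(stats::runif(spec$n_gss) < spec$minus_fraction,
                       "-", "+")
      for (gi in seq_len(spec$n_gss)) {
        p <- pos[gi]
        if (spec$cpg_enrichment != 1) {
          lo <- p - FLANK; hi <- p + FLANK      # 0-based inclusive
          chars[(lo + 1L):(hi + 1L)] <-
            cpg_enriched_chars(hi - lo + 1L, freqs, spec$cpg_enrichment,
                               prev = if (lo > 0L) chars[lo] else "")
        }
        for (off in spec$motif_offsets) {
          planted <- mutate_motif(spec$motif, spec$substitution_prob)
          if (strand[gi] == "+") {
            mstart <- p + off                   # 0-based genomic start
            written <- planted
          } else {
            mstart <- p - off - mlen + 1L
            written <- revcomp(planted)
          }
          chars[(mstart + 1L):(mstart + mlen)] <- strsplit(written, "")[[1]]
          truth_rows[[length(truth_rows) + 1L]] <-
            data.frame(chrom = chrom, gss_position = p,
                       strand = strand[gi], offset = off,
                       motif_start = mstart, planted = written,
                       stringsAsFactors = FALSE)
        }
      }
      genome[ci] <- paste(chars, collapse = "")
      gss_rows[[ci]] <- data.frame(
        chrom = chrom, position = pos, strand = strand,
        gene_name = sprintf("SYNG_%s_%03d", chrom, seq_len(spec$n_gss)),
        tx_class = "mRNA",
        accession = sprintf("NM_SYN%02d%03d", ci, seq_len(spec$n_gss)),
        stringsAsFactors = FALSE)
    }
    class(genome) <- "gss_genome"
    list(genome = genome, gss = do.call(rbind, gss_rows),
         truth = do.call(rbind, truth_rows), spec = spec)
  })
}

#' The standard desk-scale benchmark
#'
#' A fixed synthetic study design used throughout the package's
#' evaluation: 3 chromosomes of 1 Mb, 150 GSS per chromosome (chr3 is the
#' designated held-out test chromosome), the default 8-mer consensus
#' planted at offsets -30 and 0 with substitution probability 0.15, 3x CpG
#' enrichment, half of the GSS on the minus strand.
#'
#' @param seed Integer seed.
#' @return As [generate_synthetic_genome()], plus `holdout = "chr3"`.
#' @export
standard_benchmark <- function(seed = 1L) {
  spec <- synthetic_genome_spec(n_chroms = 3L, chrom_length = 1000000L,
                                n_gss = 150L, seed = seed)
  out <- generate_synthetic_genome(spec)
  out$holdout <- "chr3"
  out
}

#' Write a synthetic genome bundle to disk
#'
#' FASTA (genome), BED (GSS) and TSV (planted-motif truth table).
#'
#' @param bundle Output of [generate_synthetic_genome()] or
#'   [standard_benchmark()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"synthetic"`).
#' @return Named character vector of the paths written.
#' @export
write_synthetic_genome <- function(bundle, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(prefix, ".fa")),
             bed = file.path(dir, paste0(prefix, ".gss.bed")),
             truth = file.path(dir, paste0(prefix, ".truth.tsv")))
  write_genome_fasta(bundle$genome, paths[["fasta"]])
  write_gss_bed(bundle$gss, paths[["bed"]])
  data.table::fwrite(bundle$truth, paths[["truth"]], sep = "\t")
  paths
}
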