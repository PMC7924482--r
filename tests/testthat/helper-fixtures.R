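# Shared fixtures, all generated in code.

# Small planted-motif genome for module-level tests.
tiny_bundle <- function(seed = 7L, n_chroms = 2L, chrom_length = 40000L,
                        n_gss = 6L, ...) {
  generate_synthetic_genome(synthetic_genome_spec(
    n_chroms = n_chroms, chrom_length = chrom_length, n_gss = n_gss,
    seed = seed, ...))
}

random_dna <- function(n, width = 299L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = ""), character(1))
}

# A linearly separable window set: positives carry two exact 8-mers.
separable_sample_set <- function(n_pos = 120L, Q = 1L, seed = 11L) {
  withr::with_seed(seed, {
    n_neg <- Q * n_pos
    pos <- random_dna(n_pos)
    substr(pos, 120L, 127L) <- "TACGTCAG"
    substr(pos, 150L, 157L) <- "TACGTCAG"
    seqs <- c(pos, random_dna(n_neg))
    y <- c(rep(1L, n_pos), rep(0L, n_neg))
    split <- gssnet:::assign_split(y, c(train = 0.7, validation = 0.15,
                                        test = 0.15))
    ord <- sample(length(y))
  })
  windows <- data.frame(chrom = "synthetic", start = 0L, end = 299L,
                        strand = "+", label = y[ord], split = split[ord])
  structure(list(X = gssnet:::encode_windows(seqs[ord]), y = y[ord],
                 windows = windows, Q = Q, seed = seed,
                 holdout_chroms = character(0),
                 split_fractions = c(train = 0.7, validation = 0.15,
                                     test = 0.15)),
            class = "sample_set")
}

# Build a prediction_track directly from a numeric vector (position i of
# `scores` is genomic coordinate i - 1).
manual_track <- function(scores, chrom = "chrT") {
  structure(list(chrom = chrom, scores = as.numeric(scores),
                 window = 299L, flank = 149L, model_id = "manual"),
            class = "prediction_track")
}

make_gss <- function(chrom, position, strand = "+") {
  data.frame(chrom = chrom, position = as.integer(position),
             strand = strand, gene_name = "g", tx_class = "mRNA",
             accession = NA, stringsAsFactors = FALSE)
}

# Independent recomputation of the whole lambda pipeline from a raw score
# vector and GSS positions, kept free of package internals.
brute_force_lambda <- function(scores, positions, strands, hw, r) {
  def <- !is.na(scores)
  z <- (scores - mean(scores[def])) / stats::sd(scores[def])
  rows <- list()
  for (i in seq_along(positions)) {
    idx <- (positions[i] - hw):(positions[i] + hw) + 1L
    v <- z[idx]
    if (any(idx < 1) || any(idx > length(z)) || anyNA(v)) next
    rows[[length(rows) + 1L]] <- if (strands[i] == "-") rev(v) else v
  }
  S <- colMeans(do.call(rbind, rows))
  mean(S[(hw + 1 - r / 2):(hw + r / 2)])
}

# Independent reverse complement (no Biostrings), for oracle comparisons.
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}
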