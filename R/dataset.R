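# Limited unbalanced training sets: positive 299-bp windows centred on GSS,
# Q negatives per positive sampled at random with GSS rejection, one-hot
# encoding (A, T, C, G row order) and stratified train/validation/test
# splitting with chromosome holdout.

WINDOW_SIZE <- 299L
FLANK <- 149L
MAX_N_FRAC <- 0.1

# byte -> one-hot row (1=A, 2=T, 3=C, 4=G; 0 = N / zero column).
.base_row <- local({
  lk <- integer(256)
  lk[utf8ToInt("A")] <- 1L; lk[utf8ToInt("T")] <- 2L
  lk[utf8ToInt("C")] <- 3L; lk[utf8ToInt("G")] <- 4L
  lk
})

# byte -> scan code (0=A, 1=T, 2=C, 3=G, 4=N), the C++ convention.
.base_code <- local({
  lk <- rep(4L, 256)
  lk[utf8ToInt("A")] <- 0L; lk[utf8ToInt("T")] <- 1L
  lk[utf8ToInt("C")] <- 2L; lk[utf8ToInt("G")] <- 3L
  lk
})

seq_to_codes <- function(sequence) .base_code[utf8ToInt(sequence)]

revcomp <- function(sequences) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sequences)))
}

count_n <- function(sequences) {
  vapply(sequences,
         function(s) sum(utf8ToInt(s) == 78L), integer(1), USE.NAMES = FALSE)
}

#' One-hot encode a DNA window
#'
#' Encodes a sequence as a 4 x width binary matrix with row order A, T, C, G:
#' A = (1,0,0,0), T = (0,1,0,0), C = (0,0,1,0), G = (0,0,0,1).  An `N`
#' becomes an all-zero column.
#'
#' @param sequence A string over `A`,`C`,`G`,`T`,`N`.
#' @param width Required sequence length (default 299).
#' @return A 4 x `width` numeric matrix with rownames `A`,`T`,`C`,`G`.
#' @export
one_hot <- function(sequence, width = WINDOW_SIZE) {
  v <- utf8ToInt(toupper(sequence))
  if (length(v) != width)
    stop("sequence length ", length(v), " != required width ", width)
  if (!all(intToUtf8(v, multiple = TRUE) %in% GENOME_ALPHABET))
    stop("sequence contains characters outside {A,C,G,T,N}")
  r <- .base_row[v]
  m <- matrix(0, 4L, width, dimnames = list(c("A", "T", "C", "G"), NULL))
  hit <- which(r > 0L)
  m[cbind(r[hit], hit)] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [one_hot()]: the unit row index of each column gives the base,
#' an all-zero column gives `N`.
#'
#' @param m A 4 x width binary matrix in A, T, C, G row order.
#' @return A string.
#' @export
decode_one_hot <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 4L)
  bases <- c("A", "T", "C", "G")
  paste(vapply(seq_len(ncol(m)), function(j) {
    i <- which(m[, j] != 0)
    if (length(i) == 0) "N" else bases[i[1]]
  }, character(1)), collapse = "")
}

# Encode many windows into a (4, width, n) array.
encode_windows <- function(sequences, width = WINDOW_SIZE) {
  n <- length(sequences)
  X <- array(0, dim = c(4L, width, n))
  for (i in seq_len(n)) {
    v <- utf8ToInt(sequences[[i]])
    if (length(v) != width)
      stop("window ", i, " has length ", length(v), ", expected ", width)
    r <- .base_row[v]
    hit <- which(r > 0L)
    X[cbind(r[hit], hit, i)] <- 1
  }
  X
}

#' Extract positive windows around GSS
#'
#' Cuts the `[position - flank, position + flank + 1)` window around each
#' GSS.  Minus-strand windows are reverse-complemented so every window reads
#' in transcript orientation.  GSS too close to a chromosome end, on a
#' chromosome absent from the genome, or whose window is more than 10% `N`
#' are skipped with a warning.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param gss GSS data.frame (see [extract_gss()]).
#' @param flank Bases on each side of the GSS (default 149, i.e. 299-bp
#'   windows).
#' @return A list with `windows` (data.frame `chrom`, `start`, `end`,
#'   `strand`, `label = 1`) and `seqs` (character vector).
#' @export
extract_positive_windows <- function(genome, gss, flank = FLANK) {
  width <- 2L * flank + 1L
  len <- stats::setNames(nchar(genome), names(genome))
  known <- gss$chrom %in% names(genome)
  if (any(!known))
    warning(sum(!known), " GSS on chromosomes absent from the genome skipped")
  g <- gss[known, , drop = FALSE]
  inside <- g$position >= flank & g$position + flank < len[g$chrom]
  if (any(!inside))
    warning(sum(!inside), " GSS closer than ", flank,
            " bp to a chromosome end skipped")
  g <- g[inside, , drop = FALSE]
  start <- g$position - flank
  seqs <- substring(genome[g$chrom], start + 1L, start + width)
  nfrac_ok <- count_n(seqs) <= MAX_N_FRAC * width
  if (any(!nfrac_ok))
    warning(sum(!nfrac_ok), " positive windows with more than ",
            round(100 * MAX_N_FRAC), "% N dropped")
  g <- g[nfrac_ok, , drop = FALSE]
  seqs <- seqs[nfrac_ok]
  start <- start[nfrac_ok]
  minus <- g$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  list(windows = data.frame(chrom = g$chrom, start = start,
                            end = start + width, strand = g$strand,
                            label = 1L, stringsAsFactors = FALSE),
       seqs = unname(seqs))
}

#' Sample negative (non-GSS) windows
#'
#' Draws fixed-width windows at random genomic positions on a random strand:
#' the chromosome is chosen with probability proportional to its length, the
#' start uniformly, the strand uniformly.  A candidate is rejected and
#' redrawn if any GSS position (either strand) lies inside its span, or if
#' it is more than 10% `N`.  Minus-strand windows are reverse-complemented.
#'
#' @param genome Named character vector of chromosome sequences (holdout
#'   chromosomes already removed by the caller).
#' @param gss GSS data.frame used for rejection.
#' @param count Number of windows to return.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers can wrap the whole build in one seed).
#' @param width Window width (default 299).
#' @return A list with `windows` (data.frame, `label = 0`) and `seqs`.
#' @export
sample_negative_windows <- function(genome, gss, count, seed = NULL,
                                    width = WINDOW_SIZE) {
  stopifnot(count >= 1)
  if (!is.null(seed))
    return(withr::with_seed(seed,
      sample_negative_windows(genome, gss, count, NULL, width)))
  chroms <- names(genome)
  len <- nchar(genome)
  usable <- len >= width
  if (!any(usable)) stop("no chromosome is at least ", width, " bp long")
  chroms <- chroms[usable]; len <- len[usable]
  gpos <- lapply(chroms, function(ch) sort(gss$position[gss$chrom == ch]))
  names(gpos) <- chroms
  ncum <- lapply(chroms, function(ch) {
    c(0L, cumsum(utf8ToInt(genome[[ch]]) == 78L))
  })
  names(ncum) <- chroms

  got_ch <- character(0); got_start <- integer(0); got_strand <- character(0)
  drawn <- 0L
  while (length(got_start) < count) {
    need <- count - length(got_start)
    m <- max(ceiling(need * 1.3), 100L)
    ch <- sample(chroms, m, replace = TRUE, prob = len)
    start <- floor(stats::runif(m) * (len[ch] - width + 1))
    strand <- sample(c("+", "-"), m, replace = TRUE)
    drawn <- drawn + m
    keep <- rep(TRUE, m)
    for (c1 in unique(ch)) {
      i <- which(ch == c1)
      gp <- gpos[[c1]]
      if (length(gp))
        keep[i] <- keep[i] &
          (findInterval(start[i] + width - 1, gp) ==
             findInterval(start[i] - 1, gp))
      nc <- ncum[[c1]]
      nwin <- nc[start[i] + width + 1L] - nc[start[i] + 1L]
      keep[i] <- keep[i] & (nwin <= MAX_N_FRAC * width)
    }
    got_ch <- c(got_ch, ch[keep])
    got_start <- c(got_start, start[keep])
    got_strand <- c(got_strand, strand[keep])
    if (drawn >= 1e4 && length(got_start) / drawn < 0.01)
      stop("more than 99% of candidate windows rejected; ",
           "GSS (or N runs) tile essentially the whole genome")
  }
  got_ch <- got_ch[seq_len(count)]
  got_start <- as.integer(got_start[seq_len(count)])
  got_strand <- got_strand[seq_len(count)]
  seqs <- substring(genome[got_ch], got_start + 1L, got_start + width)
  minus <- got_strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  list(windows = data.frame(chrom = got_ch, start = got_start,
                            end = got_start + width, strand = got_strand,
                            label = 0L, stringsAsFactors = FALSE),
       seqs = unname(seqs))
}

#' Size arithmetic for a limited unbalanced dataset
#'
#' Given a positive-class size and the negative:positive ratio Q, returns
#' the implied class sizes and the genomic footprint of the negative class.
#'
#' @param n_positive Number of positive (GSS) windows.
#' @param Q Negative:positive ratio.
#' @param window_size Window width in bp (default 299).
#' @return A list: `n_positive`, `n_negative`, `n_total`,
#'   `negative_bases` and `negative_gigabases`.
#' @export
dataset_dimensions <- function(n_positive, Q, window_size = WINDOW_SIZE) {
  n_neg <- round(Q * n_positive)
  bases <- n_neg * as.numeric(window_size)
  list(n_positive = n_positive, n_negative = n_neg,
       n_total = n_positive + n_neg,
       negative_bases = bases, negative_gigabases = bases / 1e9)
}

# Stratified split, using the current RNG stream.  Positive counts follow
# the fractions; negative counts are tied to them (round(Q x positives))
# so every partition keeps the negative:positive ratio within one sample.
assign_split <- function(labels, fractions) {
  pos <- sample(which(labels == 1))
  neg <- sample(which(labels == 0))
  np_te <- round(fractions[["test"]] * length(pos))
  np_va <- round(fractions[["validation"]] * length(pos))
  np_tr <- length(pos) - np_te - np_va
  Q <- length(neg) / max(1L, length(pos))
  nn_te <- min(length(neg), round(Q * np_te))
  nn_va <- min(length(neg) - nn_te, round(Q * np_va))
  nn_tr <- length(neg) - nn_te - nn_va
  split <- character(length(labels))
  split[pos] <- rep(c("test", "validation", "train"),
                    c(np_te, np_va, np_tr))
  split[neg] <- rep(c("test", "validation", "train"),
                    c(nn_te, nn_va, nn_tr))
  split
}

#' Build a limited unbalanced sample set
#'
#' Assembles positives from all non-holdout chromosomes, samples `Q` times
#' as many negatives with GSS rejection, one-hot encodes everything,
#' shuffles with the given seed, and assigns a stratified
#' train/validation/test split (each partition keeps the Q ratio within
#' rounding).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param gss GSS data.frame.
#' @param Q Negative:positive ratio (>= 1).
#' @param holdout_chroms Chromosomes excluded from sampling entirely (kept
#'   for genome-wide evaluation).
#' @param seed Integer seed driving negative sampling, shuffling and split
#'   assignment.
#' @param split_fractions Named numeric: `train`, `validation`, `test`
#'   fractions summing to 1 (defaults 0.70/0.15/0.15).
#' @param flank Flank size (default 149).
#' @return A `sample_set`: list with `X` (4 x 299 x n array), `y` (0/1),
#'   `windows` (coordinates, strand, label, split), `Q`, `seed`,
#'   `holdout_chroms`, `split_fractions`.
#' @export
build_dataset <- function(genome, gss, Q, holdout_chroms = character(),
                          seed = 1L,
                          split_fractions = c(train = 0.70,
                                              validation = 0.15,
                                              test = 0.15),
                          flank = FLANK) {
  if (Q < 1) stop("Q must be >= 1")
  stopifnot(all(c("train", "validation", "test") %in% names(split_fractions)))
  if (any(split_fractions <= 0) || abs(sum(split_fractions) - 1) > 1e-8)
    stop("split fractions must be positive and sum to 1")
  keep <- setdiff(names(genome), holdout_chroms)
  if (!length(keep)) stop("all chromosomes are held out")
  gsub_ <- genome[keep]
  class(gsub_) <- class(genome)
  gss_use <- gss[gss$chrom %in% keep, , drop = FALSE]
  pos <- extract_positive_windows(gsub_, gss_use, flank = flank)
  P <- nrow(pos$windows)
  if (P == 0) stop("no usable positive windows")
  width <- 2L * flank + 1L

  withr::with_seed(seed, {
    neg <- sample_negative_windows(gsub_, gss_use, count = round(Q * P),
                                   seed = NULL, width = width)
    windows <- rbind(pos$windows, neg$windows)
    seqs <- c(pos$seqs, neg$seqs)
    split <- assign_split(windows$label, split_fractions)
    ord <- sample(nrow(windows))
  })
  windows <- windows[ord, , drop = FALSE]
  windows$split <- split[ord]
  seqs <- seqs[ord]
  rownames(windows) <- NULL
  structure(list(X = encode_windows(seqs, width), y = windows$label,
                 windows = windows, Q = Q, seed = seed,
                 holdout_chroms = holdout_chroms,
                 split_fractions = split_fractions),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf(
    "<sample_set> %d windows (%d positive, %d negative), Q = %g, seed = %d\n",
    length(x$y), sum(x$y == 1), sum(x$y == 0), x$Q, x$seed))
  print(table(split = x$windows$split, label = x$y))
  invisible(x)
}

#' Extract one partition of a sample set
#'
#' @param sample_set A `sample_set`.
#' @param split One of `"train"`, `"validation"`, `"test"`.
#' @return A list with `X` (array) and `y`.
#' @export
get_split <- function(sample_set, split = c("train", "validation", "test")) {
  split <- match.arg(split)
  i <- which(sample_set$windows$split == split)
  list(X = sample_set$X[, , i, drop = FALSE], y = sample_set$y[i])
}

#' Save / load a sample set
#'
#' The sample set is stored as an RDS container with a BED sidecar of all
#' window coordinates (`<path>.bed`) and a JSON sidecar of its metadata
#' (`<path>.json`).
#'
#' @param sample_set A `sample_set`.
#' @param path Output path for the RDS container.
#' @return `path`, invisibly.
#' @export
save_sample_set <- function(sample_set, path) {
  saveRDS(sample_set, path)
  w <- sample_set$windows
  data.table::fwrite(
    data.frame(w$chrom, w$start, w$end,
               paste0(ifelse(w$label == 1, "pos", "neg"), ":", w$split),
               w$label, w$strand),
    paste0(path, ".bed"), sep = "\t", col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n = length(sample_set$y), n_positive = sum(sample_set$y == 1),
         Q = sample_set$Q, seed = sample_set$seed,
         holdout_chroms = sample_set$holdout_chroms,
         split_fractions = as.list(sample_set$split_fractions)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_sample_set
#' @export
load_sample_set <- function(path) {
  ss <- readRDS(path)
  if (!inherits(ss, "sample_set")) stop("not a sample_set: ", path)
  ss
}
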