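# Stride-1 genome scanning: score every 299-bp window of a chromosome and
# assign the score to the window's centre coordinate.  The heavy lifting
# (convolutions shared across overlapping windows) happens in C++.

#' Scan a chromosome with a trained model
#'
#' Scores every 299-bp window of the forward strand at 1-bp stride; the
#' score of window `[s, s + 299)` is stored at the centre coordinate
#' `s + 149`.  Windows with more than 10% `N` are masked to `NA`, as are
#' the 149 flanking positions at each chromosome end that are not covered
#' by any window centre.
#'
#' @param model A trained `gss_model`.
#' @param sequence Chromosome sequence: a single string, or a genome
#'   (named character vector) together with `chrom`.
#' @param chrom Chromosome name (used to pick from a genome and recorded in
#'   the track; defaults to the sequence's name or `"chr"`).
#' @param both_strands When `TRUE`, the reverse-complement strand is also
#'   scanned and each position keeps the maximum of the two scores.
#' @return A `prediction_track`: list with `chrom`, `scores` (numeric of
#'   chromosome length, `NA` where undefined), `window`, `flank`,
#'   `model_id`.
#' @export
scan_chromosome <- function(model, sequence, chrom = NULL,
                            both_strands = FALSE) {
  stopifnot(inherits(model, "gss_model"))
  if (length(sequence) > 1L || !is.null(names(sequence))) {
    if (is.null(chrom)) {
      if (length(sequence) == 1L) chrom <- names(sequence)
      else stop("chrom must be given when sequence is a multi-chromosome genome")
    }
    if (!chrom %in% names(sequence))
      stop("unknown chromosome '", chrom, "'; available: ",
           paste(names(sequence), collapse = ", "))
    sequence <- sequence[[chrom]]
  }
  if (is.null(chrom)) chrom <- "chr"
  b <- model$config$input_length
  flank <- (b - 1L) %/% 2L
  L <- nchar(sequence)
  if (L < b) stop("chromosome length ", L, " is shorter than the ", b,
                  " bp window")
  codes <- seq_to_codes(sequence)
  raw <- cpp_cnn_scan(codes, model$weights, b)   # one score per window start
  if (both_strands) {
    raw_rc <- cpp_cnn_scan(seq_to_codes(revcomp(sequence)), model$weights, b)
    raw <- pmax(raw, rev(raw_rc))
  }
  # windows with > 10% N are undefined
  ncum <- c(0, cumsum(codes == 4L))
  n_in_window <- ncum[(b + 1L):(L + 1L)] - ncum[1:(L - b + 1L)]
  raw[n_in_window > MAX_N_FRAC * b] <- NA_real_
  raw[is.nan(raw)] <- NA_real_
  scores <- rep(NA_real_, L)
  scores[(flank + 1L):(L - flank)] <- raw
  structure(list(chrom = chrom, scores = scores, window = b, flank = flank,
                 model_id = sprintf("gssnet(seed=%d)", model$seed)),
            class = "prediction_track")
}

#' Scan several chromosomes
#'
#' @param model A trained `gss_model`.
#' @param genome Named character vector of chromosome sequences.
#' @param chroms Chromosomes to scan (default: all).
#' @param both_strands See [scan_chromosome()].
#' @return A named list of `prediction_track`s.
#' @export
scan_genome <- function(model, genome, chroms = NULL, both_strands = FALSE) {
  if (is.null(chroms)) chroms <- names(genome)
  unknown <- setdiff(chroms, names(genome))
  if (length(unknown))
    stop("unknown chromosome(s) ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(genome), collapse = ", "))
  stats::setNames(lapply(chroms, function(ch)
    scan_chromosome(model, genome[[ch]], chrom = ch,
                    both_strands = both_strands)), chroms)
}

#' @export
print.prediction_track <- function(x, ...) {
  d <- sum(!is.na(x$scores))
  cat(sprintf(
    "<prediction_track> %s: %s bp, %s defined positions [%s]\n",
    x$chrom, format(length(x$scores), big.mark = ","),
    format(d, big.mark = ","), x$model_id))
  invisible(x)
}

#' Positions of a track carrying a defined score
#'
#' @param track A `prediction_track` (or Z-score track).
#' @return Integer vector of 0-based genomic coordinates.
#' @export
defined_positions <- function(track) {
  which(!is.na(track$scores)) - 1L
}

track_granges <- function(track, collapse = TRUE) {
  sc <- track$scores
  r <- S4Vectors::Rle(sc)
  rl <- S4Vectors::runLength(r)
  rv <- S4Vectors::runValue(r)
  ends <- cumsum(rl)
  starts <- ends - rl + 1L
  keep <- !is.na(rv)
  if (!collapse) {
    idx <- which(!is.na(sc))
    return(GenomicRanges::GRanges(rep(track$chrom, length(idx)),
                                  IRanges::IRanges(idx, idx),
                                  score = sc[idx]))
  }
  GenomicRanges::GRanges(rep(track$chrom, sum(keep)),
                         IRanges::IRanges(starts[keep], ends[keep]),
                         score = rv[keep])
}

#' Write a prediction track to bedGraph or wiggle
#'
#' bedGraph output is 0-based half-open with runs of equal consecutive
#' values collapsed into single intervals; wiggle output is per-position.
#' Positions without a defined score are omitted in both formats.
#'
#' @param track A `prediction_track` or Z-score track.
#' @param path Output path.
#' @param format `"bedgraph"` (default) or `"wig"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("bedgraph", "wig")) {
  format <- match.arg(format)
  if (format == "bedgraph") {
    rtracklayer::export(track_granges(track, collapse = TRUE), path,
                        format = "bedGraph")
  } else {
    rtracklayer::export(track_granges(track, collapse = FALSE), path,
                        format = "wig")
  }
  invisible(path)
}

#' Read a track written by [write_track()]
#'
#' @param path Path to a bedGraph or wiggle file.
#' @param length Chromosome length; defaults to the last covered position.
#' @return A `prediction_track` (with `model_id = "file"`).
#' @export
read_track <- function(path, length = NULL) {
  gr <- rtracklayer::import(path)
  if (is.null(length)) length <- max(GenomicRanges::end(gr))
  scores <- rep(NA_real_, length)
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  sc <- gr$score
  for (i in seq_along(gr)) scores[st[i]:en[i]] <- sc[i]
  structure(list(chrom = as.character(GenomicRanges::seqnames(gr))[1],
                 scores = scores, window = WINDOW_SIZE, flank = FLANK,
                 model_id = "file"),
            class = "prediction_track")
}
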