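# Genome-wide evaluation: the lambda signal-to-noise metric (Z-score the
# track, average 10-kb windows centred on GSS into the metagene curve S,
# then average the central r bp of S), conventional test-set metrics,
# binned precision-recall, and CpG-content analyses.

#' Z-score a prediction track
#'
#' `Z_g = (y_g - mu) / sigma`, with `mu` and `sigma` the mean and standard
#' deviation of all defined positions of the scanned region.
#'
#' @param track A `prediction_track`.
#' @return A `zscore_track`: like the input but with Z values in `$scores`
#'   and the normalisation constants in `$mu`, `$sigma`.
#' @export
zscore_track <- function(track) {
  y <- track$scores
  def <- !is.na(y)
  if (sum(def) < 2L) stop("need at least 2 defined positions to Z-score")
  mu <- mean(y[def])
  sigma <- stats::sd(y[def])
  if (sigma == 0) stop("constant track (sigma = 0) cannot be Z-scored")
  z <- (y - mu) / sigma
  structure(list(chrom = track$chrom, scores = z, mu = mu, sigma = sigma,
                 window = track$window, flank = track$flank,
                 model_id = track$model_id),
            class = c("zscore_track", "prediction_track"))
}

#' Metagene profile of Z-scores around GSS
#'
#' Extracts the Z signal over `2 * half_width + 1` positions centred on
#' each GSS whose full window lies inside the defined range of the track
#' (GSS too close to the ends, or spanning masked positions, are excluded
#' and counted).  Minus-strand rows are reversed so positive offsets point
#' downstream of transcription.  `S` is the column-wise mean.
#'
#' @param z A `zscore_track` (or a list of them for several chromosomes).
#' @param gss GSS data.frame; rows on other chromosomes are ignored.
#' @param half_width Half window width in bp (default 5000: 10-kb windows).
#' @return A `metagene_profile`: list with `matrix` (GSS x offsets),
#'   `offsets` (-half_width .. half_width), `S`, `n_gss_used`,
#'   `n_excluded`.
#' @export
metagene_profile <- function(z, gss, half_width = 5000L) {
  tracks <- if (inherits(z, "prediction_track")) list(z) else z
  width <- 2L * half_width + 1L
  rows <- list(); excluded <- 0L
  for (tr in tracks) {
    g <- gss[gss$chrom == tr$chrom, , drop = FALSE]
    if (!nrow(g)) next
    L <- length(tr$scores)
    for (i in seq_len(nrow(g))) {
      pos <- g$position[i]
      lo <- pos - half_width; hi <- pos + half_width
      if (lo < 0L || hi >= L) { excluded <- excluded + 1L; next }
      v <- tr$scores[(lo + 1L):(hi + 1L)]
      if (anyNA(v)) { excluded <- excluded + 1L; next }
      if (g$strand[i] == "-") v <- rev(v)
      rows[[length(rows) + 1L]] <- v
    }
  }
  if (!length(rows))
    stop("no GSS with a fully defined ", width, " bp window (",
         excluded, " edge- or mask-excluded)")
  m <- do.call(rbind, rows)
  structure(list(matrix = m, offsets = seq(-half_width, half_width),
                 S = colMeans(m), n_gss_used = nrow(m),
                 n_excluded = excluded, half_width = half_width),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf(
    "<metagene_profile> %d GSS x %d offsets (+/- %d bp), %d excluded\n",
    x$n_gss_used, length(x$S), x$half_width, x$n_excluded))
  invisible(x)
}

#' The lambda genome-wide signal-to-noise score
#'
#' The mean of the metagene curve `S` over the central `r` offsets
#' (`-r/2 .. r/2 - 1` relative to the GSS).  Higher lambda means a higher
#' prediction signal specifically around true GSS relative to the
#' chromosome background.
#'
#' @param profile A [metagene_profile()].
#' @param r Width of the central averaging window in bp (default 400;
#'   must be even).
#' @param tags Optional named list recorded for provenance (species,
#'   chromosome, model).
#' @return A `lambda_result`: list with `lambda`, `r`, `n_gss_used`, `S`,
#'   `tags`.
#' @export
lambda_score <- function(profile, r = 400L, tags = list()) {
  stopifnot(inherits(profile, "metagene_profile"))
  if (r %% 2L != 0L) stop("r must be even")
  if (r > length(profile$S)) stop("r = ", r, " exceeds the profile width")
  centre <- profile$half_width + 1L              # offset 0
  idx <- (centre - r %/% 2L):(centre + r %/% 2L - 1L)
  structure(list(lambda = mean(profile$S[idx]), r = as.integer(r),
                 n_gss_used = profile$n_gss_used, S = profile$S,
                 tags = tags),
            class = "lambda_result")
}

#' @export
print.lambda_result <- function(x, ...) {
  cat(sprintf("<lambda_result> lambda = %.4f (r = %d bp, %d GSS)\n",
              x$lambda, x$r, x$n_gss_used))
  if (length(x$tags))
    cat("  tags:", paste(names(x$tags), unlist(x$tags), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Z-score + metagene + lambda in one call
#'
#' Each track (one per scanned chromosome) is Z-scored with its own
#' mean/sd; metagene rows are pooled across tracks before averaging.
#'
#' @param track A `prediction_track`, or a list of them.
#' @param gss GSS data.frame.
#' @param r Central window width (default 400).
#' @param half_width Metagene half-width (default 5000).
#' @param tags Provenance tags.
#' @return A `lambda_result`.
#' @export
evaluate_lambda <- function(track, gss, r = 400L, half_width = 5000L,
                            tags = list()) {
  tracks <- if (inherits(track, "prediction_track")) list(track) else track
  z <- lapply(tracks, zscore_track)
  lambda_score(metagene_profile(z, gss, half_width), r = r, tags = tags)
}

#' Export a lambda result (JSON) and its S curve (TSV)
#'
#' @param result A `lambda_result`.
#' @param json_path Path for the JSON report (`lambda`, `r`, `n_gss_used`,
#'   `tags`).
#' @param s_path Optional path for the S curve as TSV (`offset`, `mean_z`).
#' @return `json_path`, invisibly.
#' @export
write_lambda <- function(result, json_path, s_path = NULL) {
  jsonlite::write_json(list(lambda = result$lambda, r = result$r,
                            n_gss_used = result$n_gss_used,
                            tags = result$tags),
                       json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(s_path)) {
    hw <- (length(result$S) - 1L) %/% 2L
    data.table::fwrite(data.frame(offset = seq(-hw, hw), mean_z = result$S),
                       s_path, sep = "\t")
  }
  invisible(json_path)
}

#' Confusion-matrix metrics at a decision threshold
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, precision,
#' recall and the Matthews correlation coefficient.  A metric whose
#' denominator is zero is reported as `NA` and named in `$undefined`
#' rather than silently zeroed.
#'
#' @param y_true 0/1 labels.
#' @param scores Predicted scores (or already-thresholded 0/1 labels).
#' @param threshold Decision threshold (default 0.5; ties go positive).
#' @return A `confusion_summary`: list with `TP`, `FP`, `TN`, `FN`, `Sn`,
#'   `Sp`, `precision`, `recall`, `MCC`, `threshold`, `undefined`.
#' @export
confusion_metrics <- function(y_true, scores, threshold = 0.5) {
  if (!length(y_true)) stop("empty input")
  if (length(y_true) != length(scores))
    stop("y_true and scores have different lengths")
  pred <- classify(scores, threshold)
  TP <- sum(pred == 1 & y_true == 1)
  FP <- sum(pred == 1 & y_true == 0)
  TN <- sum(pred == 0 & y_true == 0)
  FN <- sum(pred == 0 & y_true == 1)
  undef <- character(0)
  rate <- function(num, den, what) {
    if (den == 0) { undef <<- c(undef, what); NA_real_ } else num / den
  }
  Sn <- rate(TP, TP + FN, "Sn")
  Sp <- rate(TN, TN + FP, "Sp")
  precision <- rate(TP, TP + FP, "precision")
  mcc_den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  MCC <- if (mcc_den == 0) { undef <- c(undef, "MCC"); NA_real_ } else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 Sn = Sn, Sp = Sp, precision = precision, recall = Sn,
                 MCC = MCC, threshold = threshold, undefined = undef),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "<confusion_summary> TP=%d FP=%d TN=%d FN=%d | Sn=%.3f Sp=%.3f MCC=%.3f (t=%g)\n",
    x$TP, x$FP, x$TN, x$FN, x$Sn, x$Sp, x$MCC, x$threshold))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Binned precision-recall along a chromosome
#'
#' Tiles the chromosome into non-overlapping bins; a bin is truly positive
#' when it contains at least one GSS and is called positive at threshold
#' `t` when the maximum defined score inside it reaches `t`.  Bins without
#' any defined score are excluded (and counted).
#'
#' @param track A `prediction_track`.
#' @param gss GSS data.frame.
#' @param bin_width Bin width in bp (default 600).
#' @param thresholds Sorted numeric thresholds.
#' @return A data.frame: `threshold`, `precision`, `recall`, `n_called`,
#'   `n_positive_bins`, `n_bins`; with attribute `n_undefined_bins`.
#' @export
binned_precision_recall <- function(track, gss, bin_width = 600L,
                                    thresholds = seq(0, 1, by = 0.05)) {
  stopifnot(bin_width >= 1)
  if (is.unsorted(thresholds)) stop("thresholds must be sorted")
  L <- length(track$scores)
  bin <- rep(seq_len(ceiling(L / bin_width)), each = bin_width)[1:L]
  def <- !is.na(track$scores)
  if (!any(def)) stop("track has no defined scores in any bin")
  bmax <- tapply(track$scores[def], bin[def], max)
  gss_here <- gss[gss$chrom == track$chrom, , drop = FALSE]
  gbin <- unique(gss_here$position %/% bin_width + 1L)
  used_bins <- as.integer(names(bmax))
  truth <- used_bins %in% gbin
  out <- lapply(thresholds, function(t) {
    called <- bmax >= t
    TP <- sum(called & truth); FP <- sum(called & !truth)
    FN <- sum(!called & truth)
    data.frame(threshold = t,
               precision = if (TP + FP == 0) NA_real_ else TP / (TP + FP),
               recall = if (TP + FN == 0) NA_real_ else TP / (TP + FN),
               n_called = TP + FP, n_positive_bins = sum(truth),
               n_bins = length(used_bins))
  })
  res <- do.call(rbind, out)
  attr(res, "n_undefined_bins") <- length(unique(bin)) - length(used_bins)
  res
}

#' Count CpG dinucleotides in a window
#'
#' Number of positions `i` with `C` at `i` and `G` at `i + 1` (every
#' occurrence counted).
#'
#' @param sequences Character vector of DNA windows.
#' @return Integer vector of CpG counts.
#' @export
cpg_count <- function(sequences) {
  as.integer(Biostrings::vcountPattern(
    "CG", Biostrings::DNAStringSet(sequences)))
}

#' Classify GSS into low / medium / high CpG promoter classes
#'
#' Counts CpG dinucleotides in the 299-bp window centred on each GSS and
#' splits the GSS set at the `lower_q` and `upper_q` quantiles of the
#' count distribution into three classes of similar size (defaults 35% and
#' 60%).
#'
#' @param gss GSS data.frame (edge GSS without a full window are dropped).
#' @param genome Named character vector of chromosome sequences.
#' @param lower_q,upper_q Class-bound quantiles (defaults 0.35 and 0.60).
#' @param flank Window flank (default 149).
#' @return A `cpg_classing`: list with `gss` (input rows plus `cpg_count`
#'   and `cpg_class`), `bounds`, `counts`.
#' @export
cpg_classes <- function(gss, genome, lower_q = 0.35, upper_q = 0.60,
                        flank = FLANK) {
  stopifnot(lower_q < upper_q)
  if (nrow(gss) < 3) stop("need at least 3 GSS to form classes")
  win <- extract_positive_windows(genome, gss, flank = flank)
  counts <- cpg_count(win$seqs)
  g <- win$windows
  g$position <- g$start + flank
  if (length(unique(counts)) == 1L) {
    warning("all CpG counts identical; single-class result")
    cls <- rep("medium", length(counts))
    bounds <- c(lower = counts[1], upper = counts[1])
  } else {
    bounds <- stats::quantile(counts, c(lower_q, upper_q), names = FALSE)
    names(bounds) <- c("lower", "upper")
    cls <- ifelse(counts < bounds[["lower"]], "low",
                  ifelse(counts >= bounds[["upper"]], "high", "medium"))
  }
  out <- data.frame(chrom = g$chrom, position = g$position,
                    strand = g$strand, cpg_count = counts,
                    cpg_class = cls, stringsAsFactors = FALSE)
  structure(list(gss = out, bounds = bounds, counts = counts),
            class = "cpg_classing")
}

#' @export
print.cpg_classing <- function(x, ...) {
  cat(sprintf("<cpg_classing> bounds [%g, %g): ", x$bounds[["lower"]],
              x$bounds[["upper"]]))
  print(table(x$gss$cpg_class))
  invisible(x)
}

#' Sliding-window CpG content as a baseline predictor
#'
#' Counts CpG dinucleotides in every 299-bp window at 1-bp stride and
#' stores the count at the window centre, producing a count-valued track
#' that can be fed through the same Z-score / metagene / lambda pipeline
#' as model predictions.
#'
#' @param sequence Chromosome sequence (string), or genome plus `chrom`.
#' @param chrom Chromosome name (as in [scan_chromosome()]).
#' @param window Window width (default 299).
#' @return A `prediction_track` whose scores are CpG counts.
#' @export
cpg_baseline_track <- function(sequence, chrom = NULL, window = WINDOW_SIZE) {
  if (length(sequence) > 1L || !is.null(names(sequence))) {
    if (is.null(chrom)) {
      if (length(sequence) == 1L) chrom <- names(sequence)
      else stop("chrom must be given for a multi-chromosome genome")
    }
    sequence <- sequence[[chrom]]
  }
  if (is.null(chrom)) chrom <- "chr"
  L <- nchar(sequence)
  if (L < window) stop("chromosome shorter than the window")
  flank <- (window - 1L) %/% 2L
  v <- utf8ToInt(sequence)
  isC <- v == 67L
  isG <- v == 71L
  cg <- as.integer(isC[-L] & isG[-1L])           # CpG starting at i (0-based i-1)
  # pairs fully inside [s, s+window): starts s .. s+window-2  ->  window-1 terms
  ccum <- c(0L, cumsum(cg))
  counts <- ccum[seq.int(window, L)] - ccum[seq_len(L - window + 1L)]
  isN <- v == 78L
  ncum <- c(0L, cumsum(isN))
  nwin <- ncum[(window + 1L):(L + 1L)] - ncum[1:(L - window + 1L)]
  counts <- as.numeric(counts)
  counts[nwin > MAX_N_FRAC * window] <- NA_real_
  scores <- rep(NA_real_, L)
  scores[(flank + 1L):(L - flank)] <- counts
  structure(list(chrom = chrom, scores = scores, window = window,
                 flank = flank, model_id = "cpg_baseline"),
            class = "prediction_track")
}
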