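# Genome sequences and gene-start-site (GSS) annotations.
#
# Coordinates are 0-based, half-open everywhere inside the package, matching
# the refGene/BED sources.  A GSS is the first transcribed base: txStart for
# a "+" transcript, txEnd - 1 for a "-" transcript.

GENOME_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a genome FASTA file
#'
#' Reads a (possibly gzipped) FASTA file with one record per chromosome.
#' Sequences are uppercased and every character outside `A`,`C`,`G`,`T`
#' (including IUPAC ambiguity codes) is mapped to `N`.
#'
#' @param path Path to a FASTA file, plain or gzip-compressed.
#' @return A named character vector of chromosome sequences, in file order,
#'   with class `gss_genome`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("FASTA file is empty: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, ">"))
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (!length(dss)) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(dss))
  seqs <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seqs)
  # header up to first whitespace, as chromosome name
  names(seqs) <- sub("\\s.*$", "", names(dss))
  bad <- grepl(sprintf("[^%s]", paste(GENOME_ALPHABET, collapse = "")), seqs)
  if (any(bad))  # anything Biostrings let through (e.g. '-') also becomes N
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  structure(seqs, class = "gss_genome")
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path (`.gz` suffix triggers compression).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(dss, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @export
print.gss_genome <- function(x, ...) {
  cat(sprintf("<gss_genome> %d chromosome(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (nm in names(x))
    cat(sprintf("  %s  %s bp\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  invisible(x)
}

# fread with transparent gzip support (no R.utils dependency).
fread_auto <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    data.table::fread(text = readLines(con), ...)
  } else {
    data.table::fread(path, ...)
  }
}

# refGene flat files come with or without the leading UCSC `bin` column.
REFGENE_COLS <- c("name", "chrom", "strand", "txStart", "txEnd",
                  "cdsStart", "cdsEnd", "exonCount", "exonStarts",
                  "exonEnds", "score", "name2", "cdsStartStat",
                  "cdsEndStat", "exonFrames")

#' Read a UCSC refGene annotation file
#'
#' Parses the tab-separated UCSC refGene flat file (15 columns, or 16 with
#' the leading `bin` column), plain or gzipped.  `txStart`/`txEnd` stay in
#' the source's 0-based half-open convention.
#'
#' @param path Path to a refGene file (`.gz` handled transparently).
#' @return A data.frame with one row per transcript: `name` (accession),
#'   `chrom`, `strand`, `txStart`, `txEnd`, `name2` (gene symbol).
#' @export
read_refgene <- function(path) {
  if (!file.exists(path)) stop("refGene file not found: ", path)
  dt <- fread_auto(path, header = FALSE, sep = "\t",
                   colClasses = list(character = 1), fill = FALSE,
                   showProgress = FALSE)
  if (!nrow(dt)) stop("refGene file is empty: ", path)
  nc <- ncol(dt)
  if (nc == length(REFGENE_COLS) + 1L) {
    dt[[1]] <- NULL  # drop the bin column
  } else if (nc != length(REFGENE_COLS)) {
    stop(sprintf(
      "refGene parse error at line 1: expected %d or %d tab-separated columns, found %d",
      length(REFGENE_COLS), length(REFGENE_COLS) + 1L, nc))
  }
  data.table::setnames(dt, REFGENE_COLS)
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("refGene parse error at line %d: unknown strand symbol '%s'",
                 bad[1], dt$strand[bad[1]]))
  out <- as.data.frame(dt[, c("name", "chrom", "strand",
                              "txStart", "txEnd", "name2")])
  out$txStart <- as.integer(out$txStart)
  out$txEnd <- as.integer(out$txEnd)
  out
}

#' Classify transcripts as mRNA or ncRNA from their RefSeq accession
#'
#' `NM_`/`XM_` accessions are messenger RNAs, `NR_`/`XR_` are non-coding;
#' anything else is treated as ncRNA with a warning.
#'
#' @param accession Character vector of transcript accessions.
#' @return Character vector, `"mRNA"` or `"ncRNA"`.
#' @export
tx_class_from_accession <- function(accession) {
  cls <- ifelse(grepl("^(NM_|XM_)", accession), "mRNA",
                ifelse(grepl("^(NR_|XR_)", accession), "ncRNA", NA_character_))
  if (anyNA(cls)) {
    warning(sum(is.na(cls)),
            " accession(s) without NM_/XM_/NR_/XR_ prefix classed as ncRNA")
    cls[is.na(cls)] <- "ncRNA"
  }
  cls
}

#' Extract gene start sites from transcript annotations
#'
#' The GSS of a `+` transcript is `txStart`; of a `-` transcript it is
#' `txEnd - 1` (the first transcribed base, in 0-based coordinates, since
#' `txEnd` is the half-open end).  Records are deduplicated on the exact
#' `(chrom, position, strand)` triple, so alternative isoforms sharing a
#' start collapse to one GSS while nearby alternative starts stay distinct.
#'
#' @param rows data.frame from [read_refgene()], or any data.frame with
#'   columns `chrom`, `strand`, `txStart`, `txEnd` and optionally `name`
#'   (accession) and `name2` (gene symbol).
#' @param genome Optional genome (named character vector); when supplied,
#'   GSS falling outside their chromosome (or on chromosomes absent from
#'   the genome) are dropped with a warning.
#' @return A data.frame of GSS records: `chrom`, `position` (0-based),
#'   `strand`, `gene_name`, `tx_class`, `accession`.
#' @export
extract_gss <- function(rows, genome = NULL) {
  stopifnot(all(c("chrom", "strand", "txStart", "txEnd") %in% names(rows)))
  if (!all(rows$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  pos <- ifelse(rows$strand == "+", rows$txStart, rows$txEnd - 1L)
  acc <- if ("name" %in% names(rows)) rows$name else rep(NA_character_, nrow(rows))
  gsym <- if ("name2" %in% names(rows)) rows$name2 else acc
  cls <- if ("tx_class" %in% names(rows)) rows$tx_class else
    tx_class_from_accession(acc)
  out <- data.frame(chrom = rows$chrom, position = as.integer(pos),
                    strand = rows$strand, gene_name = gsym,
                    tx_class = cls, accession = acc,
                    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    len <- nchar(genome)[out$chrom]
    ok <- !is.na(len) & out$position >= 0L & out$position < len
    if (any(!ok)) {
      warning(sum(!ok), " GSS outside chromosome bounds or on unknown ",
              "chromosomes were dropped")
      out <- out[ok, , drop = FALSE]
    }
  }
  dup <- duplicated(out[, c("chrom", "position", "strand")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write GSS records as 6-column BED
#'
#' One line per GSS: `chrom`, `position`, `position + 1`, `gene_name`,
#' `0`, `strand`.
#'
#' @param gss GSS data.frame from [extract_gss()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gss_bed <- function(gss, path) {
  bed <- data.frame(gss$chrom, gss$position, gss$position + 1L,
                    ifelse(is.na(gss$gene_name), ".", gss$gene_name),
                    0L, gss$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read GSS records from 6-column BED
#'
#' Accepts the BED written by [write_gss_bed()] (or any BED6 of single-base
#' features).  The `tx_class` of BED-sourced records defaults to `"mRNA"`
#' unless the name field carries a recognisable RefSeq accession.
#'
#' @param path Path to a BED file.
#' @return A GSS data.frame as from [extract_gss()].
#' @export
read_gss_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  dt <- fread_auto(path, header = FALSE, sep = "\t", showProgress = FALSE)
  if (ncol(dt) < 6) stop("expected >= 6 BED columns, found ", ncol(dt))
  nm <- as.character(dt[[4]])
  looks_refseq <- grepl("^(NM_|XM_|NR_|XR_)", nm)
  cls <- rep("mRNA", nrow(dt))
  cls[looks_refseq] <- suppressWarnings(tx_class_from_accession(nm[looks_refseq]))
  out <- data.frame(chrom = as.character(dt[[1]]),
                    position = as.integer(dt[[2]]),
                    strand = as.character(dt[[6]]),
                    gene_name = nm, tx_class = cls,
                    accession = ifelse(looks_refseq, nm, NA_character_),
                    stringsAsFactors = FALSE)
  if (!all(out$strand %in% c("+", "-"))) stop("BED strand must be '+' or '-'")
  dup <- duplicated(out[, c("chrom", "position", "strand")])
  out[!dup, , drop = FALSE]
}
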