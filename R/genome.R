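#' Load a reference genome with an optional repeat mask
#'
#' Reads a FASTA file into an in-memory genome object carrying the sequences,
#' chromosome lengths, a merged repeat mask, and the total and non-repeat
#' genome lengths used as denominators by the enrichment statistics.
#'
#' All coordinates in this package are 0-based, half-open. Chromosome names
#' are matched verbatim against the FASTA headers (no "chr" normalisation).
#'
#' @param fasta Path to a FASTA file (plain or gzip).
#' @param repeat_bed Optional path to a BED-like repeat mask whose 4th column
#'   is the repeat class (e.g. "Satellite", "LINE"). Overlapping records are
#'   merged per class for length accounting.
#' @return An object of class `genome`: a list with elements `seq` (named
#'   character vector of uppercase sequences), `lengths`, `repeat_mask`
#'   (interval data frame, possibly empty), `total_len` and `nonrepeat_len`.
#' @export
load_genome <- function(fasta, repeat_bed = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) == 0L) stop("no sequences in FASTA: ", fasta)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence contains characters other than A,C,G,T,N: ",
         names(seqs)[bad][1])
  }
  mask <- if (is.null(repeat_bed)) {
    empty_intervals()
  } else {
    read_intervals(repeat_bed, stranded = FALSE)
  }
  genome_from_seqs(seqs, mask)
}

#' Build a genome object from named sequences
#'
#' @param seqs Named character vector of uppercase DNA sequences.
#' @param repeat_mask Interval data frame of repeat records (may be empty).
#' @return A `genome` object; see [load_genome()].
#' @export
genome_from_seqs <- function(seqs, repeat_mask = empty_intervals()) {
  lens <- nchar(seqs)
  validate_intervals(repeat_mask, lens)
  g <- list(
    seq = seqs,
    lengths = lens,
    repeat_mask = repeat_mask,
    total_len = sum(as.numeric(lens)),
    nonrepeat_len = sum(as.numeric(lens)) - masked_bases(repeat_mask)
  )
  class(g) <- "genome"
  g
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome: %d sequence(s), %s bp total, %s bp non-repeat\n",
              length(x$seq), format(x$total_len, big.mark = ","),
              format(x$nonrepeat_len, big.mark = ",")))
  invisible(x)
}

# Total bases covered by a set of intervals, overlaps merged first.
masked_bases <- function(iv) {
  if (nrow(iv) == 0L) return(0)
  m <- merge_intervals(iv)
  sum(as.numeric(m$end - m$start))
}

#' Write a genome to FASTA
#'
#' @param genome A `genome` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Reference bases at stranded positions, vectorised. pos0 is 0-based; for
# minus-strand queries the plus-strand base is complemented (not reversed:
# single bases).
genome_base <- function(genome, chrom, pos0, strand) {
  stopifnot(length(chrom) == length(pos0), length(pos0) == length(strand))
  out <- character(length(pos0))
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    s <- genome$seq[[cn]]
    if (is.null(s)) stop("unknown chromosome: ", cn)
    b <- substring(s, pos0[i] + 1L, pos0[i] + 1L)
    mi <- strand[i] == "-"
    b[mi] <- chartr("ACGTN", "TGCAN", b[mi])
    out[i] <- b
  }
  out
}

# Plus-strand reference substring [start0, end0), clipped to bounds.
genome_slice <- function(genome, chrom, start0, end0) {
  s <- genome$seq[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  L <- genome$lengths[[chrom]]
  a <- max(start0, 0L); b <- min(end0, L)
  if (a >= b) return("")
  substring(s, a + 1L, b)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
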