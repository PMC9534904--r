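#' Filter and trim the protocol tag structure
#'
#' A pair is accepted iff read 1 begins with the literal AGTTGCGGAT followed
#' by a maximal G-run of 9-11 bases and read 2 begins with a maximal T-run
#' of 11-13 bases. On accept both matched prefixes are removed. "Maximal"
#' means the base following the run is not another G (respectively T): a
#' longer run cannot arise from the tagging chemistry and marks an
#' unresolvable boundary.
#'
#' @param r1,r2 Character vectors of raw read sequences (equal length).
#' @return A list: `accept` (logical), `r1_trim`, `r2_trim` (trimmed
#'   sequences, NA where rejected) and `reason` ("r1_tag"/"r2_tag", NA where
#'   accepted).
#' @export
filter_tag_structure <- function(r1, r2) {
  stopifnot(length(r1) == length(r2))
  m1 <- regexpr("^AGTTGCGGATG{9,11}(?!G)", r1, perl = TRUE)
  m2 <- regexpr("^T{11,13}(?!T)", r2, perl = TRUE)
  ok1 <- m1 > 0L
  ok2 <- m2 > 0L
  accept <- ok1 & ok2
  reason <- ifelse(accept, NA_character_,
                   ifelse(!ok1, "r1_tag", "r2_tag"))
  list(
    accept = accept,
    r1_trim = ifelse(accept, substring(r1, attr(m1, "match.length") + 1L),
                     NA_character_),
    r2_trim = ifelse(accept, substring(r2, attr(m2, "match.length") + 1L),
                     NA_character_),
    reason = reason)
}

#' Remove PCR duplicates among aligned pairs
#'
#' Pairs sharing both mates' alignment coordinates (chromosome, leftmost
#' position and strand of read 1 and of read 2) are collapsed to a single
#' representative: the pair with the highest summed MAPQ, ties broken by
#' lexicographically smallest read name for determinism.
#'
#' @param pairs Pair data frame ([align_exact()]/[load_alignments()] layout).
#' @return The deduplicated pair data frame.
#' @export
dedup_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  key <- paste(pairs$r1_chrom, pairs$r1_pos0, pairs$r1_strand,
               pairs$r2_chrom, pairs$r2_pos0, pairs$r2_strand)
  score <- ifelse(is.na(pairs$r1_mapq), 0L, pairs$r1_mapq) +
    ifelse(is.na(pairs$r2_mapq), 0L, pairs$r2_mapq)
  ord <- order(key, -score, pairs$name)
  keep <- !duplicated(key[ord])
  out <- pairs[ord[keep], , drop = FALSE]
  out[order(match(out$name, pairs$name)), , drop = FALSE]
}

#' Genomic alignment filter
#'
#' Passes a pair iff read 2 has MAPQ strictly greater than 20, a SAM flag of
#' 147 or 163 (proper pair, second in pair, one mate reversed) and a first
#' sequenced base aligned with a match to the reference (no leading
#' soft-clip or insertion, base identical to the reference).
#'
#' @param pairs Pair data frame.
#' @param genome A `genome` object for the reference comparison.
#' @return A list: `pass` (logical) and `reason` ("mapq"/"flag"/
#'   "first_base", NA where passing).
#' @export
filter_alignments_genomic <- function(pairs, genome) {
  mq <- pairs$r2_mapq
  ok_mapq <- !is.na(mq) & mq > 20L
  ok_flag <- !is.na(pairs$r2_flag) & pairs$r2_flag %in% c(147L, 163L)
  ok_first <- first_base_matched(pairs, genome)
  reason <- ifelse(!ok_mapq, "mapq",
                   ifelse(!ok_flag, "flag",
                          ifelse(!ok_first, "first_base", NA_character_)))
  list(pass = ok_mapq & ok_flag & ok_first, reason = reason)
}

# First sequenced base of read 2 aligned with a match: CIGAR must start (in
# read orientation) with M and the base must equal the reference. Stored
# sequences follow SAM orientation, so for minus-strand reads the first
# sequenced base is the last stored base compared at the rightmost
# reference position.
first_base_matched <- function(pairs, genome) {
  n <- nrow(pairs)
  out <- logical(n)
  mapped <- !is.na(pairs$r2_chrom) & pairs$r2_cigar != "*"
  if (!any(mapped)) return(out)
  i <- which(mapped)
  lead <- leading_op(pairs$r2_cigar[i], pairs$r2_strand[i])
  p5 <- read_five_prime_pos(pairs$r2_pos0[i], pairs$r2_strand[i],
                            pairs$r2_cigar[i])
  refb <- genome_base(genome, pairs$r2_chrom[i], p5, rep("+", length(i)))
  seqb <- ifelse(pairs$r2_strand[i] == "+",
                 substring(pairs$r2_seq[i], 1L, 1L),
                 substring(pairs$r2_seq[i], nchar(pairs$r2_seq[i]),
                           nchar(pairs$r2_seq[i])))
  out[i] <- lead %in% c("M", "=") & seqb == refb & refb != "N"
  out
}

#' Spike-in alignment filter
#'
#' Passes a pair iff both mates mapped uniquely (MAPQ >= 20) to opposite
#' strands of the same spike with a leftmost-coordinate distance strictly
#' below 500 bp, and the first sequenced base of read 2 matches the
#' reference. Note the MAPQ threshold is inclusive here, unlike the strict
#' "> 20" of the genomic filter.
#'
#' @param pairs Pair data frame aligned to the spike sequences.
#' @param spike_genome `genome` object of the spike sequences.
#' @return A list: `pass` and `reason` ("mapq"/"strand"/"distance"/
#'   "first_base").
#' @export
filter_alignments_spike <- function(pairs, spike_genome) {
  ok_mapq <- !is.na(pairs$r1_mapq) & !is.na(pairs$r2_mapq) &
    pairs$r1_mapq >= 20L & pairs$r2_mapq >= 20L
  ok_strand <- !is.na(pairs$r1_chrom) & !is.na(pairs$r2_chrom) &
    pairs$r1_chrom == pairs$r2_chrom &
    pairs$r1_strand != pairs$r2_strand
  dist <- abs(pairs$r1_pos0 - pairs$r2_pos0)
  ok_dist <- !is.na(dist) & dist < 500L
  ok_first <- first_base_matched(pairs, spike_genome)
  reason <- ifelse(!ok_mapq, "mapq",
                   ifelse(!ok_strand, "strand",
                          ifelse(!ok_dist, "distance",
                                 ifelse(!ok_first, "first_base",
                                        NA_character_))))
  list(pass = ok_mapq & ok_strand & ok_dist & ok_first, reason = reason)
}

#' Genomic polyA-priming filter
#'
#' Removes read-2 positions adjacent to genomic polyA runs, which mimic the
#' polyA tail: the 20 reference bases immediately 5' of read 2's first
#' aligned base, taken in read orientation on the read's alignment strand,
#' must not contain more than 40% thymines. Windows truncated by a
#' chromosome end use the available length as denominator; a read with no
#' upstream base passes.
#'
#' @param pairs Pair data frame.
#' @param genome A `genome` object.
#' @param window Upstream window size (bases).
#' @param max_t_frac Maximum allowed thymine fraction (strictly-greater
#'   values fail).
#' @return A list: `pass` (logical) and `t_frac` (the measured fraction,
#'   NaN where no window exists).
#' @export
genomic_polyA_filter <- function(pairs, genome, window = 20L,
                                 max_t_frac = 0.40) {
  n <- nrow(pairs)
  t_frac <- rep(NaN, n)
  mapped <- which(!is.na(pairs$r2_chrom))
  if (length(mapped)) {
    p5 <- read_five_prime_pos(pairs$r2_pos0[mapped],
                              pairs$r2_strand[mapped],
                              pairs$r2_cigar[mapped])
    for (k in seq_along(mapped)) {
      i <- mapped[k]
      if (pairs$r2_strand[i] == "+") {
        w <- genome_slice(genome, pairs$r2_chrom[i], p5[k] - window, p5[k])
        tc <- nchar(gsub("[^T]", "", w))
      } else {
        w <- genome_slice(genome, pairs$r2_chrom[i], p5[k] + 1L,
                          p5[k] + 1L + window)
        tc <- nchar(gsub("[^A]", "", w))   # T on the minus strand
      }
      if (nchar(w) > 0L) t_frac[i] <- tc / nchar(w)
    }
  }
  pass <- is.nan(t_frac) | t_frac <= max_t_frac
  list(pass = pass, t_frac = t_frac)
}

#' Assign lesion coordinates from filtered read-2 alignments
#'
#' The lesion lies one base past the 5' end of read 2 along the strand
#' opposite the read: for a plus-strand read 2 with first sequenced base at
#' p the site is (p - offset, "-"); for a minus-strand read 2 it is
#' (p + offset, "+"). `lesion_offset` 1 maps AP sites (the cleaved base is
#' one step 3' of the tail-bearing terminus on the damaged strand); 0 maps
#' plain strand-break (SSB) termini.
#'
#' @param pairs Pair data frame of pairs passing all filters.
#' @param genome A `genome` object (for bounds checking).
#' @param lesion_offset 1 for AP sites, 0 for SSBs.
#' @param ... Sample metadata passed to [ap_site_set()].
#' @return A list: `sites` (an `ap_sites` object) and `n_out_of_bounds`
#'   (reads whose assigned coordinate fell off the chromosome).
#' @export
assign_sites <- function(pairs, genome, lesion_offset = 1L, ...) {
  p5 <- if (nrow(pairs)) {
    read_five_prime_pos(pairs$r2_pos0, pairs$r2_strand, pairs$r2_cigar)
  } else integer()
  site_strand <- ifelse(pairs$r2_strand == "+", "-", "+")
  site_pos <- ifelse(pairs$r2_strand == "+", p5 - lesion_offset,
                     p5 + lesion_offset)
  L <- genome$lengths[pairs$r2_chrom]
  ok <- !is.na(site_pos) & site_pos >= 0L & site_pos < L
  agg <- aggregate_calls(pairs$r2_chrom[ok], site_pos[ok], site_strand[ok])
  list(sites = ap_site_set(agg, ...),
       n_out_of_bounds = sum(!ok))
}

#' Run the site-calling pipeline
#'
#' Applies the stages in order: tag-structure filtering and trimming,
#' alignment (either the packaged exact aligner against `genome`, or
#' externally produced alignments joined by read name), duplicate removal,
#' the genomic (or spike) alignment filter, the genomic polyA filter
#' (genomic branch only; spikes skip deduplication and the polyA filter),
#' and coordinate assignment.
#'
#' @param r1,r2 Raw read vectors (named) or FASTQ paths.
#' @param genome `genome` object: the reference for the toy aligner and the
#'   filters (for spikes, the spike sequences).
#' @param pairs Optional pre-aligned pair data frame of the tag-trimmed
#'   reads (e.g. from [load_alignments()]); when supplied the toy aligner
#'   is skipped and pairs are matched to tag-passing read names.
#' @param mode "ap" (one-base lesion shift) or "ssb" (no shift).
#' @param spike Use the spike-in filter branch.
#' @param ... Sample metadata passed to [ap_site_set()].
#' @return A list: `sites` (an `ap_sites` object) and `stats` (a
#'   `filter_stats` object).
#' @export
run_pipeline <- function(r1, r2, genome, pairs = NULL,
                         mode = c("ap", "ssb"), spike = FALSE, ...) {
  mode <- match.arg(mode)
  if (length(r1) == 1L && file.exists(r1[1])) {
    r1 <- read_fastq(r1); r2 <- read_fastq(r2)
  }
  n_input <- length(r1)
  tg <- filter_tag_structure(r1, r2)
  keep <- which(tg$accept)
  r1t <- stats::setNames(tg$r1_trim[keep], names(r1)[keep])
  r2t <- stats::setNames(tg$r2_trim[keep], names(r2)[keep])
  n_tag <- length(keep)
  if (is.null(pairs)) {
    aln <- align_exact(r1t, r2t, genome)
  } else {
    aln <- pairs[pairs$name %in% names(r1t), , drop = FALSE]
  }
  mapped <- !is.na(aln$r2_chrom)
  aln <- aln[mapped, , drop = FALSE]
  n_aligned <- nrow(aln)
  rejections <- list(tag = table(tg$reason[!tg$accept]),
                     unmapped = n_tag - n_aligned)
  if (!spike) {
    aln <- dedup_pairs(aln)
    n_dedup <- nrow(aln)
    fl <- filter_alignments_genomic(aln, genome)
    rejections$alignment <- table(fl$reason[!fl$pass])
    aln <- aln[fl$pass, , drop = FALSE]
    n_filter <- nrow(aln)
    pa <- genomic_polyA_filter(aln, genome)
    rejections$polyA <- sum(!pa$pass)
    aln <- aln[pa$pass, , drop = FALSE]
    n_polyA <- nrow(aln)
  } else {
    n_dedup <- n_aligned
    fl <- filter_alignments_spike(aln, genome)
    rejections$alignment <- table(fl$reason[!fl$pass])
    aln <- aln[fl$pass, , drop = FALSE]
    n_filter <- n_polyA <- nrow(aln)
    rejections$polyA <- 0L
  }
  offset <- if (mode == "ap") 1L else 0L
  asg <- assign_sites(aln, genome, lesion_offset = offset,
                      n_tag_pairs = n_tag,
                      assay = if (spike) "spike" else toupper(mode), ...)
  rejections$out_of_bounds <- asg$n_out_of_bounds
  stats <- structure(list(
    input_pairs = n_input, tag_pass = n_tag, align_pass = n_aligned,
    dedup_pass = n_dedup, filter_pass = n_filter, polyA_pass = n_polyA,
    site_reads = asg$sites$n_site_reads, rejections = rejections),
    class = "filter_stats")
  list(sites = asg$sites, stats = stats)
}

#' @export
print.filter_stats <- function(x, ...) {
  cat(sprintf(
    paste0("pairs: %d input, %d tag-pass, %d aligned, %d deduplicated,\n",
           "       %d filter-pass, %d polyA-pass, %d site reads\n"),
    x$input_pairs, x$tag_pass, x$align_pass, x$dedup_pass, x$filter_pass,
    x$polyA_pass, x$site_reads))
  invisible(x)
}

#' Convert filter statistics to a stage table
#'
#' @param stats A `filter_stats` object.
#' @return Data frame with columns `stage`, `pass`, `fail`.
#' @export
filter_stats_table <- function(stats) {
  stages <- c("input", "tag", "align", "dedup", "filter", "polyA",
              "assign")
  pass <- c(stats$input_pairs, stats$tag_pass, stats$align_pass,
            stats$dedup_pass, stats$filter_pass, stats$polyA_pass,
            stats$site_reads)
  fail <- c(0L, stats$input_pairs - stats$tag_pass,
            stats$tag_pass - stats$align_pass,
            stats$align_pass - stats$dedup_pass,
            stats$dedup_pass - stats$filter_pass,
            stats$filter_pass - stats$polyA_pass,
            stats$polyA_pass - stats$site_reads)
  data.frame(stage = stages, pass = pass, fail = fail)
}
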