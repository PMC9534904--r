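#' Unblocked 3'OH background from spike-in calls
#'
#' Read-weighted fraction of spike site reads mapping to the four 3'-most
#' bases of either strand of the spike sequences (positions [L-4, L) on the
#' plus strand, [0, 4) on the minus strand). A blocked library should show a
#' small fraction; an unblocked control approaches 1.
#'
#' @param sites `ap_sites` object called on the spike sequences.
#' @param spike_lengths Named vector of spike lengths.
#' @return Background fraction, or NA when there are no site reads.
#' @export
spike_background <- function(sites, spike_lengths) {
  s <- sites$sites
  if (nrow(s) == 0L || sum(s$depth) == 0L) return(NA_real_)
  L <- spike_lengths[s$chrom]
  in_window <- ifelse(s$strand == "+", s$pos0 >= L - 4L, s$pos0 < 4L)
  sum(s$depth[in_window]) / sum(s$depth)
}

#' Per-position relative depth across the spike set
#'
#' The depth of each called site divided by the total site reads over all
#' spikes in the sample; values sum to 1.
#'
#' @param sites `ap_sites` object on the spikes.
#' @return Data frame `chrom`, `pos0`, `strand`, `depth`, `rel_depth`.
#' @export
spike_relative_depth <- function(sites) {
  s <- sites$sites
  tot <- sum(s$depth)
  data.frame(s[, c("chrom", "pos0", "strand", "depth")],
             rel_depth = if (tot > 0) s$depth / tot else numeric(nrow(s)))
}

#' Depth-normalised spike profiles for a positive/negative library pair
#'
#' Each position's read depth is normalised by its library's total spike
#' reads and by the pooled fraction of reads mapping to that strand in both
#' libraries, making the two profiles directly comparable. Positions on a
#' strand with zero pooled reads are dropped.
#'
#' @param pos_sites,neg_sites `ap_sites` objects for the paired libraries.
#' @return A list of two data frames (`positive`, `negative`) with a
#'   `norm_depth` column.
#' @export
spike_normalized_depth <- function(pos_sites, neg_sites) {
  sp <- pos_sites$sites; sn <- neg_sites$sites
  tot_p <- sum(sp$depth); tot_n <- sum(sn$depth)
  pooled <- tot_p + tot_n
  strand_frac <- c(
    "+" = (sum(sp$depth[sp$strand == "+"]) +
             sum(sn$depth[sn$strand == "+"])) / pooled,
    "-" = (sum(sp$depth[sp$strand == "-"]) +
             sum(sn$depth[sn$strand == "-"])) / pooled)
  norm <- function(s, tot) {
    sf <- strand_frac[s$strand]
    out <- data.frame(s, norm_depth = s$depth / tot / sf)
    out[sf > 0, , drop = FALSE]
  }
  list(positive = norm(sp, tot_p), negative = norm(sn, tot_n))
}

#' Spike hotspot positions
#'
#' A position is a hotspot iff its value is strictly above the threshold
#' and strictly above the values of both flanking positions on the same
#' spike and strand (a missing neighbour counts as 0).
#'
#' @param rel_depth Data frame with `chrom`, `pos0`, `strand` and a value
#'   column (`rel_depth` or `norm_depth`).
#' @param threshold Minimum value (strict).
#' @param value Name of the value column.
#' @return The hotspot subset of `rel_depth`.
#' @export
spike_hotspots <- function(rel_depth, threshold,
                           value = intersect(c("rel_depth", "norm_depth"),
                                             names(rel_depth))[1]) {
  v <- rel_depth[[value]]
  key <- paste(rel_depth$chrom, rel_depth$strand)
  left <- v[match(paste(key, rel_depth$pos0 - 1L),
                  paste(key, rel_depth$pos0))]
  right <- v[match(paste(key, rel_depth$pos0 + 1L),
                   paste(key, rel_depth$pos0))]
  left[is.na(left)] <- 0; right[is.na(right)] <- 0
  keep <- v > threshold & v > left & v > right
  rel_depth[keep, , drop = FALSE]
}

#' Artifact background from paired negative/positive spike libraries
#'
#' For each library pair the ratio of site reads in the negative spike
#' library to those in the matched positive library; with several pairs the
#' median ratio is reported.
#'
#' @param pos_list,neg_list Lists (or single objects) of `ap_sites` for the
#'   matched positive and negative libraries.
#' @return A list with per-pair `fractions` and their `median`.
#' @export
negative_background_estimate <- function(pos_list, neg_list) {
  if (inherits(pos_list, "ap_sites")) pos_list <- list(pos_list)
  if (inherits(neg_list, "ap_sites")) neg_list <- list(neg_list)
  stopifnot(length(pos_list) == length(neg_list))
  fr <- mapply(function(p, n) {
    if (p$n_site_reads == 0L) return(NA_real_)
    n$n_site_reads / p$n_site_reads
  }, pos_list, neg_list)
  list(fractions = fr, median = stats::median(fr, na.rm = TRUE))
}

#' Nucleotide composition of spike sites at increasing depth thresholds
#'
#' @param sites `ap_sites` on the spikes.
#' @param spike_genome `genome` of the spikes.
#' @param thresholds Relative-depth thresholds; for each, the composition of
#'   sites with relative depth above it.
#' @return Data frame with `threshold`, `n_sites` and A/C/G/T fractions.
#' @export
spike_site_composition <- function(sites, spike_genome,
                                   thresholds = c(0, 1e-4, 1e-3)) {
  rd <- spike_relative_depth(sites)
  rows <- lapply(thresholds, function(th) {
    s <- rd[rd$rel_depth > th, , drop = FALSE]
    if (nrow(s) == 0L) {
      return(data.frame(threshold = th, n_sites = 0L, A = NA_real_,
                        C = NA_real_, G = NA_real_, T = NA_real_))
    }
    b <- genome_base(spike_genome, s$chrom, s$pos0, s$strand)
    f <- table(factor(b, levels = c("A", "C", "G", "T"))) / length(b)
    data.frame(threshold = th, n_sites = nrow(s), A = f[["A"]],
               C = f[["C"]], G = f[["G"]], T = f[["T"]])
  })
  do.call(rbind, rows)
}
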