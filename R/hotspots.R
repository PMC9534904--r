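#' Call sample-level hotspots
#'
#' A hotspot is a single-nucleotide stranded position detected with a depth
#' of at least `min_depth` reads in one sample.
#'
#' @param sites An `ap_sites` object.
#' @param min_depth Minimum read depth (>= 1).
#' @return Data frame of hotspot sites (subset of `sites$sites`).
#' @export
call_hotspots <- function(sites, min_depth = 2L) {
  stopifnot(min_depth >= 1L)
  s <- sites$sites
  s[s$depth >= min_depth, , drop = FALSE]
}

#' Pool per-sample hotspots and summarise sharing
#'
#' @param site_list Named list of `ap_sites` objects (one per sample).
#' @param min_depth Hotspot depth threshold applied per sample.
#' @param min_samples Sharing threshold for the returned position set.
#' @return A list: `positions` (data frame of pooled positions with
#'   `n_samples`), `shared` (subset with `n_samples >= min_samples`) and
#'   `summary` (see [sharing_summary()]).
#' @export
shared_hotspots <- function(site_list, min_depth = 2L, min_samples = 2L) {
  keys <- lapply(site_list, function(s) site_keys(call_hotspots(s,
                                                                min_depth)))
  counts <- table(unlist(keys, use.names = FALSE))
  parts <- strsplit(names(counts), ":", fixed = TRUE)
  positions <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos0 = as.integer(vapply(parts, `[`, "", 2L)),
    strand = vapply(parts, `[`, "", 3L),
    n_samples = as.integer(counts))
  positions <- positions[order(positions$chrom, positions$pos0,
                               positions$strand), , drop = FALSE]
  rownames(positions) <- NULL
  list(positions = positions,
       shared = positions[positions$n_samples >= min_samples, ,
                          drop = FALSE],
       summary = sharing_summary(table(positions$n_samples)))
}

#' Summarise a hotspot sharing distribution
#'
#' @param count_table Table (or named vector) mapping a number of samples to
#'   the number of pooled hotspot positions found in exactly that many
#'   samples.
#' @return A list with `total` pooled positions, `pct_single` (percentage
#'   found in exactly one sample) and `pct_shared_ge` (percentage shared by
#'   at least k samples, for k = 2, 3, ...).
#' @export
sharing_summary <- function(count_table) {
  k <- as.integer(names(count_table))
  n <- as.numeric(count_table)
  total <- sum(n)
  maxk <- max(k, 2L)
  ge <- vapply(2:maxk, function(m) sum(n[k >= m]), numeric(1))
  list(total = total,
       pct_single = 100 * sum(n[k == 1L]) / total,
       pct_shared_ge = stats::setNames(100 * ge / total,
                                       paste0(">=", 2:maxk)))
}

#' Tissue- or age-specific hotspots
#'
#' A position is specific to group g iff (1) it is a hotspot (depth >=
#' `min_depth`) in at least `min_samples` samples of g, and (2) its depth is
#' at most `max_other_depth` in every sample of every other group.
#'
#' @param site_list Named list of `ap_sites` objects.
#' @param groups Character vector of group labels, parallel to `site_list`.
#' @param min_depth,min_samples,max_other_depth Definition thresholds.
#' @return Named list (per group) of position data frames.
#' @export
group_specific_hotspots <- function(site_list, groups, min_depth = 2L,
                                    min_samples = 2L, max_other_depth = 1L) {
  stopifnot(length(groups) == length(site_list))
  if (any(is.na(groups) | !nzchar(groups))) stop("unlabeled sample")
  depth_maps <- lapply(site_list, function(s) {
    stats::setNames(s$sites$depth, site_keys(s))
  })
  out <- list()
  for (g in unique(groups)) {
    ing <- which(groups == g)
    outg <- which(groups != g)
    cnt <- table(unlist(lapply(depth_maps[ing], function(d) {
      names(d)[d >= min_depth]
    }), use.names = FALSE))
    cand <- names(cnt)[cnt >= min_samples]
    if (length(cand) && length(outg)) {
      for (d in depth_maps[outg]) {
        if (!length(cand)) break
        dep <- d[cand]
        cand <- cand[is.na(dep) | dep <= max_other_depth]
      }
    }
    parts <- strsplit(cand, ":", fixed = TRUE)
    out[[g]] <- data.frame(
      chrom = vapply(parts, `[`, "", 1L),
      pos0 = as.integer(vapply(parts, `[`, "", 2L)),
      strand = vapply(parts, `[`, "", 3L))
  }
  out
}

#' Simulate a random site dataset in non-repeat genomic space
#'
#' Draws `n_reads` stranded positions uniformly with replacement from the
#' non-repeat bases of the genome (both strands) and aggregates them into
#' depths, mirroring a read-matched random placement null for hotspot
#' analyses.
#'
#' @param n_reads Number of reads to place.
#' @param genome A `genome` object (its repeat mask defines the excluded
#'   space).
#' @param seed Integer seed.
#' @return An `ap_sites` object (assay "AP", enzyme "none").
#' @export
simulate_random_sites <- function(n_reads, genome, seed = 1L) {
  set.seed(seed)
  segs <- list()
  for (cn in names(genome$seq)) {
    L <- genome$lengths[[cn]]
    r <- IRanges::IRanges(1L, L)
    m <- genome$repeat_mask[genome$repeat_mask$chrom == cn, , drop = FALSE]
    if (nrow(m)) {
      r <- IRanges::setdiff(r, IRanges::IRanges(m$start + 1L, m$end))
    }
    if (length(r)) {
      segs[[cn]] <- data.frame(chrom = cn, start = IRanges::start(r) - 1L,
                               width = IRanges::width(r))
    }
  }
  segs <- do.call(rbind, segs)
  if (is.null(segs) || nrow(segs) == 0L) stop("non-repeat space is empty")
  cw <- cumsum(as.numeric(segs$width))
  total <- cw[length(cw)]
  off <- floor(stats::runif(n_reads) * total)       # 0-based offsets
  seg <- findInterval(off, c(0, cw))
  pos0 <- segs$start[seg] + (off - c(0, cw)[seg])
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  agg <- aggregate_calls(segs$chrom[seg], as.integer(pos0), strand)
  ap_site_set(agg, sample_id = "random", assay = "AP", enzyme = "none")
}

#' Label-permutation null for group-shared hotspot counts
#'
#' The observed statistic is the number of pooled hotspot positions that are
#' hotspots in at least `min_samples` samples carrying the same group
#' label. Labels are then permuted across samples `n_perm` times (hotspot
#' sets stay fixed; only labels move) and the statistic recomputed, giving
#' an empirical p-value (1 + #null >= observed) / (n_perm + 1).
#'
#' @param site_list Named list of `ap_sites` objects.
#' @param groups Group labels, parallel to `site_list`.
#' @param min_depth,min_samples Hotspot and sharing thresholds.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A list: `observed`, `null` (length `n_perm`), `p`.
#' @export
permute_labels_shared_null <- function(site_list, groups, min_depth = 2L,
                                       min_samples = 2L, n_perm = 100L,
                                       seed = 1L) {
  stopifnot(length(groups) == length(site_list))
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  set.seed(seed)
  keysets <- lapply(site_list, function(s) {
    site_keys(call_hotspots(s, min_depth))
  })
  stat <- function(lab) {
    tot <- 0L
    for (g in unique(lab)) {
      k <- unlist(keysets[lab == g], use.names = FALSE)
      if (length(k)) {
        cnt <- table(k)
        tot <- tot + sum(cnt >= min_samples)
      }
    }
    tot
  }
  observed <- stat(groups)
  null <- vapply(seq_len(n_perm), function(i) stat(sample(groups)),
                 numeric(1))
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (n_perm + 1))
}
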