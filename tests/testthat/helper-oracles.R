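# Independent brute-force reference implementations used to validate the
# package's vectorised/interval-tree code paths on small inputs. These stay
# deliberately naive: per-base boolean arrays and explicit loops.

# Total masked bases per chromosome via a per-base boolean array.
oracle_mask_len <- function(iv, chrom_lengths) {
  tot <- 0L
  for (cn in names(chrom_lengths)) {
    covered <- logical(chrom_lengths[[cn]])
    d <- iv[iv$chrom == cn, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      if (d$end[i] > d$start[i]) {
        covered[(d$start[i] + 1L):d$end[i]] <- TRUE
      }
    }
    tot <- tot + sum(covered)
  }
  tot
}

# Is position p (0-based) inside any interval of iv? Explicit scan.
oracle_in_iv <- function(chrom, pos0, iv) {
  any(iv$chrom == chrom & iv$start <= pos0 & pos0 < iv$end)
}

# Pairwise overlap odds ratio from first principles.
oracle_or_pairwise <- function(keysA, keysB, genome_positions) {
  shared <- 0L
  for (k in keysB) if (k %in% keysA) shared <- shared + 1L
  obs <- shared / length(keysB)
  expd <- length(keysA) / genome_positions
  obs / expd
}

# Read-level repeat-class odds ratios: loop every read of every site.
oracle_or_repeats <- function(sites_df, repeat_iv, genome_len) {
  classes <- unique(repeat_iv$class)
  out <- numeric(0)
  total_reads <- sum(sites_df$depth)
  for (cls in classes) {
    iv <- repeat_iv[repeat_iv$class == cls, , drop = FALSE]
    n_in <- 0L
    for (i in seq_len(nrow(sites_df))) {
      for (r in seq_len(sites_df$depth[i])) {
        if (oracle_in_iv(sites_df$chrom[i], sites_df$pos0[i], iv)) {
          n_in <- n_in + 1L
        }
      }
    }
    covered <- 0L
    for (cn in unique(iv$chrom)) {
      m <- max(iv$end[iv$chrom == cn])
      arr <- logical(m)
      d <- iv[iv$chrom == cn, , drop = FALSE]
      for (j in seq_len(nrow(d))) arr[(d$start[j] + 1L):d$end[j]] <- TRUE
      covered <- covered + sum(arr)
    }
    obs <- n_in / total_reads
    expd <- covered / genome_len
    out[cls] <- obs / expd
  }
  out
}

# Element-class odds ratios with repeat masking and coordinate collapsing.
oracle_or_elements <- function(sites_df, elements, genome) {
  mask <- genome$repeat_mask
  keep <- !vapply(seq_len(nrow(sites_df)), function(i) {
    oracle_in_iv(sites_df$chrom[i], sites_df$pos0[i], mask)
  }, logical(1))
  s <- unique(sites_df[keep, c("chrom", "pos0", "strand")])
  out <- list()
  for (cls in unique(elements$class)) {
    iv <- elements[elements$class == cls, , drop = FALSE]
    n_in <- sum(vapply(seq_len(nrow(s)), function(i) {
      oracle_in_iv(s$chrom[i], s$pos0[i], iv)
    }, logical(1)))
    cls_len <- 0L
    nr_len <- 0
    for (cn in names(genome$seq)) {
      L <- genome$lengths[[cn]]
      in_cls <- logical(L); in_mask <- logical(L)
      d <- iv[iv$chrom == cn, , drop = FALSE]
      for (j in seq_len(nrow(d))) in_cls[(d$start[j] + 1L):d$end[j]] <- TRUE
      dm <- mask[mask$chrom == cn, , drop = FALSE]
      for (j in seq_len(nrow(dm))) {
        in_mask[(dm$start[j] + 1L):dm$end[j]] <- TRUE
      }
      cls_len <- cls_len + sum(in_cls & !in_mask)
      nr_len <- nr_len + sum(!in_mask)
    }
    out[[cls]] <- list(odds_ratio = (n_in / nrow(s)) /
                         (cls_len / genome$nonrepeat_len),
                       n_obs = n_in, n_total = nrow(s))
  }
  out
}

# Upstream thymine fraction of one read-2 alignment, by character loop.
oracle_polyA_tfrac <- function(genome, chrom, p5, strand, window = 20L) {
  s <- strsplit(genome$seq[[chrom]], "")[[1]]
  L <- length(s)
  if (strand == "+") {
    idx <- (p5 - window):(p5 - 1L)   # 0-based upstream positions
    idx <- idx[idx >= 0L]
    if (!length(idx)) return(NaN)
    mean(s[idx + 1L] == "T")
  } else {
    idx <- (p5 + 1L):(p5 + window)
    idx <- idx[idx <= L - 1L]
    if (!length(idx)) return(NaN)
    mean(chartr("ACGT", "TGCA", s[idx + 1L]) == "T")
  }
}

# Spike hotspot scan: value above threshold and above both neighbours.
oracle_spike_hotspots <- function(df, threshold, value = "rel_depth") {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    v <- df[[value]][i]
    nb <- function(dp) {
      j <- which(df$chrom == df$chrom[i] & df$strand == df$strand[i] &
                   df$pos0 == df$pos0[i] + dp)
      if (length(j)) df[[value]][j] else 0
    }
    keep[i] <- v > threshold && v > nb(-1L) && v > nb(1L)
  }
  df[keep, , drop = FALSE]
}

# Group-specific hotspot definition evaluated position by position.
oracle_group_specific <- function(site_list, groups, min_depth = 2L,
                                  min_samples = 2L, max_other = 1L) {
  all_keys <- unique(unlist(lapply(site_list, function(s) {
    paste(s$sites$chrom, s$sites$pos0, s$sites$strand, sep = ":")
  })))
  depth_of <- function(s, key) {
    k <- paste(s$sites$chrom, s$sites$pos0, s$sites$strand, sep = ":")
    i <- match(key, k)
    if (is.na(i)) 0L else s$sites$depth[i]
  }
  out <- list()
  for (g in unique(groups)) {
    hits <- character()
    for (key in all_keys) {
      n_in <- sum(vapply(which(groups == g), function(i) {
        depth_of(site_list[[i]], key) >= min_depth
      }, logical(1)))
      ok_out <- all(vapply(which(groups != g), function(i) {
        depth_of(site_list[[i]], key) <= max_other
      }, logical(1)))
      if (n_in >= min_samples && ok_out) hits <- c(hits, key)
    }
    out[[g]] <- sort(hits)
  }
  out
}

# Group-shared hotspot count (the permutation statistic), brute force.
oracle_group_shared_count <- function(keysets, groups, min_samples = 2L) {
  tot <- 0L
  for (g in unique(groups)) {
    pool <- unlist(keysets[groups == g], use.names = FALSE)
    if (length(pool)) tot <- tot + sum(table(pool) >= min_samples)
  }
  tot
}
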