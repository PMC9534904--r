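#' Simulation parameters
#'
#' Bundles the tunable parameters of the protocol simulator. Defaults follow
#' the study conditions the pipeline is designed for: per-nucleotide site
#' weights favouring purines (A 0.39, G 0.31, C 0.15, T 0.15), a 1.5%
#' unblocked-3'OH background, tag runs of 9-11 G and 11-13 T, and 400 bp
#' fragments.
#'
#' @param n_site_reads Total lesion-derived read pairs to emit.
#' @param purine_weights Named weights (A, G, C, T) for the base identity of
#'   planted sites.
#' @param hotspot_count Number of planted multi-read hotspot positions.
#' @param hotspot_depth_range Integer range of reads per hotspot.
#' @param unblocked_background_rate Fraction of reads emitted from random
#'   unblocked fragment 3' ends rather than lesions.
#' @param duplicate_rate Fraction of emitted reads that are PCR duplicates.
#' @param read_len Read length before tag trimming.
#' @param g_run_len,t_run_len Integer vectors of admissible tag-run lengths.
#' @param element_enrichment Named multipliers applied to the sampling weight
#'   of positions inside annotation classes (e.g. `c(exon = 3)`).
#' @param strand_asymmetry Template:nontemplate weight ratio applied within
#'   expressed genes (TPM > 1); 1 means no asymmetry.
#' @param fragment_len Fragment length around each lesion.
#' @param seed Integer seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_site_reads = 20000,
                       purine_weights = c(A = 0.39, G = 0.31,
                                          C = 0.15, T = 0.15),
                       hotspot_count = 200,
                       hotspot_depth_range = c(2L, 5L),
                       unblocked_background_rate = 0.015,
                       duplicate_rate = 0.1,
                       read_len = 100L,
                       g_run_len = 9:11,
                       t_run_len = 11:13,
                       element_enrichment = NULL,
                       strand_asymmetry = 1,
                       fragment_len = 400L,
                       seed = 1L) {
  stopifnot(all(c("A", "G", "C", "T") %in% names(purine_weights)),
            all(purine_weights >= 0), any(purine_weights > 0),
            unblocked_background_rate >= 0, unblocked_background_rate <= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            all(g_run_len >= 9 & g_run_len <= 11),
            all(t_run_len >= 11 & t_run_len <= 13))
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

# Weighted sampling without replacement via exponential races: one pass,
# deterministic under the RNG state, linear in the candidate count.
weighted_draw <- function(n, w) {
  keys <- stats::rexp(length(w)) / w
  order(keys)[seq_len(n)]
}

#' Plant lesion sites on a simulated genome
#'
#' Samples stranded single-nucleotide positions with per-nucleotide weights,
#' optional per-annotation-class enrichment multipliers and a
#' template-strand weighting within expressed genes. Positions are
#' restricted to single-base-callable sites: far enough from chromosome
#' ends to carry a full fragment, not preceded (in read orientation) by a
#' base that would be absorbed into the polyT tag, and not upstream-T-rich
#' (such positions are invisible to the pipeline by design, so planting
#' them would only blur ground truth).
#'
#' @param genome A `genome` object.
#' @param annotations Named list of interval data frames (as from
#'   [sim_genome()]); used for enrichment multipliers and strand asymmetry.
#' @param params A [sim_params()] object.
#' @param expression Optional gene-expression data frame (gene, tpm) for the
#'   strand-asymmetry weighting.
#' @return Data frame of truth sites: `chrom`, `pos0`, `strand`,
#'   `expected_reads`, `hotspot`.
#' @export
plant_sites <- function(genome, annotations = NULL, params = sim_params(),
                        expression = NULL) {
  set.seed(params$seed)
  pw <- params$purine_weights
  frag <- params$fragment_len
  win <- 20L
  cand <- list()
  for (cn in names(genome$seq)) {
    L <- genome$lengths[[cn]]
    if (L < 2L * frag + 2L) next
    bases <- strsplit(genome$seq[[cn]], "")[[1]]
    cA <- c(0L, cumsum(bases == "A"))
    cT <- c(0L, cumsum(bases == "T"))
    pos <- frag:(L - 1L - frag)          # margin for fragment + reads
    # plus-strand sites: base at pos; 5' terminus base (pos-1) must not be
    # A (read as T, absorbed into the tag); upstream window of the minus-
    # strand read 2 is ref [pos, pos+win) whose minus-strand T's are plus A's
    a_frac <- (cA[pos + win + 1L] - cA[pos + 1L]) / win
    site_b <- bases[pos + 1L]
    ok_p <- site_b != "N" & bases[pos] != "A" & a_frac <= 0.4
    wp <- ifelse(ok_p, pw[site_b], 0)
    # minus-strand sites: base is the complement; terminus base (pos+1 on
    # ref) must not be T; upstream window is ref [pos-win+1, pos+1)
    t_frac <- (cT[pos + 2L] - cT[pos - win + 2L]) / win
    cb <- chartr("ACGTN", "TGCAN", site_b)
    ok_m <- site_b != "N" & bases[pos + 2L] != "T" & t_frac <= 0.4
    wm <- ifelse(ok_m, pw[cb], 0)
    cand[[cn]] <- data.frame(
      chrom = cn, pos0 = c(pos, pos), strand = rep(c("+", "-"),
                                                   each = length(pos)),
      w = c(wp, wm))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[cand$w > 0, , drop = FALSE]

  # element enrichment: the requested multiplier is the target odds ratio
  # (in-class site fraction over in-class length fraction), so the raw
  # weight applied is m(W - We) / (W - m We), which yields OR = m after
  # renormalisation over the whole genome
  ee <- params$element_enrichment
  if (!is.null(ee) && !is.null(annotations)) {
    all_iv <- do.call(rbind, unname(annotations))
    for (cls in names(ee)) {
      iv <- all_iv[all_iv$class == cls, , drop = FALSE]
      if (!nrow(iv)) next
      hit <- pos_in_intervals(cand$chrom, cand$pos0, iv)
      m <- ee[[cls]]
      W <- sum(cand$w); We <- sum(cand$w[hit])
      if (m * We >= W) stop("enrichment target infeasible for ", cls)
      cand$w[hit] <- cand$w[hit] * m * (W - We) / (W - m * We)
    }
  }
  # strand asymmetry within expressed genes: template strand is the strand
  # opposite the gene's
  if (params$strand_asymmetry != 1 && !is.null(annotations) &&
      !is.null(expression)) {
    genes <- annotations$genes
    expressed <- expression$gene[expression$tpm > 1]
    gsel <- genes[genes$name %in% expressed, , drop = FALSE]
    if (nrow(gsel)) {
      hits <- pos_interval_hits(cand$chrom, cand$pos0, gsel)
      is_templ <- cand$strand[hits$pos] != gsel$strand[match(
        hits$iv, seq_len(nrow(gsel)))]
      idx <- unique(hits$pos[is_templ])
      cand$w[idx] <- cand$w[idx] * params$strand_asymmetry
    }
  }

  hot_depth <- sample(params$hotspot_depth_range[1]:
                        params$hotspot_depth_range[2],
                      params$hotspot_count, replace = TRUE)
  n_single <- params$n_site_reads - sum(hot_depth)
  if (n_single < 0L) stop("hotspot reads exceed n_site_reads")
  n_distinct <- params$hotspot_count + n_single
  if (n_distinct > nrow(cand)) {
    stop("requested sites exceed available callable positions")
  }
  idx <- weighted_draw(n_distinct, cand$w)
  out <- cand[idx, c("chrom", "pos0", "strand")]
  out$expected_reads <- c(hot_depth, rep(1L, n_single))
  out$hotspot <- c(rep(TRUE, params$hotspot_count), rep(FALSE, n_single))
  rownames(out) <- NULL
  out
}

# Emit one read pair per molecule given site coordinates.
# Returns r1/r2 sequences plus template alignment coordinates.
emit_pairs <- function(genome, chrom, pos0, strand, params) {
  n <- length(pos0)
  t_run <- sample(params$t_run_len, n, replace = TRUE)
  g_run <- sample(params$g_run_len, n, replace = TRUE)
  L2 <- params$read_len - t_run
  L1 <- params$read_len - 10L - g_run
  frag <- params$fragment_len
  r1g <- r2g <- character(n)
  r1_pos <- r2_left <- integer(n)
  for (cn in unique(chrom)) {
    s <- genome$seq[[cn]]
    i <- which(chrom == cn)
    ip <- i[strand[i] == "+"]; im <- i[strand[i] == "-"]
    if (length(ip)) {
      P <- pos0[ip]
      r2g[ip] <- revcomp(substring(s, P - L2[ip] + 1L, P))
      off <- floor(stats::runif(length(ip)) *
                     (frag - L1[ip] - 21L))       # r1 start within fragment
      a <- P - frag + off
      # the read-1 genomic portion must not start with G, which would be
      # absorbed into the tag's G-run; its placement is free, so nudge it
      for (k in 1:20) {
        isg <- substring(s, a + 1L, a + 1L) == "G"
        if (!any(isg)) break
        a[isg] <- a[isg] + 1L
      }
      r1g[ip] <- substring(s, a + 1L, a + L1[ip])
      r1_pos[ip] <- a
      r2_left[ip] <- P - L2[ip]
    }
    if (length(im)) {
      P <- pos0[im]
      r2g[im] <- substring(s, P + 2L, P + 1L + L2[im])
      off <- floor(stats::runif(length(im)) * (frag - L1[im] - 21L))
      e <- P + frag - off                         # r1 3'-side right end
      # first read-1 base is the complement of base e: avoid reference C
      for (k in 1:20) {
        isc <- substring(s, e + 1L, e + 1L) == "C"
        if (!any(isc)) break
        e[isc] <- e[isc] - 1L
      }
      r1g[im] <- revcomp(substring(s, e - L1[im] + 2L, e + 1L))
      r1_pos[im] <- e - L1[im] + 1L
      r2_left[im] <- P + 1L
    }
  }
  list(
    r1 = paste0("AGTTGCGGAT", strrep("G", g_run), r1g),
    r2 = paste0(strrep("T", t_run), r2g),
    r1_pos0 = r1_pos, r2_left0 = r2_left,
    r2_strand = ifelse(strand == "+", "-", "+"))
}

#' Simulate tagged read pairs from planted sites
#'
#' Emits, for every expected read of every truth site, a read pair with the
#' protocol's tag structure: read 1 starts with AGTTGCGGAT plus a G-run,
#' read 2 with a T-run followed by the reverse complement of the damaged
#' strand starting at the base 5' of the lesion. Unblocked background pairs
#' are emitted from random fragment 3' ends, and PCR duplicates are exact
#' re-emissions of existing molecules. Deterministic for the seed carried in
#' `params`.
#'
#' @param genome A `genome` object.
#' @param truth Truth-site data frame from [plant_sites()].
#' @param params A [sim_params()] object.
#' @return A list: `r1`, `r2` (named character vectors of read sequences),
#'   `reads` (per-read data frame with `name`, `category`
#'   ("site"/"background"/"duplicate"), `site_index`, `template_id`), and
#'   `templates` (one row per distinct molecule with its true alignment
#'   coordinates).
#' @export
simulate_reads <- function(genome, truth, params = sim_params()) {
  set.seed(params$seed + 1L)
  if (params$read_len > params$fragment_len) {
    stop("read_len longer than fragment")
  }
  site_idx <- rep(seq_len(nrow(truth)), truth$expected_reads)
  n_site <- length(site_idx)
  rate <- params$unblocked_background_rate
  n_bg <- round(n_site * rate / (1 - rate))
  frag <- params$fragment_len
  bg <- if (n_bg > 0) {
    cn <- sample(names(genome$seq), n_bg, replace = TRUE,
                 prob = as.numeric(genome$lengths))
    L <- genome$lengths[cn]
    data.frame(chrom = cn,
               pos0 = frag + floor(stats::runif(n_bg) * (L - 2L * frag)),
               strand = sample(c("+", "-"), n_bg, replace = TRUE))
  } else data.frame(chrom = character(), pos0 = integer(),
                    strand = character())
  chrom <- c(truth$chrom[site_idx], bg$chrom)
  pos0 <- c(truth$pos0[site_idx], bg$pos0)
  strand <- c(truth$strand[site_idx], bg$strand)
  em <- emit_pairs(genome, chrom, pos0, strand, params)
  n_templ <- length(chrom)
  templates <- data.frame(
    template_id = seq_len(n_templ), chrom = chrom, pos0 = pos0,
    strand = strand,
    category = c(rep("site", n_site), rep("background", nrow(bg))),
    site_index = c(site_idx, rep(NA_integer_, nrow(bg))),
    r1_pos0 = em$r1_pos0, r2_left0 = em$r2_left0,
    r2_strand = em$r2_strand)
  n_dup <- round(n_templ * params$duplicate_rate /
                   (1 - params$duplicate_rate))
  dup_of <- if (n_dup > 0) sample.int(n_templ, n_dup, replace = TRUE) else
    integer()
  ord <- c(seq_len(n_templ), dup_of)
  nm <- sprintf("mol%06d%s", ord,
                c(rep("", n_templ),
                  sprintf(".d%d", seq_along(dup_of))))
  reads <- data.frame(
    name = nm, category = c(templates$category, rep("duplicate", n_dup)),
    site_index = templates$site_index[ord],
    template_id = ord)
  r1 <- em$r1[ord]; r2 <- em$r2[ord]
  names(r1) <- names(r2) <- nm
  list(r1 = r1, r2 = r2, reads = reads, templates = templates)
}

#' Generate synthetic spike-in sequences
#'
#' Random sequences designed for clean single-base lesion localisation: the
#' dinucleotides AA, AT and TT never occur, so a planted lesion at a
#' thymine (or a ragged unblocked terminus) is never preceded by bases that
#' the tag trimmer would absorb. Real spike-in design applies the same kind
#' of context constraint.
#'
#' @param lengths Integer vector of spike lengths (>= 100).
#' @param seed Integer seed.
#' @return Named character vector of sequences ("spike1", ...).
#' @export
make_spike_seqs <- function(lengths = c(150L, 200L, 250L), seed = 1L) {
  set.seed(seed)
  stopifnot(all(lengths >= 100L))
  nxt <- list(A = c("C", "G"), T = c("A", "C", "G"),
              C = c("A", "C", "G", "T"), G = c("A", "C", "G", "T"))
  out <- vapply(lengths, function(L) {
    s <- character(L)
    # first base C (a leading G would extend the read-1 tag G-run); last
    # base not C (its complement leads read 1 from the other end)
    s[1] <- "C"
    for (i in 2:L) s[i] <- sample(nxt[[s[i - 1L]]], 1L)
    if (s[L] == "C") s[L] <- "G"
    paste(s, collapse = "")
  }, "")
  names(out) <- sprintf("spike%d", seq_along(out))
  out
}

#' Simulate spike-in read pairs
#'
#' Positive mode plants lesions at thymine positions on either strand with
#' probability `du_rate` per T (emulating uracil incorporation at a 1:125
#' dUTP:dTTP ratio, i.e. 1/126 per T, followed by UDG excision); negative
#' mode plants a 10x smaller spontaneous-depurination rate at purines;
#' unblocked mode emits all reads from ragged 3' termini. In positive and
#' negative modes a fraction `unblocked_frac` of reads additionally comes
#' from unblocked termini.
#'
#' @param spike_seqs Named character vector of spike sequences (>= 100 bp),
#'   e.g. from [make_spike_seqs()].
#' @param mode "positive", "negative" or "unblocked".
#' @param du_rate Per-thymine lesion probability (positive mode).
#' @param n_reads Total read pairs to emit.
#' @param unblocked_frac Fraction of reads from unblocked 3' termini.
#' @param read_len,t_run_len,g_run_len Read-structure parameters.
#' @param seed Integer seed.
#' @return A list: `r1`, `r2`, `truth` (planted sites with `chrom`, `pos0`,
#'   `strand`), `reads` (per-read map), `genome` (spike `genome` object).
#' @export
make_spike_reads <- function(spike_seqs, mode = c("positive", "negative",
                                                  "unblocked"),
                             du_rate = 1 / 126, n_reads = 10000L,
                             unblocked_frac = 0.01, read_len = 100L,
                             t_run_len = 11:13, g_run_len = 9:11,
                             seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  stopifnot(all(nchar(spike_seqs) >= 100L))
  sg <- genome_from_seqs(toupper(spike_seqs))
  # candidate lesion positions, keeping clear of the 4 terminal bases of
  # each strand (reserved for the unblocked-background window)
  cands <- list()
  for (cn in names(sg$seq)) {
    b <- strsplit(sg$seq[[cn]], "")[[1]]
    L <- length(b)
    tgt <- if (mode == "negative") c("A", "G") else "T"
    # read 2 extends from the lesion toward the strand's 5' end: keep 20
    # bases of mappable context there, and stay out of the 4-base 3'
    # terminal background window
    pp <- which(b %in% tgt) - 1L                      # plus strand
    pp <- pp[pp >= 20L & pp <= L - 5L]
    pm <- which(chartr("ACGT", "TGCA", b) %in% tgt) - 1L  # minus strand
    pm <- pm[pm >= 4L & pm <= L - 21L]
    cands[[cn]] <- data.frame(
      chrom = cn, pos0 = c(pp, pm),
      strand = rep(c("+", "-"), c(length(pp), length(pm))))
  }
  cands <- do.call(rbind, cands)
  rate <- switch(mode, positive = du_rate, negative = du_rate / 10,
                 unblocked = 0)
  keep <- stats::runif(nrow(cands)) < rate
  truth <- cands[keep, , drop = FALSE]
  rownames(truth) <- NULL
  if (mode != "unblocked" && nrow(truth) == 0L) {
    stop("no lesions planted; increase du_rate or spike length")
  }
  ub_frac <- if (mode == "unblocked") 1 else unblocked_frac
  n_bg <- round(n_reads * ub_frac)
  n_site <- n_reads - n_bg
  site_idx <- if (n_site > 0) sample.int(nrow(truth), n_site, replace = TRUE)
              else integer()
  # ragged unblocked termini within 3 bases of each strand's 3' end, so the
  # called spurious sites land inside the 4-base background window
  bg <- if (n_bg > 0) {
    cn <- sample(names(sg$seq), n_bg, replace = TRUE,
                 prob = as.numeric(sg$lengths))
    st <- sample(c("+", "-"), n_bg, replace = TRUE)
    L <- sg$lengths[cn]
    q <- ifelse(st == "+", L - 1L - sample(1:3, n_bg, replace = TRUE),
                sample(1:3, n_bg, replace = TRUE))
    # pseudo-site one base past the terminus along the damaged strand
    data.frame(chrom = cn, pos0 = as.integer(ifelse(st == "+", q + 1L,
                                                    q - 1L)),
               strand = st)
  } else data.frame(chrom = character(), pos0 = integer(),
                    strand = character())
  chrom <- c(truth$chrom[site_idx], bg$chrom)
  pos0 <- c(truth$pos0[site_idx], bg$pos0)
  strand <- c(truth$strand[site_idx], bg$strand)

  n <- length(pos0)
  t_run <- sample(t_run_len, n, replace = TRUE)
  g_run <- sample(g_run_len, n, replace = TRUE)
  L2 <- read_len - t_run
  L1 <- read_len - 10L - g_run
  r1g <- r2g <- character(n)
  for (cn in unique(chrom)) {
    s <- sg$seq[[cn]]
    L <- sg$lengths[[cn]]
    i <- which(chrom == cn)
    ip <- i[strand[i] == "+"]; im <- i[strand[i] == "-"]
    if (length(ip)) {
      P <- pos0[ip]
      r2g[ip] <- revcomp(substring(s, pmax(1L, P - L2[ip] + 1L), P))
      r1g[ip] <- substring(s, 1L, pmin(L1[ip], L))
    }
    if (length(im)) {
      P <- pos0[im]
      r2g[im] <- substring(s, P + 2L, pmin(P + 1L + L2[im], L))
      r1g[im] <- revcomp(substring(s, pmax(1L, L - L1[im] + 1L), L))
    }
  }
  nm <- sprintf("spk%06d", seq_len(n))
  r1 <- stats::setNames(paste0("AGTTGCGGAT", strrep("G", g_run), r1g), nm)
  r2 <- stats::setNames(paste0(strrep("T", t_run), r2g), nm)
  reads <- data.frame(
    name = nm,
    category = rep(c("site", "background"), c(length(site_idx), nrow(bg))),
    site_index = c(site_idx, rep(NA_integer_, nrow(bg))))
  list(r1 = r1, r2 = r2, truth = truth, reads = reads, genome = sg)
}

#' Write reads as FASTQ
#'
#' @param reads Named character vector of sequences.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4L * length(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", names(reads))
  out[c(FALSE, TRUE, FALSE, FALSE)] <- unname(reads)
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- strrep("I", nchar(reads))
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path.
#' @return Named character vector of sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Align read pairs to a genome by exact matching
#'
#' A toy aligner for simulated data: each (tag-trimmed) read is located by
#' exact substring search on both strands. Unique hits get MAPQ 60;
#' multi-mappers MAPQ 0; proper pairs (mates unique, same chromosome,
#' opposite strands, within `max_insert`) get the standard 99/147 or 83/163
#' flag pairs. Stored sequences follow the SAM convention (reverse-
#' complemented for minus-strand alignments).
#'
#' @param r1,r2 Named character vectors of trimmed read sequences (names are
#'   read names; shared between mates).
#' @param genome A `genome` object.
#' @param max_insert Maximum leftmost-coordinate distance for a proper pair.
#' @return A pair data frame in the layout of [load_alignments()].
#' @export
align_exact <- function(r1, r2, genome, max_insert = 1000L) {
  stopifnot(identical(names(r1), names(r2)))
  loc1 <- locate_exact(r1, genome)
  loc2 <- locate_exact(r2, genome)
  n <- length(r1)
  proper <- !is.na(loc1$chrom) & !is.na(loc2$chrom) &
    loc1$nhits == 1L & loc2$nhits == 1L &
    loc1$chrom == loc2$chrom & loc1$strand != loc2$strand &
    abs(loc1$pos0 - loc2$pos0) <= max_insert
  flag1 <- 64L + 1L + ifelse(is.na(loc1$chrom), 4L, 0L) +
    ifelse(!is.na(loc1$chrom) & loc1$strand == "-", 16L, 0L) +
    ifelse(!is.na(loc2$chrom) & loc2$strand == "-", 32L, 0L) +
    ifelse(is.na(loc2$chrom), 8L, 0L) + ifelse(proper, 2L, 0L)
  flag2 <- 128L + 1L + ifelse(is.na(loc2$chrom), 4L, 0L) +
    ifelse(!is.na(loc2$chrom) & loc2$strand == "-", 16L, 0L) +
    ifelse(!is.na(loc1$chrom) & loc1$strand == "-", 32L, 0L) +
    ifelse(is.na(loc1$chrom), 8L, 0L) + ifelse(proper, 2L, 0L)
  mapq <- function(loc) ifelse(is.na(loc$chrom), 0L,
                               ifelse(loc$nhits == 1L, 60L, 0L))
  sam_seq <- function(reads, loc) {
    out <- unname(reads)
    i <- which(!is.na(loc$chrom) & loc$strand == "-")
    if (length(i)) out[i] <- revcomp(out[i])
    out
  }
  data.frame(
    name = names(r1),
    r1_chrom = loc1$chrom, r1_pos0 = loc1$pos0, r1_strand = loc1$strand,
    r1_mapq = mapq(loc1), r1_flag = flag1,
    r1_cigar = ifelse(is.na(loc1$chrom), "*", paste0(nchar(r1), "M")),
    r1_seq = sam_seq(r1, loc1),
    r2_chrom = loc2$chrom, r2_pos0 = loc2$pos0, r2_strand = loc2$strand,
    r2_mapq = mapq(loc2), r2_flag = flag2,
    r2_cigar = ifelse(is.na(loc2$chrom), "*", paste0(nchar(r2), "M")),
    r2_seq = sam_seq(r2, loc2),
    stringsAsFactors = FALSE)
}

# Exact search of reads against both strands; equal-width groups are matched
# with a PDict for speed.
locate_exact <- function(reads, genome) {
  n <- length(reads)
  res <- data.frame(chrom = rep(NA_character_, n),
                    pos0 = rep(NA_integer_, n),
                    strand = rep(NA_character_, n),
                    nhits = rep(0L, n))
  u <- unique(unname(reads))
  u <- u[nzchar(u) & !grepl("[^ACGT]", u)]
  if (!length(u)) return(res)
  hits_chrom <- rep(NA_character_, length(u))
  hits_pos <- rep(NA_integer_, length(u))
  hits_strand <- rep(NA_character_, length(u))
  hits_n <- integer(length(u))
  subjects <- lapply(genome$seq, Biostrings::DNAString)
  for (w in unique(nchar(u))) {
    gi <- which(nchar(u) == w)
    fwd <- Biostrings::DNAStringSet(u[gi])
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(fwd))
    for (cn in names(subjects)) {
      for (sd in c("+", "-")) {
        pd <- if (sd == "+") pd_f else pd_r
        m <- Biostrings::matchPDict(pd, subjects[[cn]])
        cnt <- S4Vectors::elementNROWS(m)
        hit <- which(cnt > 0L)
        for (k in hit) {
          j <- gi[k]
          if (hits_n[j] == 0L) {
            hits_chrom[j] <- cn
            hits_pos[j] <- IRanges::start(m[[k]])[1] - 1L
            hits_strand[j] <- sd
          }
          hits_n[j] <- hits_n[j] + cnt[k]
        }
      }
    }
  }
  idx <- match(unname(reads), u)
  ok <- !is.na(idx)
  res$chrom[ok] <- hits_chrom[idx[ok]]
  res$pos0[ok] <- hits_pos[idx[ok]]
  res$strand[ok] <- hits_strand[idx[ok]]
  res$nhits[ok] <- hits_n[idx[ok]]
  res$chrom[res$nhits == 0L] <- NA_character_
  res
}
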