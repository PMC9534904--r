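#' Pairwise overlap odds ratio between two position sets
#'
#' Technical-reproducibility style overlap: the expected fraction is the
#' size of set A divided by the (double-stranded) genome length; the
#' observed fraction is the number of positions shared by both sets divided
#' by the size of set B. OR = observed / expected. Computed over the whole
#' genome, repeats included.
#'
#' @param setA,setB `ap_sites` objects or position data frames
#'   (chrom/pos0/strand); A plays the role of replica 1, B of replica 2.
#' @param genome_positions Size of the stranded position space: 2 x the
#'   genome length in bp (positions are stranded).
#' @return An enrichment row (data frame) with observed/expected fractions,
#'   `odds_ratio`, counts and a two-sided exact binomial p-value.
#' @export
or_pairwise <- function(setA, setB, genome_positions) {
  ka <- site_keys(setA); kb <- site_keys(setB)
  if (length(kb) == 0L) {
    return(enrich_row("pairwise", "overlap", NA, length(ka) /
                        genome_positions, 0L, 0L))
  }
  n_shared <- sum(kb %in% ka)
  obs <- n_shared / length(kb)
  exp_ <- length(ka) / genome_positions
  enrich_row("pairwise", "overlap", obs, exp_, n_shared, length(kb))
}

enrich_row <- function(mode, class, obs, exp_, n_obs, n_total) {
  p <- if (!is.na(obs) && n_total > 0 && exp_ > 0 && exp_ < 1) {
    stats::binom.test(n_obs, n_total, exp_)$p.value
  } else NA_real_
  data.frame(mode = mode, feature_class = class,
             observed_frac = obs, expected_frac = exp_,
             odds_ratio = if (!is.na(obs) && exp_ > 0) obs / exp_ else
               NA_real_,
             n_obs = n_obs, n_total = n_total, p_two_sided = p,
             stringsAsFactors = FALSE)
}

#' Read-level enrichment of sites in repeat classes
#'
#' For each repeat class: observed = site reads falling in the class /
#' total site reads (sites with the same coordinates counted separately,
#' i.e. depth-weighted); expected = merged class length / genome length.
#'
#' @param sites An `ap_sites` object.
#' @param repeat_classes Interval data frame with a `class` column.
#' @param genome_len Single-strand genome length in bp.
#' @return Data frame with one enrichment row per class.
#' @export
or_repeats <- function(sites, repeat_classes, genome_len) {
  s <- sites$sites
  tot_reads <- sum(s$depth)
  lens <- class_lengths(repeat_classes)
  rows <- lapply(names(lens), function(cls) {
    iv <- repeat_classes[repeat_classes$class == cls, , drop = FALSE]
    hit <- pos_in_intervals(s$chrom, s$pos0, iv)
    n_obs <- sum(s$depth[hit])
    enrich_row("repeats", cls,
               if (tot_reads > 0) n_obs / tot_reads else NA_real_,
               lens[[cls]] / genome_len, n_obs, tot_reads)
  })
  do.call(rbind, rows)
}

#' Collapsed-site enrichment in genomic element classes
#'
#' Repeat-masked, position-level enrichment: sites falling in repeats are
#' removed and duplicate coordinates count once. For each element class:
#' observed = distinct non-repeat sites in the class / all distinct
#' non-repeat sites; expected = non-repeat bases of the class / non-repeat
#' genome length.
#'
#' @param sites An `ap_sites` object.
#' @param elements Interval data frame with a `class` column.
#' @param genome A `genome` object (supplies the repeat mask and
#'   non-repeat length).
#' @return Data frame with one enrichment row per class.
#' @export
or_elements <- function(sites, elements, genome) {
  s <- sites$sites
  mask <- merge_intervals(genome$repeat_mask)
  if (!is.null(mask) && nrow(mask)) {
    s <- s[!pos_in_intervals(s$chrom, s$pos0, mask), , drop = FALSE]
  }
  n_total <- nrow(s)                       # collapsed: one row per position
  lens <- nonrepeat_class_lengths(elements, mask)
  rows <- lapply(names(lens), function(cls) {
    iv <- elements[elements$class == cls, , drop = FALSE]
    n_obs <- sum(pos_in_intervals(s$chrom, s$pos0, iv))
    exp_ <- lens[[cls]] / genome$nonrepeat_len
    if (exp_ == 0) {
      return(enrich_row("elements", cls, NA_real_, 0, n_obs, n_total))
    }
    enrich_row("elements", cls,
               if (n_total > 0) n_obs / n_total else NA_real_,
               exp_, n_obs, n_total)
  })
  do.call(rbind, rows)
}

#' Template vs nontemplate strand ratio per element class
#'
#' For stranded elements, a site on the strand opposite the element's is on
#' the template (transcribed) strand; a site on the same strand is
#' nontemplate. Sites overlapping several elements count once per
#' overlapping element.
#'
#' @param sites An `ap_sites` object (positions counted once each).
#' @param elements Stranded interval data frame with a `class` column.
#' @return Data frame per class: `template_count`, `nontemplate_count`,
#'   `ratio` (NA when the nontemplate count is zero).
#' @export
template_nontemplate_ratio <- function(sites, elements) {
  s <- sites$sites
  rows <- lapply(split(elements, elements$class), function(iv) {
    hits <- pos_interval_hits(s$chrom, s$pos0, iv)
    is_templ <- s$strand[hits$pos] != iv$strand[match(hits$iv,
                                                      seq_len(nrow(iv)))]
    tc <- sum(is_templ); nc <- sum(!is_templ)
    data.frame(feature_class = iv$class[1], template_count = tc,
               nontemplate_count = nc,
               ratio = if (nc > 0) tc / nc else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expression-stratified element enrichment, density and strand ratios
#'
#' Genes are split into three strata (TPM <= 1 nonexpressed, 1 < TPM <= 10
#' low, TPM > 10 high); the elements of each stratum get an element-level
#' odds ratio, per-strand site densities (distinct sites per element bp)
#' and a template/nontemplate ratio.
#'
#' @param sites An `ap_sites` object.
#' @param elements Stranded interval data frame whose `name` column carries
#'   the owning gene.
#' @param expression Data frame gene/tpm; genes without a TPM are treated
#'   as nonexpressed with a warning.
#' @param genome A `genome` object.
#' @return Data frame per stratum with odds ratio, densities and ratio.
#' @export
stratify_and_density <- function(sites, elements, expression, genome) {
  tpm <- expression$tpm[match(elements$name, expression$gene)]
  if (anyNA(tpm)) {
    warning("elements without TPM assigned to the nonexpressed stratum")
    tpm[is.na(tpm)] <- 0
  }
  stratum <- ifelse(tpm <= 1, "nonexpressed",
                    ifelse(tpm <= 10, "low", "high"))
  s <- sites$sites
  rows <- lapply(c("nonexpressed", "low", "high"), function(st) {
    iv <- elements[stratum == st, , drop = FALSE]
    if (nrow(iv) == 0L) return(NULL)
    iv$class <- st
    orr <- or_elements(sites, iv, genome)
    tlen <- masked_bases(iv)
    hits <- pos_interval_hits(s$chrom, s$pos0, iv)
    upos <- unique(hits$pos)
    n_plus <- sum(s$strand[upos] == "+")
    n_minus <- sum(s$strand[upos] == "-")
    tn <- template_nontemplate_ratio(sites, iv)
    data.frame(stratum = st, n_elements = nrow(iv), element_bp = tlen,
               odds_ratio = orr$odds_ratio,
               density_plus = n_plus / tlen,
               density_minus = n_minus / tlen,
               template_ratio = tn$ratio)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nucleotide composition of sites at increasing depth thresholds
#'
#' For each minimum depth, the fraction of distinct sites whose genomic
#' base, read on the site's strand, is A, C, G or T, next to the background
#' composition of the non-repeat genome over both strands. Sites over N
#' bases are excluded and counted.
#'
#' @param sites An `ap_sites` object.
#' @param genome A `genome` object.
#' @param min_depths Integer vector of depth thresholds.
#' @return A list: `composition` (data frame per threshold) and
#'   `background` (named A/C/G/T fractions), plus `n_excluded_N`.
#' @export
nucleotide_composition <- function(sites, genome, min_depths = c(1L, 2L,
                                                                 3L)) {
  s <- sites$sites
  b <- if (nrow(s)) genome_base(genome, s$chrom, s$pos0, s$strand) else
    character()
  keep <- b != "N"
  rows <- lapply(min_depths, function(d) {
    i <- keep & s$depth >= d
    f <- table(factor(b[i], levels = c("A", "C", "G", "T"))) / sum(i)
    data.frame(min_depth = d, n_sites = sum(i), A = f[["A"]], C = f[["C"]],
               G = f[["G"]], T = f[["T"]])
  })
  bg <- nonrepeat_background_composition(genome)
  list(composition = do.call(rbind, rows), background = bg,
       n_excluded_N = sum(!keep))
}

# Base composition of the non-repeat genome over both strands: the
# double-stranded fraction of A equals (A + T)/(2N) of the plus strand.
nonrepeat_background_composition <- function(genome) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  mask <- merge_intervals(genome$repeat_mask)
  for (cn in names(genome$seq)) {
    r <- IRanges::IRanges(1L, genome$lengths[[cn]])
    if (!is.null(mask) && nrow(mask)) {
      m <- mask[mask$chrom == cn, , drop = FALSE]
      if (nrow(m)) {
        r <- IRanges::setdiff(r, IRanges::IRanges(m$start + 1L, m$end))
      }
    }
    if (!length(r)) next
    v <- Biostrings::Views(Biostrings::DNAString(genome$seq[[cn]]), r)
    n <- colSums(Biostrings::letterFrequency(v, c("A", "C", "G", "T")))
    counts <- counts + n
  }
  tot <- 2 * sum(counts)
  c(A = unname(counts["A"] + counts["T"]), C = unname(counts["C"] +
                                                        counts["G"]),
    G = unname(counts["G"] + counts["C"]), T = unname(counts["T"] +
                                                        counts["A"])) / tot
}

#' Shared-step technical bias as a coefficient of determination
#'
#' Squared Pearson correlation between the read depths of a sample and of
#' its unblocked control over the sample's site (or hotspot) positions,
#' depth 0 where the control lacks the position: the variance attributable
#' to steps shared with the unblocked control.
#'
#' @param sample,control `ap_sites` objects on the same genome.
#' @param universe "sites" (all sample positions) or "hotspots" (depth >=
#'   `min_depth`).
#' @param min_depth Hotspot threshold for the hotspot universe.
#' @return r-squared, or NA when either depth vector has zero variance.
#' @export
technical_bias_r2 <- function(sample, control, universe = c("sites",
                                                            "hotspots"),
                              min_depth = 2L) {
  universe <- match.arg(universe)
  s <- if (universe == "sites") sample$sites else
    call_hotspots(sample, min_depth)
  if (nrow(s) < 2L) return(NA_real_)
  ck <- site_keys(control)
  cd <- control$sites$depth[match(site_keys(s), ck)]
  cd[is.na(cd)] <- 0L
  if (stats::sd(s$depth) == 0 || stats::sd(cd) == 0) return(NA_real_)
  stats::cor(s$depth, cd)^2
}

#' Enrichment of sites at TpC-context heterozygous C mutations
#'
#' Restricts to heterozygous SNPs whose reference allele reads C in a TpC
#' context on its own strand (ref C with a T at the 5' neighbour on the
#' plus strand, or ref G with the complementary context on the minus
#' strand), classed as C>G, C>A or C>T. Expected fractions are the
#' class shares among all such mutations; observed fractions the shares
#' among mutations overlapping site positions (strand-blind).
#'
#' @param variants Data frame from [load_variants()].
#' @param sites An `ap_sites` object.
#' @return Data frame with one enrichment row per mutation type, or NULL
#'   when no eligible variants exist.
#' @export
tpcn_variant_or <- function(variants, sites) {
  v <- variants[variants$vtype == "SNP" & variants$zygosity %in% "het" &
                  !is.na(variants$context), , drop = FALSE]
  plus <- v$ref == "C" & substr(v$context, 1L, 1L) == "T"
  minus <- v$ref == "G" & substr(v$context, 3L, 3L) == "A"
  v <- v[plus | minus, , drop = FALSE]
  if (nrow(v) == 0L) return(NULL)
  mut <- ifelse(v$ref == "C", paste0("C>", v$alt),
                paste0("C>", chartr("ACGT", "TGCA", v$alt)))
  v <- v[mut %in% c("C>G", "C>A", "C>T"), , drop = FALSE]
  mut <- mut[mut %in% c("C>G", "C>A", "C>T")]
  pos_keys <- paste(sites$sites$chrom, sites$sites$pos0)
  over <- paste(v$chrom, v$pos0) %in% pos_keys
  n_tot <- table(factor(mut, levels = c("C>G", "C>A", "C>T")))
  n_obs <- table(factor(mut[over], levels = c("C>G", "C>A", "C>T")))
  rows <- lapply(c("C>G", "C>A", "C>T"), function(m) {
    exp_ <- n_tot[[m]] / sum(n_tot)
    obs <- if (sum(n_obs) > 0) n_obs[[m]] / sum(n_obs) else NA_real_
    enrich_row("variants", m, obs, exp_, n_obs[[m]], sum(n_obs))
  })
  do.call(rbind, rows)
}

#' Mitochondrial strand asymmetry outside an excluded region
#'
#' Read-weighted fractions of sites on the minus ("heavy") and plus
#' ("light") strands of the mitochondrial chromosome, excluding a window
#' (the D-loop hotspot region) on both strands, and their fold ratio. When
#' the genome is supplied the sequence purine fraction of each strand is
#' reported alongside.
#'
#' @param sites An `ap_sites` object.
#' @param chrom Mitochondrial chromosome name.
#' @param exclude Length-2 vector: 0-based half-open window to drop.
#' @param genome Optional `genome` object for strand composition.
#' @return A list: `frac_heavy`, `frac_light`, `fold` (heavy/light),
#'   `n_reads`, and `seq_purine_frac` when a genome is given.
#' @export
mito_strand_analysis <- function(sites, chrom = "chrM",
                                 exclude = c(15650L, 15900L),
                                 genome = NULL) {
  s <- sites$sites[sites$sites$chrom == chrom, , drop = FALSE]
  if (!is.null(exclude)) {
    s <- s[s$pos0 < exclude[1] | s$pos0 >= exclude[2], , drop = FALSE]
  }
  tot <- sum(s$depth)
  if (tot == 0L) {
    return(list(frac_heavy = NA_real_, frac_light = NA_real_,
                fold = NA_real_, n_reads = 0L,
                message = "no reads outside the excluded window"))
  }
  h <- sum(s$depth[s$strand == "-"]) / tot
  l <- sum(s$depth[s$strand == "+"]) / tot
  out <- list(frac_heavy = h, frac_light = l,
              fold = if (l > 0) h / l else NA_real_, n_reads = tot)
  if (!is.null(genome)) {
    pf <- strand_purine_fraction(genome, chrom)
    out$seq_purine_frac <- c(heavy = unname(pf["-"]),
                             light = unname(pf["+"]))
  }
  out
}

#' Spearman correlation of a per-sample metric with age
#'
#' @param metrics Data frame with columns `sample`, `tissue`, `age` and the
#'   metric column.
#' @param metric Name of the metric column (e.g. "apf").
#' @return Data frame of Spearman rho per tissue plus a pooled row; NA for
#'   groupings with fewer than 3 samples or a constant metric.
#' @export
spearman_age_correlation <- function(metrics, metric = "apf") {
  one <- function(d, label) {
    rho <- if (nrow(d) >= 3L && stats::sd(d[[metric]]) > 0 &&
                 stats::sd(d$age) > 0) {
      stats::cor(d[[metric]], d$age, method = "spearman")
    } else NA_real_
    data.frame(tissue = label, n = nrow(d), rho = rho)
  }
  rows <- lapply(split(metrics, metrics$tissue), function(d) {
    one(d, d$tissue[1])
  })
  out <- rbind(do.call(rbind, rows), one(metrics, "pooled"))
  rownames(out) <- NULL
  out
}
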