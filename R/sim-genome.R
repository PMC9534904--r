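#' Simulate a small annotated genome
#'
#' Generates random chromosome sequences with a target GC content, a repeat
#' mask covering roughly `repeat_frac` of the genome, non-overlapping genes
#' with exon/intron structure, TSS +/- 1 kb flanks, regulatory element
#' classes (PLS, pELS, dELS), and a gene-expression table whose TPM values
#' span the three expression strata used downstream (TPM <= 1, 1 < TPM <= 10,
#' TPM > 10). Deterministic for a fixed seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome (bp).
#' @param gc GC content of the random sequence.
#' @param repeat_frac Target fraction of masked (repeat) bases.
#' @param n_genes Total number of genes.
#' @param seed Integer seed.
#' @return A list with `genome` (a [load_genome()]-style object carrying the
#'   repeat mask), `annotations` (named list of interval data frames:
#'   `genes`, `exons`, `introns`, `tss`, `regulatory`) and `expression`
#'   (data frame gene/tpm).
#' @export
sim_genome <- function(n_chrom = 2, chrom_len = 100000, gc = 0.42,
                       repeat_frac = 0.2, n_genes = 20, seed = 1) {
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(chroms, function(cn) {
    paste(sample(names(p), chrom_len, replace = TRUE, prob = p),
          collapse = "")
  }, "")

  # repeat mask: non-overlapping blocks until the target fraction is reached
  rep_classes <- c("LINE", "SINE", "LTR", "Satellite", "Simple_repeat")
  mask <- list()
  for (cn in chroms) {
    covered <- 0L
    guard <- 0L
    taken <- IRanges::IRanges()
    while (covered < repeat_frac * chrom_len && guard < 10000L) {
      guard <- guard + 1L
      w <- sample(200:1500, 1L)
      s <- sample.int(chrom_len - w, 1L) - 1L
      cand <- IRanges::IRanges(s + 1L, s + w)
      if (length(taken) && any(IRanges::overlapsAny(cand, taken))) next
      taken <- c(taken, cand)
      covered <- covered + w
      mask[[length(mask) + 1L]] <- data.frame(
        chrom = cn, start = s, end = s + w,
        class = sample(rep_classes, 1L))
    }
  }
  mask_iv <- if (length(mask)) {
    m <- do.call(rbind, mask)
    intervals(m$chrom, m$start, m$end, ".", m$class,
              sprintf("rep%d", seq_len(nrow(m))))
  } else empty_intervals()

  # genes: non-overlapping, alternating exon/intron structure
  gene_rows <- list(); exon_rows <- list(); intron_rows <- list()
  tss_rows <- list(); reg_rows <- list()
  per_chrom <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
  gid <- 0L
  for (ci in seq_along(chroms)) {
    cn <- chroms[ci]
    ng <- per_chrom[ci]
    if (ng == 0L) next
    glen <- sample(2000:6000, ng, replace = TRUE)
    if (sum(glen + 500) > chrom_len - 4000) {
      stop("gene layout infeasible: genes exceed chromosome length")
    }
    # lay genes left to right with random gaps
    gaps <- stats::rmultinom(1, chrom_len - 4000 - sum(glen), rep(1, ng))[, 1]
    cursor <- 2000L
    for (k in seq_len(ng)) {
      gid <- gid + 1L
      gname <- sprintf("gene%03d", gid)
      gstart <- cursor + gaps[k]
      gend <- gstart + glen[k]
      cursor <- gend
      gstrand <- sample(c("+", "-"), 1L)
      gene_rows[[gid]] <- data.frame(chrom = cn, start = gstart, end = gend,
                                     strand = gstrand, name = gname)
      # 3 exons of 200-400 bp: first, middle, last
      el <- sample(200:400, 3L, replace = TRUE)
      mid <- gstart + (glen[k] - el[2]) %/% 2L
      ex <- rbind(c(gstart, gstart + el[1]),
                  c(mid, mid + el[2]),
                  c(gend - el[3], gend))
      for (e in seq_len(3)) {
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          chrom = cn, start = ex[e, 1], end = ex[e, 2], strand = gstrand,
          name = gname)
      }
      intron_rows[[length(intron_rows) + 1L]] <- data.frame(
        chrom = cn, start = ex[1, 2], end = ex[2, 1], strand = gstrand,
        name = gname)
      intron_rows[[length(intron_rows) + 1L]] <- data.frame(
        chrom = cn, start = ex[2, 2], end = ex[3, 1], strand = gstrand,
        name = gname)
      tss <- if (gstrand == "+") gstart else gend - 1L
      tss_rows[[gid]] <- data.frame(
        chrom = cn, start = max(0L, tss - 1000L),
        end = min(chrom_len, tss + 1000L), strand = gstrand, name = gname)
      # promoter-like element at the TSS plus one distal enhancer-like
      reg_rows[[length(reg_rows) + 1L]] <- data.frame(
        chrom = cn, start = max(0L, tss - 100L),
        end = min(chrom_len, tss + 100L), strand = ".",
        class = "PLS", name = gname)
      dlen <- sample(150:350, 1L)
      dstart <- sample.int(chrom_len - dlen, 1L) - 1L
      reg_rows[[length(reg_rows) + 1L]] <- data.frame(
        chrom = cn, start = dstart, end = dstart + dlen, strand = ".",
        class = sample(c("pELS", "dELS"), 1L), name = gname)
    }
  }
  bind_iv <- function(rows, cls) {
    if (!length(rows)) return(empty_intervals())
    d <- do.call(rbind, rows)
    intervals(d$chrom, d$start, d$end, d$strand,
              if (is.null(d$class)) cls else d$class, d$name)
  }
  genes <- bind_iv(gene_rows, "gene")
  ann <- list(
    genes = genes,
    exons = bind_iv(exon_rows, "exon"),
    introns = bind_iv(intron_rows, "intron"),
    tss = bind_iv(tss_rows, "TSS1kb"),
    regulatory = bind_iv(reg_rows, NULL)
  )
  # TPM values spanning the three strata in roughly equal numbers
  n <- nrow(genes)
  strat <- rep_len(c("non", "low", "high"), n)[sample.int(n)]
  tpm <- numeric(n)
  tpm[strat == "non"] <- stats::runif(sum(strat == "non"), 0, 1)
  tpm[strat == "low"] <- stats::runif(sum(strat == "low"), 1.5, 9.5)
  tpm[strat == "high"] <- 10^stats::runif(sum(strat == "high"), 1.05, 3)
  expr <- data.frame(gene = genes$name, tpm = tpm, stringsAsFactors = FALSE)

  list(genome = genome_from_seqs(seqs, mask_iv), annotations = ann,
       expression = expr)
}

#' Simulate a mitochondrial-like chromosome with a chosen strand purine bias
#'
#' Generates a synthetic sequence (this is a stand-in, not a real
#' mitochondrial genome) whose minus ("heavy") strand carries the requested
#' purine fraction, for exercising strand-composition analyses.
#'
#' @param length Sequence length (bp).
#' @param h_purine_frac Purine (A+G) fraction on the minus strand.
#' @param seed Integer seed.
#' @return A `genome` object with one chromosome named "chrM".
#' @export
sim_mt_sequence <- function(length = 16299, h_purine_frac = 0.5311,
                            seed = 1) {
  set.seed(seed)
  # purines on the minus strand are pyrimidines on the plus strand
  p <- c(A = (1 - h_purine_frac) / 2, G = (1 - h_purine_frac) / 2,
         C = h_purine_frac / 2, T = h_purine_frac / 2)
  s <- paste(sample(names(p), length, replace = TRUE, prob = p),
             collapse = "")
  genome_from_seqs(c(chrM = s))
}

#' Purine fraction of each strand of a chromosome
#'
#' @param genome A `genome` object.
#' @param chrom Chromosome name.
#' @return Named vector with the A+G fraction of the plus and minus strands.
#' @export
strand_purine_fraction <- function(genome, chrom) {
  s <- genome$seq[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  n <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                   c("A", "C", "G", "T"))
  tot <- sum(n)
  c("+" = unname((n["A"] + n["G"]) / tot),
    "-" = unname((n["C"] + n["T"]) / tot))
}
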