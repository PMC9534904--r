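test_that("pairwise overlap odds ratios match first principles", {
  a <- mk_sites("c1", seq(0, 90, 10), "+", 1)
  got <- or_pairwise(a, a, 1000)
  expect_equal(got$odds_ratio, 100)          # (10/10) / (10/1000)
  expect_equal(got$observed_frac, 1)

  b <- mk_sites("c1", seq(1, 91, 10), "+", 1)
  expect_equal(or_pairwise(a, b, 1000)$odds_ratio, 0)

  # random sets on a large genome: OR near 1
  sim <- fx_sim()
  G2 <- 2 * sim$genome$total_len
  ra <- mk_random_sites(sim$genome, 3000, seed = 111)
  rb <- mk_random_sites(sim$genome, 3000, seed = 112)
  or <- or_pairwise(ra, rb, G2)$odds_ratio
  expect_lt(abs(or - 1), 0.5)

  # exact agreement with the loop-based oracle
  got <- or_pairwise(ra, rb, G2)
  expect_equal(got$odds_ratio,
               oracle_or_pairwise(site_keys(ra), site_keys(rb), G2))
})

test_that("repeat-class enrichment is read-weighted and oracle-exact", {
  g <- genome_from_seqs(c(c1 = strrep("ACGT", 250)))   # 1 kb
  cls <- intervals("c1", 0, 100, ".", "Satellite")     # 10% of genome
  inside <- mk_sites("c1", c(10, 50), "+", c(3, 2))
  got <- or_repeats(inside, cls, 1000)
  expect_equal(got$odds_ratio, 10)                     # all reads inside

  spread <- mk_sites("c1", seq(5, 995, length.out = 100), "+", 1)
  expect_lt(abs(or_repeats(spread, cls, 1000)$odds_ratio - 1), 0.15)

  # depth-2 sites count twice; verify against the per-read oracle
  set.seed(121)
  mixed <- mk_sites("c1", sample(0:999, 80), sample(c("+", "-"), 80, TRUE),
                    sample(1:4, 80, replace = TRUE))
  two_cls <- intervals(c("c1", "c1", "c1"), c(0, 300, 500),
                       c(100, 420, 560), ".",
                       c("Satellite", "LINE", "LINE"))
  got <- or_repeats(mixed, two_cls, 1000)
  want <- oracle_or_repeats(mixed$sites, two_cls, 1000)
  expect_equal(stats::setNames(got$odds_ratio, got$feature_class),
               want[got$feature_class])
})

test_that("element enrichment masks repeats, collapses sites, matches oracle", {
  sim <- fx_sim()
  elements <- rbind(sim$annotations$exons, sim$annotations$tss)
  elements$class <- rep(c("exon", "TSS1kb"),
                        c(nrow(sim$annotations$exons),
                          nrow(sim$annotations$tss)))
  sites <- mk_random_sites(sim$genome, 800, seed = 131,
                           depth = sample(1:5, 800, replace = TRUE))
  got <- or_elements(sites, elements, sim$genome)
  want <- oracle_or_elements(sites$sites, elements, sim$genome)
  for (i in seq_len(nrow(got))) {
    cls <- got$feature_class[i]
    expect_equal(got$n_obs[i], want[[cls]]$n_obs)
    expect_equal(got$n_total[i], want[[cls]]$n_total)
    expect_equal(got$odds_ratio[i], want[[cls]]$odds_ratio)
  }
  # depth does not inflate the collapsed counts
  heavy <- sites
  heavy$sites$depth <- heavy$sites$depth * 5L
  got2 <- or_elements(heavy, elements, sim$genome)
  expect_equal(got2$n_obs, got$n_obs)

  # uniform sites give OR near 1, and the binomial p is well-formed
  expect_true(all(got$p_two_sided > 0 & got$p_two_sided <= 1))
  expect_lt(abs(got$odds_ratio[got$feature_class == "TSS1kb"] - 1), 0.5)
})

test_that("template/nontemplate ratios follow element strand", {
  gene <- intervals("c1", 100, 200, "+", "exon", "g1")
  # template for a plus gene is the minus strand
  s <- mk_sites("c1", c(110, 120, 130, 140, 150, 160, 170, 180, 190),
                c("-", "-", "-", "+", "+", "+", "+", "+", "+"), 1)
  got <- template_nontemplate_ratio(s, gene)
  expect_equal(got$ratio, 0.5)
  expect_equal(got$template_count, 3L)

  both <- rbind(gene, intervals("c1", 100, 200, "-", "exon", "g2"))
  got2 <- template_nontemplate_ratio(s, both)
  expect_equal(got2$template_count + got2$nontemplate_count, 18L)

  none <- template_nontemplate_ratio(mk_sites("c1", 50, "+", 1), gene)
  expect_true(is.na(none$ratio) | none$nontemplate_count > 0)
})

test_that("expression strata split at TPM 1 and 10", {
  sim <- fx_sim()
  genes <- sim$annotations$genes
  expr <- data.frame(gene = genes$name,
                     tpm = rep_len(c(1, 10, 10.1), nrow(genes)))
  el <- genes
  el$class <- "gene"
  got <- stratify_and_density(mk_random_sites(sim$genome, 300, seed = 141),
                              el, expr, sim$genome)
  n_non <- sum(expr$tpm <= 1)
  n_low <- sum(expr$tpm > 1 & expr$tpm <= 10)
  n_high <- sum(expr$tpm > 10)
  expect_equal(got$n_elements[got$stratum == "nonexpressed"], n_non)
  expect_equal(got$n_elements[got$stratum == "low"], n_low)
  expect_equal(got$n_elements[got$stratum == "high"], n_high)
  expect_warning(
    stratify_and_density(mk_random_sites(sim$genome, 50, seed = 142), el,
                         expr[-1, ], sim$genome),
    "nonexpressed")
})

test_that("site nucleotide composition reads the site strand", {
  g <- genome_from_seqs(c(c1 = "TTTTTAAAAA"))
  # minus-strand sites over reference T read as A
  s <- mk_sites("c1", 0:4, "-", 1)
  comp <- nucleotide_composition(s, g, min_depths = 1L)
  expect_equal(comp$composition$A, 1)
  # an A/T-only genome is half A, half T over both strands
  expect_equal(unname(comp$background), c(0.5, 0, 0, 0.5))
  # a balanced genome has a flat double-strand background
  bal <- genome_from_seqs(c(c1 = strrep("ACGT", 10)))
  expect_equal(unname(nucleotide_composition(s = mk_sites("c1", 0, "+", 1),
                                             bal,
                                             min_depths = 1L)$background),
               rep(0.25, 4))

  # depth thresholds subset the sites
  s2 <- mk_sites("c1", c(0, 1, 5), c("+", "+", "+"), c(1, 2, 2))
  c2 <- nucleotide_composition(s2, g, min_depths = c(1L, 2L))
  expect_equal(c2$composition$n_sites, c(3L, 2L))
  expect_equal(c2$composition$T[1], 2 / 3)
  expect_equal(c2$composition$A[2], 1 / 2)
})

test_that("technical bias r2 behaves at the extremes", {
  a <- mk_sites("c1", c(1, 2, 3), "+", c(1, 5, 9))
  expect_equal(technical_bias_r2(a, a), 1)
  b <- mk_sites("c1", c(1, 2, 3), "+", c(2, 6, 10))
  expect_equal(technical_bias_r2(a, b), 1)   # affine depths correlate fully
  none <- mk_sites("c1", 9, "+", 1)
  expect_true(is.na(technical_bias_r2(a, none)))  # control all zero

  # independent random site sets decorrelate
  sim <- fx_sim()
  x <- mk_random_sites(sim$genome, 2000, seed = 151,
                       depth = sample(1:4, 2000, replace = TRUE))
  y <- mk_random_sites(sim$genome, 2000, seed = 152,
                       depth = sample(1:4, 2000, replace = TRUE))
  expect_lt(technical_bias_r2(x, y), 0.05)
})

test_that("TpC-context variant odds ratios reproduce the count arithmetic", {
  # 50 C>G, 25 C>A, 25 C>T; overlaps 8/1/1
  mk_var <- function(n, alt, start) {
    data.frame(chrom = "c1", pos0 = seq(start, by = 10,
                                        length.out = n),
               ref = "C", alt = alt, vtype = "SNP", zygosity = "het",
               context = "TCA", stringsAsFactors = FALSE)
  }
  v <- rbind(mk_var(50, "G", 0), mk_var(25, "A", 1000),
             mk_var(25, "T", 2000))
  over <- c(seq(0, 70, 10), 1000, 2000)     # 8 C>G, 1 C>A, 1 C>T
  sites <- mk_sites("c1", over, "+", 1)
  got <- tpcn_variant_or(v, sites)
  expect_equal(got$odds_ratio[got$feature_class == "C>G"],
               (8 / 10) / (50 / 100))
  expect_equal(got$odds_ratio[got$feature_class == "C>A"],
               (1 / 10) / (25 / 100))

  # overlaps proportional to totals: all ORs 1
  prop <- mk_sites("c1", c(seq(0, 10, 10), 1000), "+", 1)  # 2 G, 1 A
  v2 <- rbind(mk_var(20, "G", 0), mk_var(10, "A", 1000))
  got2 <- tpcn_variant_or(v2, prop)
  expect_equal(got2$odds_ratio[1:2], c(1, 1))

  # minus-strand context: ref G with A at the plus-strand 3' position
  vm <- data.frame(chrom = "c1", pos0 = 5L, ref = "G", alt = "C",
                   vtype = "SNP", zygosity = "het", context = "CGA",
                   stringsAsFactors = FALSE)
  got3 <- tpcn_variant_or(rbind(vm, mk_var(5, "G", 100)),
                          mk_sites("c1", 5, "+", 1))
  # the minus-strand G>C variant reads C>G on its own strand
  expect_equal(got3$n_obs[got3$feature_class == "C>G"], 1L)
  # homozygous and non-TpC records are excluded
  hom <- mk_var(5, "G", 0); hom$zygosity <- "hom"
  expect_null(tpcn_variant_or(hom, sites))
})

test_that("mitochondrial strand analysis excludes the window and reports fold", {
  s <- mk_sites("chrM", c(100, 200, 300, 15700), c("-", "-", "+", "-"),
                c(2, 3, 2, 50))
  got <- mito_strand_analysis(s, exclude = c(15650L, 15900L))
  expect_equal(got$n_reads, 7L)            # the D-loop burst is dropped
  expect_equal(got$fold, 5 / 2)

  all_in <- mk_sites("chrM", 15700, "-", 10)
  got2 <- mito_strand_analysis(all_in)
  expect_true(is.na(got2$fold))

  even <- mk_sites("chrM", c(10, 20), c("+", "-"), 3)
  expect_equal(mito_strand_analysis(even)$fold, 1)

  g <- sim_mt_sequence(length = 16299, h_purine_frac = 0.5311, seed = 4)
  got3 <- mito_strand_analysis(even, genome = g)
  expect_lt(abs(got3$seq_purine_frac[["heavy"]] - 0.5311), 0.012)
  expect_equal(got3$seq_purine_frac[["heavy"]] +
                 got3$seq_purine_frac[["light"]], 1)
})

test_that("age correlations recover monotone and null relationships", {
  d <- data.frame(sample = letters[1:6], tissue = "liver",
                  age = c(3, 6, 9, 12, 18, 22),
                  apf = c(0.10, 0.12, 0.13, 0.15, 0.18, 0.22))
  got <- spearman_age_correlation(d)
  expect_equal(got$rho[got$tissue == "liver"], 1)
  expect_equal(got$rho[got$tissue == "pooled"], 1)

  set.seed(161)
  big <- data.frame(sample = as.character(1:120),
                    tissue = rep(c("a", "b"), 60),
                    age = rep(c(3, 6, 9, 12), 30),
                    apf = stats::runif(120))
  got2 <- spearman_age_correlation(big)
  expect_lt(abs(got2$rho[got2$tissue == "pooled"]), 0.25)

  const <- d; const$apf <- 0.5
  expect_true(all(is.na(spearman_age_correlation(const)$rho)))
})
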