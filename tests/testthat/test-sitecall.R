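test_that("tag filter enforces the literal-plus-maximal-run grammar", {
  tag10 <- paste0("AGTTGCGGAT", strrep("G", 10))
  res <- filter_tag_structure(paste0(tag10, "ACTGCA"),
                              paste0(strrep("T", 12), "CAGTGA"))
  expect_true(res$accept)
  expect_equal(res$r1_trim, "ACTGCA")
  expect_equal(res$r2_trim, "CAGTGA")

  # G-run bounds: 8 too short, 12 too long (not maximal within 9-11)
  for (n in c(8, 12)) {
    r <- filter_tag_structure(paste0("AGTTGCGGAT", strrep("G", n), "ACT"),
                              paste0(strrep("T", 12), "CAG"))
    expect_false(r$accept)
    expect_equal(r$reason, "r1_tag")
  }
  # T-run bounds: 10 and 14 both rejected
  for (n in c(10, 14)) {
    r <- filter_tag_structure(paste0(tag10, "ACT"),
                              paste0(strrep("T", n), "CAG"))
    expect_false(r$accept)
    expect_equal(r$reason, "r2_tag")
  }
  # a run that ends the read still counts as maximal
  r <- filter_tag_structure(paste0(tag10, "ACT"), strrep("T", 13))
  expect_true(r$accept)
  expect_equal(r$r2_trim, "")
  # empty reads are rejections, not errors
  r <- filter_tag_structure("", "")
  expect_false(r$accept)
})

test_that("deduplication keys on both mates and keeps the best pair", {
  a <- mk_pair(name = "a", r2_pos0 = 100L, r1_pos0 = 400L)
  b <- mk_pair(name = "b", r2_pos0 = 100L, r1_pos0 = 400L, r2_mapq = 10L)
  c <- mk_pair(name = "c", r2_pos0 = 100L, r1_pos0 = 450L)
  dd <- dedup_pairs(rbind(a, b, c))
  expect_equal(sort(dd$name), c("a", "c"))   # same r2, different r1: kept

  # deterministic tie-break by name
  b2 <- mk_pair(name = "b", r2_pos0 = 100L, r1_pos0 = 400L)
  expect_equal(dedup_pairs(rbind(b2, a))$name, "a")

  # duplicate-laden simulation: retained pairs equal distinct template
  # coordinate tuples among tag-passing reads
  sim <- fx_sim()
  p <- sim_params(n_site_reads = 800, hotspot_count = 10,
                  duplicate_rate = 0.2, unblocked_background_rate = 0.02,
                  seed = 51)
  rd <- simulate_reads(sim$genome,
                       plant_sites(sim$genome, sim$annotations, p), p)
  tg <- filter_tag_structure(rd$r1, rd$r2)
  keep <- which(tg$accept)
  aln <- align_exact(stats::setNames(tg$r1_trim[keep],
                                     names(rd$r1)[keep]),
                     stats::setNames(tg$r2_trim[keep],
                                     names(rd$r2)[keep]), sim$genome)
  tpl <- rd$templates[rd$reads$template_id[keep], ]
  expect_equal(nrow(dedup_pairs(aln)),
               nrow(unique(tpl[, c("chrom", "r1_pos0", "r2_left0",
                                   "r2_strand")])))
})

test_that("genomic alignment filter applies MAPQ, flag and first-base rules", {
  g <- genome_from_seqs(c(c1 = strrep("ACGTG", 200)))
  ok <- mk_pair(r2_pos0 = 100L, r2_seq = substring(g$seq[["c1"]], 101, 150),
                r2_cigar = "50M")
  expect_true(filter_alignments_genomic(ok, g)$pass)

  # the MAPQ threshold is strict: exactly 20 fails
  mq <- ok; mq$r2_mapq <- 20L
  r <- filter_alignments_genomic(mq, g)
  expect_false(r$pass); expect_equal(r$reason, "mapq")
  mq$r2_mapq <- 21L
  expect_true(filter_alignments_genomic(mq, g)$pass)

  fl <- ok; fl$r2_flag <- 99L
  r <- filter_alignments_genomic(fl, g)
  expect_false(r$pass); expect_equal(r$reason, "flag")

  sc <- ok; sc$r2_cigar <- "1S49M"
  r <- filter_alignments_genomic(sc, g)
  expect_false(r$pass); expect_equal(r$reason, "first_base")

  mm <- ok; mm$r2_seq <- paste0("T", substring(mm$r2_seq, 2))
  expect_false(filter_alignments_genomic(mm, g)$pass)

  # minus-strand read: first sequenced base is the last stored base,
  # compared at the rightmost reference position
  rev <- mk_pair(r2_pos0 = 100L, r2_strand = "-", r2_flag = 147L,
                 r2_cigar = "50M",
                 r2_seq = substring(g$seq[["c1"]], 101, 150))
  expect_true(filter_alignments_genomic(rev, g)$pass)
  rev$r2_seq <- paste0(substring(rev$r2_seq, 1, 49), "T")
  expect_false(filter_alignments_genomic(rev, g)$pass)
})

test_that("spike filter uses inclusive MAPQ, strand opposition and distance", {
  g <- genome_from_seqs(c(sp1 = strrep("ACGTG", 120)))
  base <- mk_pair(r2_chrom = "sp1", r1_chrom = "sp1", r2_pos0 = 100L,
                  r2_seq = substring(g$seq[["sp1"]], 101, 150),
                  r1_pos0 = 300L, r1_strand = "-")
  base$r1_mapq <- base$r2_mapq <- 20L     # inclusive, unlike genomic
  expect_true(filter_alignments_spike(base, g)$pass)
  low <- base; low$r2_mapq <- 19L
  expect_false(filter_alignments_spike(low, g)$pass)

  same <- base; same$r1_strand <- "+"
  r <- filter_alignments_spike(same, g)
  expect_false(r$pass); expect_equal(r$reason, "strand")

  far <- base; far$r1_pos0 <- 600L   # distance exactly 500 fails
  r <- filter_alignments_spike(far, g)
  expect_false(r$pass); expect_equal(r$reason, "distance")
  near <- base; near$r1_pos0 <- 599L
  expect_true(filter_alignments_spike(near, g)$pass)
})

test_that("polyA filter measures the upstream window on the read strand", {
  # plus-strand read at 100: window is the 20 reference bases before it
  win9 <- paste0(strrep("C", 80), paste0(strrep("T", 9), strrep("C", 11)),
                 strrep("ACGTG", 100))
  g <- genome_from_seqs(c(c1 = win9))
  p <- mk_pair(r2_pos0 = 100L, r2_cigar = "50M")
  expect_false(genomic_polyA_filter(p, g)$pass)      # 45% > 40%
  win8 <- paste0(strrep("C", 80), paste0(strrep("T", 8), strrep("C", 12)),
                 strrep("ACGTG", 100))
  g8 <- genome_from_seqs(c(c1 = win8))
  expect_true(genomic_polyA_filter(p, g8)$pass)      # exactly 40% passes

  # minus-strand read: upstream is to the right, read as the complement;
  # an all-A plus-strand reference is all-T on the read strand
  ga <- genome_from_seqs(c(c1 = strrep("A", 400)))
  m <- mk_pair(r2_pos0 = 100L, r2_strand = "-", r2_flag = 147L,
               r2_cigar = "50M")
  r <- genomic_polyA_filter(m, ga)
  expect_false(r$pass)
  expect_equal(r$t_frac, 1)

  # truncated window rescales by the available length
  edge <- mk_pair(r2_pos0 = 10L, r2_cigar = "50M")
  gt <- genome_from_seqs(c(c1 = paste0(strrep("T", 5), strrep("C", 395))))
  expect_equal(genomic_polyA_filter(edge, gt)$t_frac, 0.5)

  # randomized agreement with the character-loop oracle
  sim <- fx_sim()
  set.seed(61)
  n <- 60
  pr <- mk_pair()[rep(1, n), ]
  pr$r2_chrom <- sample(names(sim$genome$seq), n, replace = TRUE)
  pr$r2_strand <- sample(c("+", "-"), n, replace = TRUE)
  pr$r2_pos0 <- sample(100:40000, n)
  pr$r2_cigar <- "50M"
  got <- genomic_polyA_filter(pr, sim$genome)
  for (i in seq_len(n)) {
    p5 <- if (pr$r2_strand[i] == "+") pr$r2_pos0[i] else
      pr$r2_pos0[i] + 49L
    expect_equal(got$t_frac[i],
                 oracle_polyA_tfrac(sim$genome, pr$r2_chrom[i], p5,
                                    pr$r2_strand[i]))
  }
})

test_that("site assignment shifts one base past the read along the site strand", {
  g <- genome_from_seqs(c(c1 = strrep("ACGTG", 1000)))
  plus <- mk_pair(r2_pos0 = 1000L, r2_strand = "+", r2_cigar = "50M")
  got <- assign_sites(plus, g, 1L)$sites$sites
  expect_equal(got$pos0, 999L)
  expect_equal(got$strand, "-")

  minus <- mk_pair(r2_pos0 = 1951L, r2_strand = "-", r2_flag = 147L,
                   r2_cigar = "50M")
  got <- assign_sites(minus, g, 1L)$sites$sites
  expect_equal(got$pos0, 2001L)   # 5' end at 2000, shifted +1
  expect_equal(got$strand, "+")

  # SSB mode: no shift
  got0 <- assign_sites(rbind(plus, minus), g, 0L)$sites$sites
  expect_setequal(got0$pos0, c(1000L, 2000L))

  # reads sharing a site aggregate into depth; out-of-bounds are counted
  two <- rbind(mk_pair(name = "x", r2_pos0 = 1000L),
               mk_pair(name = "y", r2_pos0 = 1000L))
  got <- assign_sites(two, g, 1L)
  expect_equal(got$sites$sites$depth, 2L)
  oob <- mk_pair(r2_pos0 = 0L)
  got <- assign_sites(oob, g, 1L)
  expect_equal(got$n_out_of_bounds, 1L)
  expect_equal(nrow(got$sites$sites), 0L)
})

test_that("the full pipeline recovers planted truth and conserves counts", {
  run <- fx_clean_run()
  called <- site_keys(run$res$sites)
  truthk <- paste(run$truth$chrom, run$truth$pos0, run$truth$strand,
                  sep = ":")
  expect_setequal(called, truthk)
  m <- match(truthk, called)
  expect_equal(run$res$sites$sites$depth[m], run$truth$expected_reads)

  st <- run$res$stats
  expect_equal(st$input_pairs, length(run$reads$r1))
  expect_true(all(diff(c(st$tag_pass, st$align_pass)) <= 0))
  tab <- filter_stats_table(st)
  expect_true(all(tab$fail >= 0))
  expect_equal(tab$pass[1], st$input_pairs)

  # all-reject input yields an empty set with tag_pass 0
  bad <- run_pipeline(c(x = "ACGT"), c(x = "ACGT"), run$sim$genome)
  expect_equal(bad$stats$tag_pass, 0L)
  expect_equal(nrow(bad$sites$sites), 0L)
})

test_that("AP and SSB modes differ by exactly one base along the site strand", {
  run <- fx_clean_run()
  ap <- run_pipeline(run$reads$r1, run$reads$r2, run$sim$genome,
                     mode = "ap")$sites$sites
  ssb <- run_pipeline(run$reads$r1, run$reads$r2, run$sim$genome,
                      mode = "ssb")$sites$sites
  shifted <- paste(ap$chrom, ap$pos0 + ifelse(ap$strand == "+", -1L, 1L),
                   ap$strand, sep = ":")
  expect_setequal(shifted, paste(ssb$chrom, ssb$pos0, ssb$strand,
                                 sep = ":"))
})
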