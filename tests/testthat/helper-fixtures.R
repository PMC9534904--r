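# Shared fixtures, built once per test run. Everything is generated in
# code; sizes are kept small so the whole suite stays fast.

fx <- new.env()

# A 2 x 50 kb annotated genome with a repeat mask and expression table.
fx_sim <- function() {
  if (is.null(fx$sim)) {
    fx$sim <- sim_genome(n_chrom = 2, chrom_len = 50000, gc = 0.42,
                         repeat_frac = 0.2, n_genes = 8, seed = 11)
  }
  fx$sim
}

# A clean simulated library (no background, no duplicates) plus its truth
# and the pipeline result, used by several files.
fx_clean_run <- function() {
  if (is.null(fx$clean)) {
    sim <- fx_sim()
    params <- sim_params(n_site_reads = 1500, hotspot_count = 30,
                         duplicate_rate = 0, unblocked_background_rate = 0,
                         seed = 21)
    truth <- plant_sites(sim$genome, sim$annotations, params,
                         sim$expression)
    reads <- simulate_reads(sim$genome, truth, params)
    res <- run_pipeline(reads$r1, reads$r2, sim$genome, mode = "ap",
                        sample_id = "clean")
    fx$clean <- list(sim = sim, params = params, truth = truth,
                     reads = reads, res = res)
  }
  fx$clean
}

# Build an ap_sites object from vectors, with depth defaulting to 1.
mk_sites <- function(chrom, pos0, strand, depth = 1L, ...) {
  ap_site_set(data.frame(chrom = chrom, pos0 = as.integer(pos0),
                         strand = strand,
                         depth = as.integer(rep_len(depth,
                                                    length(pos0)))), ...)
}

# Random site set on a genome (uniform, distinct positions).
mk_random_sites <- function(genome, n, seed, depth = 1L, ...) {
  set.seed(seed)
  pool <- do.call(rbind, lapply(names(genome$seq), function(cn) {
    data.frame(chrom = cn, pos0 = seq_len(genome$lengths[[cn]]) - 1L)
  }))
  i <- sample.int(nrow(pool) * 2L, n)
  strand <- ifelse(i > nrow(pool), "-", "+")
  i <- ((i - 1L) %% nrow(pool)) + 1L
  df <- unique(data.frame(chrom = pool$chrom[i], pos0 = pool$pos0[i],
                          strand = strand))
  mk_sites(df$chrom, df$pos0, df$strand, depth, ...)
}

# A minimal aligned pair row for filter unit tests.
mk_pair <- function(r2_chrom = "c1", r2_pos0 = 100L, r2_strand = "+",
                    r2_mapq = 60L, r2_flag = 163L, r2_cigar = "50M",
                    r2_seq = strrep("A", 50), r1_chrom = "c1",
                    r1_pos0 = 400L, r1_strand = "-", r1_mapq = 60L,
                    r1_flag = 83L, r1_cigar = "50M",
                    r1_seq = strrep("A", 50), name = "p1") {
  data.frame(name = name, r1_chrom = r1_chrom, r1_pos0 = r1_pos0,
             r1_strand = r1_strand, r1_mapq = r1_mapq, r1_flag = r1_flag,
             r1_cigar = r1_cigar, r1_seq = r1_seq, r2_chrom = r2_chrom,
             r2_pos0 = r2_pos0, r2_strand = r2_strand, r2_mapq = r2_mapq,
             r2_flag = r2_flag, r2_cigar = r2_cigar, r2_seq = r2_seq,
             stringsAsFactors = FALSE)
}
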