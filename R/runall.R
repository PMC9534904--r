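#' Run an end-to-end analysis from a flat configuration
#'
#' Drives a reproducible run: read inputs (or simulate them when the config
#' asks for a synthetic run), call sites, compute abundance metrics,
#' hotspots and enrichment tables, and write everything plus a manifest
#' (input checksums, parameters, package version) and a stage log to the
#' output directory.
#'
#' @param config Path to a flat YAML file or an equivalent named list.
#'   Recognised keys: either `simulate: true` with simulator settings
#'   (`chrom_len`, `n_chrom`, `n_genes`, `repeat_frac`, `n_site_reads`,
#'   `hotspot_count`, ...), or input paths (`fastq1`, `fastq2`, `genome`,
#'   optional `sam`, `repeats`, `elements`, `expression`); shared keys:
#'   `mode` ("ap"/"ssb"), `min_depth`, `seed`, `outdir`.
#' @param outdir Output directory (overrides the config).
#' @return Invisibly, a list with the principal results (`sites`, `stats`,
#'   `apf`, `hotspots`, `enrichment`).
#' @export
run_all <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  get <- function(k, default) if (!is.null(cfg[[k]])) cfg[[k]] else default
  outdir <- if (!is.null(outdir)) outdir else get("outdir", "apsitemap_out")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(get("seed", 1L))
  mode <- get("mode", "ap")
  min_depth <- as.integer(get("min_depth", 2L))
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  manifest <- list(package_version =
                     as.character(utils::packageVersion("apsitemap")),
                   config = cfg, seed = seed)

  elements <- NULL; expression <- NULL
  if (isTRUE(get("simulate", FALSE))) {
    say("simulating genome and reads (seed %d)", seed)
    sim <- sim_genome(n_chrom = get("n_chrom", 2L),
                      chrom_len = get("chrom_len", 100000L),
                      repeat_frac = get("repeat_frac", 0.2),
                      n_genes = get("n_genes", 20L), seed = seed)
    genome <- sim$genome
    elements <- rbind(sim$annotations$exons, sim$annotations$introns,
                      sim$annotations$tss)
    elements$class <- rep(c("exon", "intron", "TSS1kb"),
                          c(nrow(sim$annotations$exons),
                            nrow(sim$annotations$introns),
                            nrow(sim$annotations$tss)))
    expression <- sim$expression
    params <- sim_params(
      n_site_reads = get("n_site_reads", 20000L),
      hotspot_count = get("hotspot_count", 200L),
      duplicate_rate = get("duplicate_rate", 0.1),
      unblocked_background_rate = get("unblocked_background_rate", 0.015),
      seed = seed)
    truth <- plant_sites(genome, sim$annotations, params, sim$expression)
    reads <- simulate_reads(genome, truth, params)
    write_genome(genome, file.path(outdir, "genome.fa"))
    write_fastq(reads$r1, file.path(outdir, "reads_1.fq"))
    write_fastq(reads$r2, file.path(outdir, "reads_2.fq"))
    write_intervals(intervals(truth$chrom, truth$pos0, truth$pos0 + 1L,
                              truth$strand, "truth",
                              ifelse(truth$hotspot, "hotspot", "site")),
                    file.path(outdir, "truth.bed"))
    r1 <- reads$r1; r2 <- reads$r2
    pairs <- NULL
  } else {
    genome <- load_genome(get("genome", stop("config needs 'genome'")),
                          get("repeats", NULL))
    r1 <- get("fastq1", stop("config needs 'fastq1'"))
    r2 <- get("fastq2", stop("config needs 'fastq2'"))
    pairs <- if (!is.null(cfg$sam)) load_alignments(cfg$sam)$pairs else NULL
    if (!is.null(cfg$elements)) elements <- read_intervals(cfg$elements)
    if (!is.null(cfg$expression)) expression <-
        read_expression(cfg$expression)
    for (p in c("genome", "fastq1", "fastq2", "sam", "repeats", "elements",
                "expression")) {
      if (!is.null(cfg[[p]])) {
        manifest$inputs[[p]] <- list(path = cfg[[p]],
                                     md5 = unname(tools::md5sum(cfg[[p]])))
      }
    }
  }

  say("calling sites (mode %s)", mode)
  res <- run_pipeline(r1, r2, genome, pairs = pairs, mode = mode,
                      sample_id = get("sample_id", "sample"))
  write_sites(res$sites, file.path(outdir, "sites.bed"))
  utils::write.table(filter_stats_table(res$stats),
                     file.path(outdir, "stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  apf <- compute_apf(res$stats$site_reads, res$stats$tag_pass)
  say("tag pairs %d, site reads %d, APF %.4f", res$stats$tag_pass,
      res$stats$site_reads, apf)

  hs <- call_hotspots(res$sites, min_depth)
  write_intervals(intervals(hs$chrom, hs$pos0, hs$pos0 + 1L, hs$strand,
                            "hotspot", as.character(hs$depth)),
                  file.path(outdir, "hotspots.bed"))
  say("%d hotspots at depth >= %d", nrow(hs), min_depth)

  enr <- NULL
  if (nrow(genome$repeat_mask)) {
    enr <- or_repeats(res$sites, genome$repeat_mask, genome$total_len)
  }
  if (!is.null(elements)) {
    enr <- rbind(enr, or_elements(res$sites, elements, genome))
  }
  if (!is.null(enr)) {
    utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  comp <- nucleotide_composition(res$sites, genome)
  utils::write.table(comp$composition,
                     file.path(outdir, "composition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  writeLines(yaml::as.yaml(manifest), file.path(outdir, "manifest.yaml"))
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(list(sites = res$sites, stats = res$stats, apf = apf,
                 hotspots = hs, enrichment = enr,
                 composition = comp))
}
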