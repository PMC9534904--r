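#' Load sequence variants from a VCF v4 file
#'
#' Parses the fixed columns plus the first sample's GT field, classifies each
#' record as SNP, insertion or deletion, assigns het/hom zygosity, and
#' extracts the reference trinucleotide context centred on the variant base
#' (plus strand). Deletions are anchored at the first deleted base;
#' insertions at the base left of the insertion point (the VCF anchor base).
#'
#' @param path VCF path (plain or gzip text).
#' @param genome A `genome` object used to verify REF and extract context.
#' @return Data frame with columns `chrom`, `pos0`, `ref`, `alt`, `vtype`,
#'   `zygosity`, `context` (NA where the triplet is truncated by a
#'   chromosome end).
#' @export
load_variants <- function(path, genome) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    return(data.frame(chrom = character(), pos0 = integer(),
                      ref = character(), alt = character(),
                      vtype = character(), zygosity = character(),
                      context = character()))
  }
  recs <- strsplit(body, "\t", fixed = TRUE)
  f <- function(k) vapply(recs, `[`, "", k)
  chrom <- f(1)
  pos0 <- as.integer(f(2)) - 1L
  ref <- toupper(f(4))
  alt <- toupper(f(5))
  gt <- vapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (length(r) < 10L) return(NA_character_)
    fmt <- strsplit(r[9], ":", fixed = TRUE)[[1]]
    smp <- strsplit(r[10], ":", fixed = TRUE)[[1]]
    gi <- match("GT", fmt)
    if (is.na(gi) || gi > length(smp)) NA_character_ else smp[gi]
  }, "")
  alleles <- lapply(gt, function(g) {
    if (is.na(g)) return(NA_integer_)
    suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  zyg <- vapply(alleles, function(a) {
    if (all(is.na(a))) return(NA_character_)
    if (length(unique(a[!is.na(a)])) > 1L) "het" else "hom"
  }, "")
  vtype <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP",
                  ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  # REF check against the genome
  for (i in seq_along(chrom)) {
    obs <- genome_slice(genome, chrom[i], pos0[i], pos0[i] + nchar(ref[i]))
    if (!identical(obs, ref[i])) {
      stop(sprintf("VCF REF mismatch at %s:%d (REF %s, genome %s)",
                   chrom[i], pos0[i] + 1L, ref[i], obs))
    }
  }
  # deletions: position of the first deleted base (anchor + 1)
  vpos <- pos0 + ifelse(vtype == "deletion", 1L, 0L)
  ctx <- vapply(seq_along(chrom), function(i) {
    s <- genome_slice(genome, chrom[i], vpos[i] - 1L, vpos[i] + 2L)
    if (nchar(s) == 3L) s else NA_character_
  }, "")
  data.frame(chrom = chrom, pos0 = vpos, ref = ref, alt = alt,
             vtype = vtype, zygosity = zyg, context = ctx,
             stringsAsFactors = FALSE)
}

#' Read a gene-expression table
#'
#' @param path TSV with columns gene and TPM (header optional).
#' @return Data frame with columns `gene`, `tpm`.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (suppressWarnings(is.na(as.numeric(df[2, 2]))) ||
      suppressWarnings(is.na(as.numeric(df[1, 2])))) {
    df <- df[-1, , drop = FALSE]
  }
  data.frame(gene = df[[1]], tpm = as.numeric(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Read a fragment-size profile
#'
#' @param path TSV with columns size (bp) and intensity (header optional).
#' @return Data frame with columns `size_bp`, `intensity`, sizes strictly
#'   increasing.
#' @export
read_size_profile <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (suppressWarnings(is.na(as.numeric(df[1, 1])))) {
    df <- df[-1, , drop = FALSE]
  }
  out <- data.frame(size_bp = as.numeric(df[[1]]),
                    intensity = as.numeric(df[[2]]))
  out <- out[order(out$size_bp), , drop = FALSE]
  if (any(diff(out$size_bp) <= 0)) stop("sizes not strictly increasing")
  if (any(out$size_bp <= 0) || any(out$intensity < 0)) {
    stop("invalid size profile")
  }
  rownames(out) <- NULL
  out
}
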