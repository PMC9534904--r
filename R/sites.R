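#' AP / SSB site sets
#'
#' A site set is the per-sample multiset of single-nucleotide lesion calls:
#' one row per distinct (chrom, pos0, strand) with the supporting read depth,
#' plus sample metadata and the pipeline totals needed by the abundance
#' metrics.
#'
#' @param sites Data frame with columns `chrom`, `pos0` (0-based), `strand`
#'   ("+"/"-") and `depth` (reads, >= 1).
#' @param sample_id,tissue,age,assay,enzyme Sample metadata. `assay` is one
#'   of "AP", "SSB", "unblocked", "spike"; `enzyme` one of "APE1", "EndoIV",
#'   "none".
#' @param n_tag_pairs Number of read pairs passing the tag-structure filter
#'   (the APF/ASF denominator).
#' @return An object of class `ap_sites`.
#' @export
ap_site_set <- function(sites, sample_id = "sample", tissue = NA_character_,
                        age = NA_real_, assay = "AP", enzyme = "APE1",
                        n_tag_pairs = NA_integer_) {
  sites <- as.data.frame(sites)
  if (nrow(sites) == 0L) {
    sites <- data.frame(chrom = character(), pos0 = integer(),
                        strand = character(), depth = integer())
  }
  stopifnot(all(c("chrom", "pos0", "strand", "depth") %in% names(sites)))
  if (any(sites$depth < 1L)) stop("site with depth < 1")
  key <- paste(sites$chrom, sites$pos0, sites$strand)
  if (anyDuplicated(key)) stop("duplicate (chrom,pos0,strand) in site set")
  sites <- sites[order(sites$chrom, sites$pos0, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites, sample_id = sample_id, tissue = tissue,
                 age = age, assay = assay, enzyme = enzyme,
                 n_tag_pairs = n_tag_pairs,
                 n_site_reads = sum(sites$depth)),
            class = "ap_sites")
}

#' @export
print.ap_sites <- function(x, ...) {
  cat(sprintf("%s site set '%s': %d sites, %d site reads\n",
              x$assay, x$sample_id, nrow(x$sites), x$n_site_reads))
  invisible(x)
}

#' Write a site set as BED6
#'
#' One line per site: chrom, pos0, pos0+1, ".", depth, strand; deterministic
#' ordering (chrom lexical, then position, then strand).
#'
#' @param sites An `ap_sites` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  s <- sites$sites
  if (any(s$depth < 1L)) stop("site with depth < 1")
  if (nrow(s) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  df <- data.frame(s$chrom, s$pos0, s$pos0 + 1L, ".", s$depth, s$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a site set from BED6
#'
#' @param path BED6 path as written by [write_sites()].
#' @param ... Sample metadata passed to [ap_site_set()].
#' @return An `ap_sites` object.
#' @export
load_sites <- function(path, ...) {
  if (file.size(path) == 0) {
    return(ap_site_set(NULL, ...))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character"))
  ap_site_set(data.frame(chrom = df[[1]], pos0 = df[[2]],
                         strand = df[[6]], depth = df[[5]]), ...)
}

# Stranded position keys "chrom:pos0:strand".
site_keys <- function(x) {
  s <- if (inherits(x, "ap_sites")) x$sites else x
  paste(s$chrom, s$pos0, s$strand, sep = ":")
}

# Aggregate raw per-read calls (chrom, pos0, strand) into a depth table.
aggregate_calls <- function(chrom, pos0, strand) {
  if (length(pos0) == 0L) {
    return(data.frame(chrom = character(), pos0 = integer(),
                      strand = character(), depth = integer()))
  }
  key <- paste(chrom, pos0, strand, sep = "\r")
  t <- table(key)
  parts <- strsplit(names(t), "\r", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             pos0 = as.integer(vapply(parts, `[`, "", 2L)),
             strand = vapply(parts, `[`, "", 3L),
             depth = as.integer(t))
}
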