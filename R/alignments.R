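#' Load paired alignments from a SAM file
#'
#' Assembles mate pairs by read name. Coordinates are converted from SAM's
#' 1-based POS to the package's 0-based convention on read. Records whose
#' mate is absent are counted, not returned.
#'
#' @param path SAM file (plain text, with header).
#' @return A list with `pairs` (data frame, one row per mate pair; columns
#'   `name`, then `r1_`/`r2_`-prefixed `chrom`, `pos0` (leftmost), `strand`,
#'   `mapq`, `flag`, `cigar`, `seq`) and `skipped` (unpaired record count).
#' @export
load_alignments <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1], "@")) {
    stop("SAM file has no header: ", path)
  }
  body <- which(!startsWith(lines, "@"))
  recs <- strsplit(lines[body], "\t", fixed = TRUE)
  short <- which(lengths(recs) < 11L)
  if (length(short)) {
    stop("truncated SAM record at line ", body[short[1]])
  }
  f <- function(k) vapply(recs, `[`, "", k)
  df <- data.frame(
    name = f(1), flag = as.integer(f(2)), chrom = f(3),
    pos0 = as.integer(f(4)) - 1L, mapq = as.integer(f(5)),
    cigar = f(6), seq = f(10), stringsAsFactors = FALSE)
  df$strand <- ifelse(bitwAnd(df$flag, 16L) > 0L, "-", "+")
  df$mate <- ifelse(bitwAnd(df$flag, 64L) > 0L, 1L,
                    ifelse(bitwAnd(df$flag, 128L) > 0L, 2L, NA_integer_))
  pair_records(df)
}

pair_records <- function(df) {
  r1 <- df[!is.na(df$mate) & df$mate == 1L, , drop = FALSE]
  r2 <- df[!is.na(df$mate) & df$mate == 2L, , drop = FALSE]
  common <- intersect(r1$name, r2$name)
  skipped <- nrow(df) - 2L * length(common)
  i1 <- match(common, r1$name)
  i2 <- match(common, r2$name)
  # preserve input order of read 1 records
  ord <- order(i1)
  i1 <- i1[ord]; i2 <- i2[ord]
  cols <- c("chrom", "pos0", "strand", "mapq", "flag", "cigar", "seq")
  pairs <- data.frame(name = r1$name[i1], stringsAsFactors = FALSE)
  for (k in cols) pairs[[paste0("r1_", k)]] <- r1[[k]][i1]
  for (k in cols) pairs[[paste0("r2_", k)]] <- r2[[k]][i2]
  rownames(pairs) <- NULL
  list(pairs = pairs, skipped = skipped)
}

#' Write paired alignments as SAM
#'
#' @param pairs Pair data frame as returned by [load_alignments()] or
#'   [align_exact()].
#' @param chrom_lengths Named vector of reference lengths for the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  rec <- function(name, p, mate_pos0) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*",
            name, p$flag, p$chrom, p$pos0 + 1L, p$mapq, p$cigar,
            "=", mate_pos0 + 1L, p$seq)
  }
  g <- function(m) {
    list(flag = pairs[[paste0(m, "_flag")]],
         chrom = pairs[[paste0(m, "_chrom")]],
         pos0 = pairs[[paste0(m, "_pos0")]],
         mapq = pairs[[paste0(m, "_mapq")]],
         cigar = pairs[[paste0(m, "_cigar")]],
         seq = pairs[[paste0(m, "_seq")]])
  }
  r1 <- g("r1"); r2 <- g("r2")
  out <- character(2L * nrow(pairs))
  if (nrow(pairs)) {
    out[c(TRUE, FALSE)] <- rec(pairs$name, r1, r2$pos0)
    out[c(FALSE, TRUE)] <- rec(pairs$name, r2, r1$pos0)
  }
  writeLines(c(hdr, out), path)
  invisible(path)
}

# SAM flag helpers: proper pair with read 2 on `r2_strand`.
# r1 gets 99/83, r2 gets 163/147.
pair_flags <- function(r2_strand) {
  r1 <- ifelse(r2_strand == "-", 99L, 83L)
  r2 <- ifelse(r2_strand == "-", 147L, 163L)
  list(r1 = r1, r2 = r2)
}

# 0-based coordinate of the first *sequenced* base of an aligned read:
# leftmost for "+", rightmost (5' end) for "-". Reference span length is
# taken from the CIGAR (M/D/N/=/X consume reference).
read_five_prime_pos <- function(pos0, strand, cigar) {
  span <- cigar_ref_span(cigar)
  ifelse(strand == "+", pos0, pos0 + span - 1L)
}

cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# CIGAR operation at the first sequenced base (read orientation): first op
# for "+", last op for "-". Hard clips are ignored.
leading_op <- function(cigar, strand) {
  mapply(function(cg, st) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    op <- sub("^\\d+", "", ops)
    op <- op[op != "H"]
    if (!length(op)) return("*")
    if (st == "+") op[1] else op[length(op)]
  }, cigar, strand, USE.NAMES = FALSE)
}
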