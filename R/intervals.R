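#' Interval sets
#'
#' Feature collections (repeat classes, exons, introns, TSS flanks,
#' regulatory elements) are plain data frames with columns `chrom`, `start`,
#' `end` (0-based half-open), `strand` ("+", "-" or "."), `class` and `name`.
#'
#' @param chrom,start,end,strand,class,name Vectors recycled to a common
#'   length.
#' @return An interval data frame.
#' @export
intervals <- function(chrom = character(), start = integer(),
                      end = integer(), strand = ".",
                      class = "feature", name = ".") {
  if (length(chrom) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      class = character(), name = character()))
  }
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   class = as.character(class), name = as.character(name),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$start >= df$end)) {
    stop("interval with start >= end")
  }
  if (nrow(df) && any(!nzchar(df$class))) stop("empty class label")
  df[order(df$chrom, df$start), , drop = FALSE]
}

empty_intervals <- function() intervals()

validate_intervals <- function(iv, chrom_lengths) {
  if (nrow(iv) == 0L) return(invisible(iv))
  unknown <- setdiff(unique(iv$chrom), names(chrom_lengths))
  if (length(unknown)) stop("interval on unknown chromosome: ", unknown[1])
  L <- chrom_lengths[iv$chrom]
  bad <- which(iv$start < 0L | iv$end > L)
  if (length(bad)) {
    stop(sprintf("interval out of bounds: %s:%d-%d", iv$chrom[bad[1]],
                 iv$start[bad[1]], iv$end[bad[1]]))
  }
  invisible(iv)
}

#' Read a BED-like interval file
#'
#' Columns: chrom, start, end, then optionally name, class, strand. The class
#' label is carried in the 5th column (the BED score slot); when absent the
#' name column doubles as the class.
#'
#' @param path Input path.
#' @param stranded Whether the 6th column should be interpreted as strand.
#' @return An interval data frame.
#' @export
read_intervals <- function(path, stranded = TRUE) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", comment.char = "#"),
    error = function(e) NULL)
  if (is.null(df)) return(empty_intervals())
  nc <- ncol(df)
  intervals(
    chrom = df[[1]],
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    strand = if (stranded && nc >= 6) df[[6]] else ".",
    class = if (nc >= 5) df[[5]] else if (nc >= 4) df[[4]] else "feature",
    name = if (nc >= 4) df[[4]] else "."
  )
}

#' Write an interval data frame as BED-like text
#'
#' @param iv Interval data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(iv, path) {
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  utils::write.table(
    data.frame(iv$chrom, iv$start, iv$end, iv$name, iv$class, iv$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping intervals
#'
#' Strand and class are ignored: the result is the union of covered bases,
#' as used for repeat-mask length accounting.
#'
#' @param iv Interval data frame.
#' @return Interval data frame of disjoint merged records.
#' @export
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  out <- lapply(split(iv, iv$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    intervals(chrom = d$chrom[1], start = IRanges::start(r) - 1L,
              end = IRanges::end(r), class = "merged")
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Sum of merged interval lengths, per class label.
class_lengths <- function(iv) {
  if (nrow(iv) == 0L) return(numeric())
  vapply(split(iv, iv$class), masked_bases, numeric(1))
}

# Logical: is each (chrom, pos0) inside any interval? Strand-blind.
pos_in_intervals <- function(chrom, pos0, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(pos0)))
  hit <- rep(FALSE, length(pos0))
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    d <- iv[iv$chrom == cn, , drop = FALSE]
    if (nrow(d) == 0L) next
    q <- IRanges::IRanges(start = pos0[i] + 1L, width = 1L)
    s <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    hit[i] <- IRanges::overlapsAny(q, s)
  }
  hit
}

# Index pairs (query position index, subject interval row) of overlaps.
pos_interval_hits <- function(chrom, pos0, iv) {
  if (nrow(iv) == 0L || length(pos0) == 0L) {
    return(data.frame(pos = integer(), iv = integer()))
  }
  res <- list()
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    j <- which(iv$chrom == cn)
    if (!length(j)) next
    q <- IRanges::IRanges(start = pos0[i] + 1L, width = 1L)
    s <- IRanges::IRanges(start = iv$start[j] + 1L, end = iv$end[j])
    ov <- IRanges::findOverlaps(q, s)
    res[[cn]] <- data.frame(pos = i[S4Vectors::queryHits(ov)],
                            iv = j[S4Vectors::subjectHits(ov)])
  }
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(pos = integer(), iv = integer()) else out
}

# Subtract merged mask from intervals of one class; returns merged
# non-masked bases count per class.
nonrepeat_class_lengths <- function(iv, mask) {
  if (nrow(iv) == 0L) return(numeric())
  vapply(split(iv, iv$class), function(d) {
    tot <- 0
    for (cn in unique(d$chrom)) {
      dd <- d[d$chrom == cn, , drop = FALSE]
      r <- IRanges::reduce(IRanges::IRanges(dd$start + 1L, dd$end))
      if (nrow(mask)) {
        mm <- mask[mask$chrom == cn, , drop = FALSE]
        if (nrow(mm)) {
          r <- IRanges::setdiff(r, IRanges::IRanges(mm$start + 1L, mm$end))
        }
      }
      tot <- tot + sum(as.numeric(IRanges::width(r)))
    }
    tot
  }, numeric(1))
}
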