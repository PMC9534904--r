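#' AP-site fraction (APF) / strand-break fraction (ASF)
#'
#' The number of read pairs representing lesion sites divided by the number
#' of read pairs with the expected tag structure in the same library. The
#' same formula on an SSB library yields the ASF.
#'
#' @param site_read_count Lesion-representing read pairs (sum of site
#'   depths after all filters).
#' @param tag_pass_pair_count Tag-structure-passing read pairs.
#' @return Fraction in [0, 1]; NA when the denominator is zero.
#' @export
compute_apf <- function(site_read_count, tag_pass_pair_count) {
  if (is.na(tag_pass_pair_count) || tag_pass_pair_count == 0) {
    return(NA_real_)
  }
  v <- site_read_count / tag_pass_pair_count
  stopifnot(v >= 0, v <= 1)
  v
}

#' Library size-range fraction (APL) from a fragment-size profile
#'
#' Fraction of DNA mass in the 180-1000 bp range (above the ~160 bp maximum
#' primer-dimer size) relative to the total mass in 1-1000 bp, computed by
#' trapezoid integration of the electropherogram intensity over size.
#'
#' @param profile Data frame `size_bp`, `intensity` (strictly increasing
#'   sizes), e.g. from [read_size_profile()].
#' @param signal_range,total_range Integration ranges in bp.
#' @return Fraction in [0, 1]; NA when the total integral is zero.
#' @export
compute_apl <- function(profile, signal_range = c(180, 1000),
                        total_range = c(1, 1000)) {
  num <- integrate_profile(profile, signal_range[1], signal_range[2])
  den <- integrate_profile(profile, total_range[1], total_range[2])
  if (den == 0) return(NA_real_)
  num / den
}

# Trapezoid integral of the piecewise-linear profile restricted to
# [lo, hi], with linear interpolation at the range boundaries.
integrate_profile <- function(profile, lo, hi) {
  x <- profile$size_bp; y <- profile$intensity
  if (length(x) < 2L || hi <= x[1] || lo >= x[length(x)]) return(0)
  lo <- max(lo, x[1]); hi <- min(hi, x[length(x)])
  inner <- x > lo & x < hi
  xs <- c(lo, x[inner], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inner],
          stats::approx(x, y, xout = hi)$y)
  pracma::trapz(xs, ys)
}
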