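#' Smooth a 4C near-cis profile
#'
#' Centered moving mean over a `span`-wide window (default 5 kb on 50 bp
#' bins, i.e. the mean of the ~100 bins around each bin). Windows shrink
#' at chromosome ends — the mean is taken over the bins available — so no
#' artificial dilution is introduced at termini. Smoothing is for display;
#' quantification uses the unsmoothed track.
#'
#' @param track A `signal_track` (typically 50 bp bins).
#' @param span Smoothing span in bp (default 5000), a multiple of the bin
#'   size and at least one bin.
#' @return The smoothed `signal_track`.
#' @export
smooth_4c <- function(track, span = 5000) {
  bs <- track_bin_size(track)
  if (span < bs) stop("`span` must be at least one bin", call. = FALSE)
  if (span %% bs != 0) stop("`span` must be a multiple of the bin size",
                            call. = FALSE)
  w <- as.integer(span / bs)
  # window covers exactly span/bin bins: centered for odd w, one extra bin
  # downstream for even w
  off_lo <- (w - 1L) %/% 2L
  off_hi <- w %/% 2L
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    sel <- sel[order(track$bin[sel])]
    v <- track$value[sel]
    n <- length(v)
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_len(n) - off_lo, 1)
    hi <- pmin(seq_len(n) + off_hi, n)
    track$value[sel] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  attr(track, "normalization") <- paste0(attr(track, "normalization"),
                                         "+smoothed")
  track
}

#' Quantify a 4C region against a background region
#'
#' The mean unsmoothed signal over the region of interest divided by the
#' mean over a far-cis background region on the same chromosome.
#'
#' @param track An (unsmoothed) normalized `signal_track`.
#' @param region,background Interval tibbles or 1-row lists with `chrom`,
#'   `start`, `end`.
#' @return A list: `ratio` (`NA`, flagged, when the background mean is 0),
#'   `region_mean`, `background_mean`.
#' @export
quantify_region <- function(track, region, background) {
  as_iv <- function(x) tibble::tibble(chrom = x$chrom[[1]],
                                      start = x$start[[1]], end = x$end[[1]])
  r <- signal_at_intervals(track, as_iv(region))
  b <- signal_at_intervals(track, as_iv(background))
  if (is.na(b) || b == 0) {
    warning("background mean is zero; ratio undefined", call. = FALSE)
    return(list(ratio = NA_real_, region_mean = r, background_mean = b))
  }
  list(ratio = r / b, region_mean = r, background_mean = b)
}
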