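#' Diamond insulation score
#'
#' For each bin `i`, the raw score is the mean balanced contact in the
#' `w x w` diamond pairing the `w` bins upstream with the `w` bins
#' downstream (`w = window / resolution`). The reported value is
#' `log2(raw_i / mean(raw))` against the chromosome-wide mean, so a global
#' rescaling of the matrix cancels. Bins whose diamond does not fit on the
#' chromosome, or masked bins, are `NA`. Local minima mark insulating
#' (TAD) boundaries.
#'
#' @param mat A `balanced`-state `contact_matrix`.
#' @param window Diamond extent in bp on each side (must be a multiple of
#'   the matrix bin size, and at least 2 bins).
#' @return An insulation tibble `chrom`, `bin`, `start`, `insulation`
#'   (log2), with attributes `window` and `resolution`.
#' @export
insulation_score <- function(mat, window) {
  if (mat$state != "balanced") {
    stop("insulation requires a balanced matrix", call. = FALSE)
  }
  res <- mat$bin_size
  if (window %% res != 0) {
    stop("`window` must be a multiple of the bin size", call. = FALSE)
  }
  w <- as.integer(window / res)
  if (w < 2) stop("`window` must span at least 2 bins", call. = FALSE)
  n <- mat$n_bins
  M <- dense_matrix(mat)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    if (is.na(mat$weights[i])) next
    D <- M[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
    if (all(is.na(D))) next
    raw[i] <- mean(D, na.rm = TRUE)
  }
  mu <- mean(raw[is.finite(raw)])
  ins <- ifelse(is.na(raw), NA_real_,
                ifelse(raw > 0, log2(raw / mu), -Inf))
  out <- tibble::tibble(chrom = mat$chrom, bin = 0:(n - 1),
                        start = (0:(n - 1)) * res, insulation = ins)
  attr(out, "window") <- window
  attr(out, "resolution") <- res
  out
}

#' Aggregate insulation change around features
#'
#' Aligns the per-bin insulation difference (`after - before`) on each
#' feature's center and averages across features — the aggregate boundary
#' strengthening/weakening profile.
#'
#' @param before,after Insulation tibbles from [insulation_score()] on the
#'   same binning (row-bind across chromosomes for multi-chromosome use).
#' @param features Interval tibble; features on chromosomes absent from
#'   the tracks are skipped.
#' @param flank Flank in bp on each side of the feature center.
#' @return A list: `profile` — tibble `offset_bp`, `mean_delta`,
#'   `n_features`; `per_feature` — tibble with one row per used feature and
#'   its central delta (`delta_center`).
#' @export
aggregate_insulation_delta <- function(before, after, features, flank) {
  res <- attr(before, "resolution")
  if (is.null(res)) res <- attr(after, "resolution")
  stopifnot(!is.null(res))
  fb <- as.integer(flank %/% res)
  offs <- -fb:fb
  key_b <- paste(before$chrom, before$bin)
  delta <- after$insulation[match(key_b, paste(after$chrom, after$bin))] -
    before$insulation
  sums <- rep(0, length(offs))
  cnts <- rep(0, length(offs))
  rows <- list()
  for (i in seq_len(nrow(features))) {
    ch <- features$chrom[i]
    if (!any(before$chrom == ch)) next
    b <- floor(interval_mid(features$start[i], features$end[i]) / res)
    idx <- match(paste(ch, b + offs), key_b)
    v <- delta[idx]
    ok <- !is.na(v) & is.finite(v)
    sums[ok] <- sums[ok] + v[ok]
    cnts[ok] <- cnts[ok] + 1
    ctr <- v[fb + 1L]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chrom = ch, start = features$start[i], end = features$end[i],
      delta_center = if (length(ctr) && is.finite(ctr)) ctr else NA_real_)
  }
  profile <- tibble::tibble(
    offset_bp = offs * res,
    mean_delta = ifelse(cnts > 0, sums / cnts, NA_real_),
    n_features = cnts)
  list(profile = profile,
       per_feature = if (length(rows)) dplyr::bind_rows(rows) else
         tibble::tibble(chrom = character(), start = numeric(),
                        end = numeric(), delta_center = numeric()))
}
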