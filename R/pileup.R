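#' Aggregate peak analysis (APA)
#'
#' Stacks the `(2*flank_bins+1)^2` observed/expected submatrix centered on
#' each loop pixel and averages cell-wise (masked source cells are skipped
#' via per-cell denominators). The enrichment score is the mean of the
#' central 3x3 cells — the standard APA strength readout.
#'
#' @param mats A named list of `oe`-state `contact_matrix` objects (or a
#'   single one).
#' @param loops A loop tibble (see [loop_tbl()]).
#' @param flank_bins Flank on each side of the loop pixel, in bins
#'   (default 10).
#' @return A `pileup_result`: list with the mean matrix `pileup`, per-cell
#'   `counts`, `n_windows` used, `n_skipped` (off-chromosome windows),
#'   `enrichment`, and `resolution`.
#' @export
apa <- function(mats, loops, flank_bins = 10) {
  if (inherits(mats, "contact_matrix")) {
    mats <- stats::setNames(list(mats), mats$chrom)
  }
  centers <- lapply(seq_len(nrow(loops)), function(i) {
    m <- mats[[loops$chrom[i]]]
    if (is.null(m)) return(NULL)
    c1 <- floor(interval_mid(loops$start1[i], loops$end1[i]) / m$bin_size)
    c2 <- floor(interval_mid(loops$start2[i], loops$end2[i]) / m$bin_size)
    list(chrom = loops$chrom[i], i = c1, j = c2)
  })
  stack_windows(mats, centers, flank_bins)
}

#' Diagonal-centered local pileup
#'
#' Like [apa()] but each window is centered on the diagonal at an anchor's
#' bin — the local-interaction readout used for promoters, enhancers, CTCF
#' sites and superenhancers.
#'
#' @param mats `oe` contact matrices (named list or single).
#' @param anchors An interval tibble (`chrom`, `start`, `end`).
#' @param flank_bins Flank in bins (default 10).
#' @return A `pileup_result` (see [apa()]).
#' @export
local_pileup <- function(mats, anchors, flank_bins = 10) {
  if (inherits(mats, "contact_matrix")) {
    mats <- stats::setNames(list(mats), mats$chrom)
  }
  centers <- lapply(seq_len(nrow(anchors)), function(i) {
    m <- mats[[anchors$chrom[i]]]
    if (is.null(m)) return(NULL)
    b <- floor(interval_mid(anchors$start[i], anchors$end[i]) / m$bin_size)
    list(chrom = anchors$chrom[i], i = b, j = b)
  })
  stack_windows(mats, centers, flank_bins)
}

stack_windows <- function(mats, centers, flank_bins) {
  F <- as.integer(flank_bins)
  side <- 2L * F + 1L
  S <- matrix(0, side, side)
  N <- matrix(0, side, side)
  dense <- list()
  used <- 0L
  skipped <- 0L
  res <- NULL
  for (ct in centers) {
    if (is.null(ct)) { skipped <- skipped + 1L; next }
    m <- mats[[ct$chrom]]
    res <- m$bin_size
    n <- m$n_bins
    if (ct$i - F < 0 || ct$j - F < 0 || ct$i + F >= n || ct$j + F >= n) {
      skipped <- skipped + 1L
      next
    }
    if (is.null(dense[[ct$chrom]])) dense[[ct$chrom]] <- dense_oe(m)
    W <- dense[[ct$chrom]][(ct$i - F):(ct$i + F) + 1L,
                           (ct$j - F):(ct$j + F) + 1L]
    ok <- !is.na(W)
    S[ok] <- S[ok] + W[ok]
    N[ok] <- N[ok] + 1
    used <- used + 1L
  }
  if (used == 0) stop("no usable windows for pileup", call. = FALSE)
  P <- ifelse(N > 0, S / N, NA_real_)
  new_pileup(P, N, used, skipped, res)
}

new_pileup <- function(P, N, used, skipped, resolution) {
  ctr <- (nrow(P) + 1L) %/% 2L
  sel <- max(1L, ctr - 1L):min(nrow(P), ctr + 1L)
  structure(
    list(pileup = P, counts = N, n_windows = used, n_skipped = skipped,
         enrichment = mean(P[sel, sel], na.rm = TRUE),
         resolution = resolution),
    class = "pileup_result")
}

#' @export
print.pileup_result <- function(x, ...) {
  cat("<pileup_result> ", nrow(x$pileup), "x", ncol(x$pileup), " cells, ",
      x$n_windows, " windows (", x$n_skipped, " skipped), central 3x3 ",
      "enrichment = ", signif(x$enrichment, 4), "\n", sep = "")
  invisible(x)
}

#' Interaction-frequency enrichment curve around anchors
#'
#' For each genomic distance `d` up to `max_dist`, the mean O/E over all
#' pixels pairing an anchor's bin with a bin `d` away (both directions
#' pooled) — the per-distance profile of how strongly anchor-containing
#' bins interact.
#'
#' @param mats `oe` contact matrices (named list or single).
#' @param anchors Interval tibble.
#' @param max_dist Maximum distance in bp.
#' @return A tibble `distance_bp`, `mean_oe`, `n_pixels`.
#' @export
pileup_decay_curve <- function(mats, anchors, max_dist) {
  if (inherits(mats, "contact_matrix")) {
    mats <- stats::setNames(list(mats), mats$chrom)
  }
  sums <- NULL
  for (ch in unique(anchors$chrom)) {
    m <- mats[[ch]]
    if (is.null(m)) next
    D <- as.integer(max_dist %/% m$bin_size)
    if (is.null(sums)) {
      sums <- rep(0, D + 1)
      cnts <- rep(0, D + 1)
      res <- m$bin_size
    }
    M <- dense_oe(m)
    n <- m$n_bins
    sel <- anchors$chrom == ch
    bins <- floor(interval_mid(anchors$start[sel], anchors$end[sel]) /
                    m$bin_size)
    for (b in bins) {
      for (d in 0:D) {
        for (o in unique(c(b - d, b + d))) {
          if (o >= 0 && o < n) {
            v <- M[b + 1L, o + 1L]
            if (!is.na(v)) {
              sums[d + 1] <- sums[d + 1] + v
              cnts[d + 1] <- cnts[d + 1] + 1
            }
          }
        }
      }
    }
  }
  if (is.null(sums)) {
    return(tibble::tibble(distance_bp = numeric(), mean_oe = numeric(),
                          n_pixels = numeric()))
  }
  keep <- cnts > 0
  tibble::tibble(distance_bp = (0:(length(sums) - 1))[keep] * res,
                 mean_oe = sums[keep] / cnts[keep], n_pixels = cnts[keep])
}

#' Rescaled meta-domain pileup
#'
#' Each domain of length `L` is padded by `pad_factor * L` on both sides,
#' its on-diagonal O/E submatrix extracted and block-averaged down (or up)
#' to `out_size x out_size`, and the rescaled windows averaged — the
#' meta-TAD map. Block averaging is mass-preserving and deterministic; no
#' interpolation.
#'
#' @param mats `oe` contact matrices (named list or single).
#' @param domains Interval tibble of domains (`chrom`, `start`, `end`),
#'   each at least 3 bins long.
#' @param out_size Side length of the rescaled window in cells.
#' @param pad_factor Padding as a multiple of domain length (default 1).
#' @return A `pileup_result` whose `enrichment` is the mean of the central
#'   domain block relative cells; windows falling off-chromosome are
#'   skipped and counted.
#' @export
rescaled_domain_pileup <- function(mats, domains, out_size = 90,
                                   pad_factor = 1.0) {
  if (inherits(mats, "contact_matrix")) {
    mats <- stats::setNames(list(mats), mats$chrom)
  }
  S <- matrix(0, out_size, out_size)
  N <- matrix(0, out_size, out_size)
  used <- 0L
  skipped <- 0L
  res <- NULL
  for (i in seq_len(nrow(domains))) {
    m <- mats[[domains$chrom[i]]]
    if (is.null(m)) { skipped <- skipped + 1L; next }
    res <- m$bin_size
    b0 <- floor(domains$start[i] / m$bin_size)
    b1 <- ceiling(domains$end[i] / m$bin_size) - 1L
    L <- b1 - b0 + 1L
    if (L < 3) { skipped <- skipped + 1L; next }
    pad <- as.integer(round(pad_factor * L))
    lo <- b0 - pad
    hi <- b1 + pad
    if (lo < 0 || hi >= m$n_bins) { skipped <- skipped + 1L; next }
    M <- dense_oe(m)
    W <- M[(lo:hi) + 1L, (lo:hi) + 1L]
    R <- block_resample(W, out_size)
    ok <- !is.na(R)
    S[ok] <- S[ok] + R[ok]
    N[ok] <- N[ok] + 1
    used <- used + 1L
  }
  if (used == 0) stop("no usable domains for pileup", call. = FALSE)
  P <- ifelse(N > 0, S / N, NA_real_)
  new_pileup(P, N, used, skipped, res)
}

# Resample a square matrix to out x out by averaging source cells assigned
# proportionally to target cells (NA-aware).
block_resample <- function(W, out) {
  n <- nrow(W)
  if (n == out) return(W)
  map <- pmin(out, floor(seq_len(n) * out / n - 1e-9) + 1L)
  S <- matrix(0, out, out)
  N <- matrix(0, out, out)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      v <- W[a, b]
      if (!is.na(v)) {
        S[map[a], map[b]] <- S[map[a], map[b]] + v
        N[map[a], map[b]] <- N[map[a], map[b]] + 1
      }
    }
  }
  ifelse(N > 0, S / N, NA_real_)
}

#' Write a pileup result
#'
#' Tab-separated square matrix plus a JSON sidecar (`<path>.json`) with
#' `n_windows`, `n_skipped`, `enrichment` and `resolution`.
#'
#' @param x A `pileup_result`.
#' @param path Output path for the matrix.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(x, path) {
  utils::write.table(x$pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(n_windows = x$n_windows, n_skipped = x$n_skipped,
         enrichment = x$enrichment, resolution = x$resolution),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
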