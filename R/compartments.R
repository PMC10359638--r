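#' Compartment eigenvector of an O/E matrix
#'
#' The leading eigenvector of the Pearson correlation matrix of the dense
#' observed/expected map — the usual A/B compartment summary. The result is
#' unsigned: orient it against an active-chromatin reference with
#' [orient_eigenvector()] before calling the positive side "A".
#'
#' @param mat An `oe`-state `contact_matrix`.
#' @param min_bins Minimum number of unmasked bins required (default 20);
#'   below this the chromosome is skipped with a warning.
#' @return A tibble `chrom`, `bin`, `start`, `E1` (unit-norm, `NA` at
#'   masked or degenerate bins); `NULL` (with a warning) for a skipped or
#'   degenerate chromosome.
#' @export
compartment_eigenvector <- function(mat, min_bins = 20) {
  if (mat$state != "oe") stop("eigenvector requires an O/E matrix",
                              call. = FALSE)
  n <- mat$n_bins
  M <- dense_oe(mat)
  keep <- which(!is.na(mat$weights))
  E1 <- rep(NA_real_, n)
  if (length(keep) < min_bins) {
    warning("chromosome ", mat$chrom, " skipped: only ", length(keep),
            " unmasked bins", call. = FALSE)
    return(NULL)
  }
  A <- M[keep, keep, drop = FALSE]
  sds <- apply(A, 2, stats::sd, na.rm = TRUE)
  usable <- !is.na(sds) & sds > 0
  if (sum(usable) < min_bins) {
    warning("chromosome ", mat$chrom,
            " degenerate: O/E has (near-)constant columns, E1 undefined",
            call. = FALSE)
    return(NULL)
  }
  C <- suppressWarnings(
    stats::cor(A[usable, usable, drop = FALSE],
               use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  ev <- eigen(C, symmetric = TRUE)
  v <- ev$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  E1[keep[usable]] <- v
  tibble::tibble(chrom = mat$chrom, bin = 0:(n - 1),
                 start = (0:(n - 1)) * mat$bin_size, E1 = E1)
}

#' Orient a compartment eigenvector by an active-chromatin track
#'
#' An eigenvector's sign is arbitrary; by convention positive values mark
#' the active (A) compartment. Per chromosome, the eigenvector is negated
#' iff its Pearson correlation with the active reference (e.g. an H3K27ac
#' coverage track binned at the same resolution) is negative.
#'
#' @param e1 Eigenvector tibble from [compartment_eigenvector()] (possibly
#'   row-bound across chromosomes).
#' @param active A `signal_track` on the same binning.
#' @return The eigenvector tibble with signs fixed and a logical
#'   `flipped` attribute naming chromosomes that were negated; chromosomes
#'   with zero-variance overlap are left unchanged with a warning.
#' @export
orient_eigenvector <- function(e1, active) {
  flipped <- character()
  for (ch in unique(e1$chrom)) {
    sel <- e1$chrom == ch
    a <- active$value[match(paste(ch, e1$bin[sel]),
                            paste(active$chrom, active$bin))]
    ok <- !is.na(e1$E1[sel]) & !is.na(a)
    if (sum(ok) < 3 || stats::sd(e1$E1[sel][ok]) == 0 ||
        stats::sd(a[ok]) == 0) {
      warning("orientation undefined on ", ch,
              " (zero-variance overlap); sign left unchanged",
              call. = FALSE)
      next
    }
    if (stats::cor(e1$E1[sel][ok], a[ok]) < 0) {
      e1$E1[sel] <- -e1$E1[sel]
      flipped <- c(flipped, ch)
    }
  }
  attr(e1, "flipped") <- flipped
  e1
}

#' Saddle decomposition and compartmentalization score
#'
#' Bins are ranked by eigenvector value into equal-occupancy quantiles per
#' chromosome (ties broken by bin index) and the mean O/E contact is pooled
#' genome-wide for every quantile pair. The compartment strength is
#' `(AA + BB) / (2 * AB)` where `AA` is the mean O/E among the top
#' `top_frac` of bins (the strongest A side), `BB` among the bottom
#' `top_frac`, and `AB` across the A-vs-B rectangle between them.
#'
#' @param mats A list of `oe`-state `contact_matrix` objects (or a single
#'   one).
#' @param e1 A signed eigenvector tibble covering those chromosomes.
#' @param n_quantiles Number of eigenvector quantiles (default 50).
#' @param top_frac Fraction of quantiles defining the A (top) and B
#'   (bottom) blocks (default 0.2).
#' @return A `saddle_result`: list with the `Q x Q` `saddle` matrix (mean
#'   O/E per quantile pair), `counts`, `AA`, `BB`, `AB`, `enrichment`, and
#'   the parameters. `enrichment` is `NA` when `AB` is undefined or zero.
#' @export
saddle <- function(mats, e1, n_quantiles = 50, top_frac = 0.2) {
  if (inherits(mats, "contact_matrix")) mats <- list(mats)
  if (n_quantiles < 5) stop("`n_quantiles` must be >= 5", call. = FALSE)
  Q <- as.integer(n_quantiles)
  S <- matrix(0, Q, Q)
  N <- matrix(0, Q, Q)
  for (mat in mats) {
    if (mat$state != "oe") stop("saddle requires O/E matrices", call. = FALSE)
    sel <- e1$chrom == mat$chrom & !is.na(e1$E1)
    bins <- e1$bin[sel]
    vals <- e1$E1[sel]
    if (length(bins) < Q) next
    # equal-occupancy quantiles, ties broken by bin index
    rk <- rank(vals, ties.method = "first")
    q <- as.integer(ceiling(rk * Q / length(bins)))
    qb <- rep(NA_integer_, mat$n_bins)
    qb[bins + 1L] <- q
    M <- dense_oe(mat)
    use <- which(!is.na(qb))
    A <- M[use, use, drop = FALSE]
    qq <- qb[use]
    # pool sums and counts per quantile pair over the upper triangle
    iu <- which(upper.tri(A, diag = TRUE), arr.ind = TRUE)
    v <- A[iu]
    ok <- !is.na(v)
    qi <- qq[iu[ok, 1]]
    qj <- qq[iu[ok, 2]]
    v <- v[ok]
    lo <- pmin(qi, qj)
    hi <- pmax(qi, qj)
    idx <- (lo - 1L) * Q + hi
    sums <- tapply(v, idx, sum)
    cnts <- tapply(rep(1, length(v)), idx, sum)
    pos <- as.integer(names(sums))
    r <- (pos - 1L) %/% Q + 1L
    c_ <- (pos - 1L) %% Q + 1L
    S[cbind(r, c_)] <- S[cbind(r, c_)] + as.numeric(sums)
    N[cbind(r, c_)] <- N[cbind(r, c_)] + as.numeric(cnts)
  }
  # symmetrize (accumulated on lo<=hi only)
  S <- S + t(S) - diag(diag(S), Q)
  N <- N + t(N) - diag(diag(N), Q)
  sad <- ifelse(N > 0, S / N, NA_real_)
  k <- max(1L, as.integer(round(top_frac * Q)))
  top <- (Q - k + 1):Q     # highest-E1 quantiles (A)
  bot <- 1:k               # lowest-E1 quantiles (B)
  blk <- function(rows, cols) {
    s <- sum(S[rows, cols, drop = FALSE])
    n <- sum(N[rows, cols, drop = FALSE])
    if (n > 0) s / n else NA_real_
  }
  AA <- blk(top, top)
  BB <- blk(bot, bot)
  AB <- blk(top, bot)
  enr <- if (is.na(AB) || AB == 0) NA_real_ else (AA + BB) / (2 * AB)
  structure(
    list(saddle = sad, counts = N, quantiles = Q, top_frac = top_frac,
         AA = AA, BB = BB, AB = AB, enrichment = enr),
    class = "saddle_result")
}

#' @export
print.saddle_result <- function(x, ...) {
  cat("<saddle_result> ", x$quantiles, "x", x$quantiles,
      " quantile bins; AA=", signif(x$AA, 4), " BB=", signif(x$BB, 4),
      " AB=", signif(x$AB, 4), "; enrichment (AA+BB)/2AB = ",
      signif(x$enrichment, 4), "\n", sep = "")
  invisible(x)
}

#' Write a saddle result
#'
#' The `Q x Q` saddle matrix goes to a tab-separated file and the scalar
#' summary (AA/BB/AB/enrichment plus parameters) to a JSON sidecar at
#' `<path>.json`.
#'
#' @param x A `saddle_result`.
#' @param path Output path for the matrix.
#' @return `path`, invisibly.
#' @export
write_saddle <- function(x, path) {
  utils::write.table(x$saddle, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(AA = x$AA, BB = x$BB, AB = x$AB, enrichment = x$enrichment,
         n_quantiles = x$quantiles, top_frac = x$top_frac),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
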