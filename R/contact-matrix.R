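#' Construct a per-chromosome sparse contact matrix
#'
#' The container behind all Hi-C style computations: an upper-triangle
#' sparse pixel table for one chromosome at a fixed bin size, per-bin
#' balancing weights (`NA` = masked bin) and a state flag tracking which
#' transform the pixel values are in (`raw` counts, `balanced`, or
#' observed/expected `oe`).
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp.
#' @param n_bins Number of bins on the chromosome.
#' @param pixels Tibble `bin1`, `bin2`, `count` with `bin1 <= bin2`
#'   (0-based bin indices); duplicates are summed.
#' @param weights Per-bin balancing weights, `NA` where masked; defaults to
#'   all-`NA` for a raw matrix.
#' @param state One of `"raw"`, `"balanced"`, `"oe"`.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(chrom, bin_size, n_bins, pixels,
                           weights = rep(NA_real_, n_bins), state = "raw") {
  stopifnot(state %in% c("raw", "balanced", "oe"))
  pixels <- tibble::as_tibble(pixels)
  if (nrow(pixels)) {
    if (any(pixels$count < 0)) stop("negative contact counts", call. = FALSE)
    if (any(pixels$bin1 < 0 | pixels$bin2 >= n_bins)) {
      stop("pixel bin index out of range for ", chrom, call. = FALSE)
    }
    swap <- pixels$bin1 > pixels$bin2
    if (any(swap)) {
      tmp <- pixels$bin1[swap]
      pixels$bin1[swap] <- pixels$bin2[swap]
      pixels$bin2[swap] <- tmp
    }
    pixels <- dplyr::summarise(
      dplyr::group_by(pixels, .data$bin1, .data$bin2),
      count = sum(.data$count), .groups = "drop")
    pixels <- pixels[order(pixels$bin1, pixels$bin2), ]
    if (state == "raw" && any(abs(pixels$count - round(pixels$count)) > 1e-9)) {
      stop("raw counts must be integer-valued", call. = FALSE)
    }
  }
  structure(
    list(chrom = chrom, bin_size = bin_size, n_bins = as.integer(n_bins),
         pixels = pixels, weights = weights, state = state,
         converged = NA),
    class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", x$chrom, ": ", x$n_bins, " bins x ", x$bin_size,
      " bp, ", nrow(x$pixels), " pixels, state=", x$state,
      ", masked=", sum(is.na(x$weights)), "\n", sep = "")
  invisible(x)
}

#' Load contact matrices from a COO text file
#'
#' The format is tab-separated `chrom bin1 bin2 count` with a header line
#' `# bin_size=<bp>` (or `bin_size` passed explicitly). Pixels are folded
#' into the upper triangle and duplicates summed. Only intrachromosomal
#' pixels are representable in this format.
#'
#' @param path COO text file.
#' @param genome A [genome_model()].
#' @param bin_size Bin width in bp; read from the header when `NULL`.
#' @return A named list of `contact_matrix` objects, one per genome
#'   chromosome (chromosomes absent from the file get empty matrices).
#' @export
load_contacts <- function(path, genome, bin_size = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(bin_size)) {
    m <- regmatches(hdr, regexpr("bin_size=[0-9]+", hdr))
    if (length(m) == 0) stop("no bin_size header and none supplied",
                             call. = FALSE)
    bin_size <- as.numeric(sub("bin_size=", "", m[[1]]))
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(f) < 4)) {
      stop("malformed COO line ", which(lengths(f) < 4)[1], call. = FALSE)
    }
    tibble::tibble(chrom = vapply(f, `[[`, character(1), 1),
                   bin1 = as.numeric(vapply(f, `[[`, character(1), 2)),
                   bin2 = as.numeric(vapply(f, `[[`, character(1), 3)),
                   count = as.numeric(vapply(f, `[[`, character(1), 4)))
  } else {
    tibble::tibble(chrom = character(), bin1 = numeric(), bin2 = numeric(),
                   count = numeric())
  }
  if (nrow(df) && any(df$count < 0)) stop("negative counts", call. = FALSE)
  bad <- setdiff(unique(df$chrom), genome$chrom)
  if (length(bad)) stop("chromosome(s) not in genome: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out <- lapply(genome$chrom, function(ch) {
    nb <- genome_nbins(genome, ch, bin_size)
    px <- df[df$chrom == ch, c("bin1", "bin2", "count")]
    contact_matrix(ch, bin_size, nb, px)
  })
  stats::setNames(out, genome$chrom)
}

#' Write contact matrices to a COO text file
#' @param mats A named list of `contact_matrix` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(mats, path) {
  if (inherits(mats, "contact_matrix")) mats <- list(mats)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_size=%d", as.integer(mats[[1]]$bin_size)), con)
  for (m in mats) {
    if (nrow(m$pixels)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", m$chrom, as.integer(m$pixels$bin1),
                         as.integer(m$pixels$bin2),
                         format(m$pixels$count, trim = TRUE,
                                scientific = FALSE, digits = 15)), con)
    }
  }
  invisible(path)
}

#' Remove short-range pixels
#'
#' Keeps only pixels whose bin separation strictly exceeds `min_sep` bp, the
#' rule used to drop sub-resolution ligation noise: with `min_sep = 20000`
#' at 25 kb bins the self-diagonal goes and distance-1 pixels (25 kb)
#' stay.
#'
#' @param mat A `contact_matrix`.
#' @param min_sep Minimum genomic separation in bp (default 20 kb); pixels
#'   at separation `<= min_sep` are removed.
#' @return The filtered `contact_matrix`.
#' @export
filter_min_distance <- function(mat, min_sep = 20000) {
  if (min_sep < 0) stop("`min_sep` must be >= 0", call. = FALSE)
  sep <- (mat$pixels$bin2 - mat$pixels$bin1) * mat$bin_size
  mat$pixels <- mat$pixels[sep > min_sep, ]
  mat
}

#' Downsample contact pairs to a fixed depth
#'
#' Multinomial thinning of pixel counts: the retained total equals
#' `target_n` exactly and every pair is kept with equal probability, the
#' standard depth-matching step before comparing libraries.
#'
#' @param mat A raw-state `contact_matrix`.
#' @param target_n Target total count; must not exceed the current total.
#' @param seed Integer seed making the draw reproducible.
#' @return The thinned `contact_matrix` (zero-count pixels dropped).
#' @export
downsample_pairs <- function(mat, target_n, seed = 1L) {
  total <- sum(mat$pixels$count)
  if (target_n > total) {
    stop("`target_n` (", target_n, ") exceeds total count (", total, ")",
         call. = FALSE)
  }
  if (target_n == total) return(mat)
  local_seed(seed)
  if (nrow(mat$pixels) == 0 || target_n == 0) {
    mat$pixels <- mat$pixels[0, ]
    return(mat)
  }
  p <- mat$pixels$count / total
  newc <- as.numeric(stats::rmultinom(1, size = target_n, prob = p))
  mat$pixels$count <- newc
  mat$pixels <- mat$pixels[newc > 0, ]
  mat
}

# Dense symmetric matrix of current pixel values (NA where masked, for
# balanced/oe states). Structural zeros between unmasked bins are 0.
dense_matrix <- function(mat, na_masked = TRUE) {
  n <- mat$n_bins
  M <- matrix(0, n, n)
  if (nrow(mat$pixels)) {
    i <- mat$pixels$bin1 + 1L
    j <- mat$pixels$bin2 + 1L
    M[cbind(i, j)] <- mat$pixels$count
    M[cbind(j, i)] <- mat$pixels$count
  }
  if (na_masked && mat$state != "raw") {
    masked <- which(is.na(mat$weights))
    M[masked, ] <- NA_real_
    M[, masked] <- NA_real_
  }
  M
}

#' Iteratively balance a contact matrix (ICE)
#'
#' Iterative correction: low-coverage bins are masked by a
#' median-absolute-deviation cut on log marginals, then per-bin weights are
#' updated by dividing out the current marginal until the unmasked marginals
#' agree to within `tol` relative deviation. Weights are scaled so every
#' unmasked row of the balanced matrix sums to 1, the matrix-level analogue
#' of equal visibility per locus.
#'
#' @param mat A `contact_matrix` in `raw` (or `balanced`) state.
#' @param max_iter Maximum iterations (default 200).
#' @param tol Convergence tolerance on the max relative marginal deviation
#'   (default 1e-5).
#' @param mad_max Mask bins whose log marginal is more than this many MADs
#'   below the median (default 5); zero-marginal bins are always masked.
#' @return A `balanced`-state `contact_matrix` with `weights` filled in and
#'   a logical `converged` flag (non-convergence is flagged, not silent).
#' @export
ice_balance <- function(mat, max_iter = 200, tol = 1e-5, mad_max = 5) {
  if (mat$state == "oe") stop("cannot balance an O/E matrix", call. = FALSE)
  n <- mat$n_bins
  M <- dense_matrix(mat, na_masked = FALSE)
  marg <- rowSums(M)
  mask <- marg <= 0
  lm <- log(marg[!mask])
  if (length(lm)) {
    cut <- stats::median(lm) - mad_max * stats::mad(lm)
    mask[!mask][log(marg[!mask]) < cut] <- TRUE
  }
  if (all(mask)) stop("no unmasked bins to balance", call. = FALSE)
  keep <- which(!mask)
  A <- M[keep, keep, drop = FALSE]
  w <- rep(1, length(keep))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- as.numeric(A %*% w) * w
    ms <- mean(s)
    if (ms == 0) stop("degenerate matrix: zero marginals after masking",
                      call. = FALSE)
    dev <- max(abs(s / ms - 1))
    if (dev < tol) { converged <- TRUE; break }
    w <- w / sqrt(s / ms)
  }
  # scale so unmasked balanced rowsums are 1
  s <- as.numeric(A %*% w) * w
  w <- w / sqrt(mean(s))
  weights <- rep(NA_real_, n)
  weights[keep] <- w
  px <- mat$pixels
  if (nrow(px)) {
    wv <- weights[px$bin1 + 1L] * weights[px$bin2 + 1L]
    px$count <- px$count * wv
    px <- px[!is.na(px$count), ]
  }
  out <- mat
  out$pixels <- px
  out$weights <- weights
  out$state <- "balanced"
  out$converged <- converged
  if (!converged) {
    warning("ICE did not converge on ", mat$chrom, " within ", max_iter,
            " iterations", call. = FALSE)
  }
  out
}

#' Distance-decay expected profile
#'
#' The mean balanced contact at each bin separation, the per-chromosome
#' expected value used by the observed/expected transform. Structural zeros
#' between unmasked bins count in the denominator so long-range expectation
#' is not inflated.
#'
#' @param mat A `balanced`-state `contact_matrix`.
#' @return A tibble `chrom`, `distance` (bins), `distance_bp`, `expected`,
#'   `n_pixels` (valid unmasked pairs at that distance), for every distance
#'   with at least one unmasked pair.
#' @export
expected_by_distance <- function(mat) {
  if (mat$state != "balanced") {
    stop("expected profile requires a balanced matrix (state is '",
         mat$state, "')", call. = FALSE)
  }
  n <- mat$n_bins
  valid <- as.numeric(!is.na(mat$weights))
  # n_valid(d) = number of unmasked (i, i+d) pairs
  nv <- vapply(0:(n - 1), function(d) {
    sum(valid[seq_len(n - d)] * valid[seq_len(n - d) + d])
  }, numeric(1))
  sums <- rep(0, n)
  px <- mat$pixels
  if (nrow(px)) {
    d <- px$bin2 - px$bin1
    agg <- tapply(px$count, d, sum)
    sums[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  }
  keep <- nv >= 1
  tibble::tibble(
    chrom = mat$chrom,
    distance = (0:(n - 1))[keep],
    distance_bp = (0:(n - 1))[keep] * mat$bin_size,
    expected = sums[keep] / nv[keep],
    n_pixels = nv[keep]
  )
}

#' Observed/expected transform
#'
#' Divides each balanced pixel by the expected contact at its distance;
#' distances with zero expected are masked out. Per-diagonal O/E means are
#' 1 by construction.
#'
#' @param mat A `balanced`-state `contact_matrix`.
#' @param expected An expected profile from [expected_by_distance()];
#'   computed from `mat` when `NULL`.
#' @return An `oe`-state `contact_matrix`.
#' @export
oe_transform <- function(mat, expected = NULL) {
  if (mat$state != "balanced") {
    stop("O/E transform requires a balanced matrix", call. = FALSE)
  }
  if (is.null(expected)) expected <- expected_by_distance(mat)
  if (!all(expected$distance_bp %% mat$bin_size == 0) ||
      any(expected$distance * mat$bin_size != expected$distance_bp)) {
    stop("expected profile bin size does not match matrix", call. = FALSE)
  }
  px <- mat$pixels
  if (nrow(px)) {
    d <- px$bin2 - px$bin1
    e <- expected$expected[match(d, expected$distance)]
    ok <- !is.na(e) & e > 0
    px <- px[ok, ]
    px$count <- px$count / e[ok]
  }
  out <- mat
  out$pixels <- px
  out$state <- "oe"
  attr(out, "expected") <- expected
  out
}

#' Contact frequency vs genomic distance
#'
#' Aggregates pixel values into distance bins, the classic decay curve. On
#' a balanced matrix this is the scaling curve; on an O/E matrix it reads
#' enrichment relative to expectation.
#'
#' @param mat A `balanced` or `oe` `contact_matrix`.
#' @param min_sep Minimum separation in bp; shorter distances are excluded
#'   (default 0).
#' @param bin_scheme `"linear"` (one row per bin distance) or `"log"`
#'   (log2-spaced distance bins).
#' @param n_log_bins Number of log bins when `bin_scheme = "log"`.
#' @return A tibble `distance_bp` (bin midpoint), `mean_contact`,
#'   `n_pixels`.
#' @export
decay_curve <- function(mat, min_sep = 0, bin_scheme = c("linear", "log"),
                        n_log_bins = 30) {
  bin_scheme <- match.arg(bin_scheme)
  if (mat$state == "raw") stop("decay_curve needs balanced or oe state",
                               call. = FALSE)
  px <- mat$pixels
  sep <- (px$bin2 - px$bin1) * mat$bin_size
  keep <- sep >= min_sep & sep > 0
  px <- px[keep, ]
  sep <- sep[keep]
  if (nrow(px) == 0) {
    warning("no pixels after distance filtering", call. = FALSE)
    return(tibble::tibble(distance_bp = numeric(), mean_contact = numeric(),
                          n_pixels = numeric()))
  }
  grp <- if (bin_scheme == "linear") {
    sep
  } else {
    edges <- 2^seq(log2(min(sep)), log2(max(sep)) + 1e-9,
                   length.out = n_log_bins + 1)
    mids <- sqrt(edges[-1] * edges[-length(edges)])
    mids[pmax(pmin(findInterval(sep, edges, rightmost.closed = TRUE),
                   n_log_bins), 1L)]
  }
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(grp = grp, v = px$count), .data$grp),
    mean_contact = mean(.data$v), n_pixels = dplyr::n(), .groups = "drop")
  tibble::tibble(distance_bp = out$grp, mean_contact = out$mean_contact,
                 n_pixels = out$n_pixels)
}

# Dense O/E matrix: masked bins NA, and cells at distances where the
# expected profile is absent or zero (e.g. the filtered short range) NA
# rather than 0, so downstream averages skip them.
dense_oe <- function(mat) {
  stopifnot(mat$state == "oe")
  M <- dense_matrix(mat)
  expd <- attr(mat, "expected")
  n <- mat$n_bins
  valid_d <- rep(FALSE, n)
  if (!is.null(expd)) {
    ok <- expd$expected > 0
    valid_d[expd$distance[ok] + 1L] <- TRUE
  } else {
    valid_d[] <- TRUE
  }
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  M[!valid_d[D + 1L]] <- NA_real_
  M
}

# internal: seed the RNG for a reproducible draw
local_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}
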