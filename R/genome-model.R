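#' Define a genome model
#'
#' A genome model fixes the chromosome universe every other function works
#' against: chromosome names, their lengths in bp, and (optionally) a bin
#' size used wherever coordinates are discretised. Chromosome order is the
#' order given here, and all sorting in the package follows it — never
#' lexicographic order.
#'
#' All coordinates in the package are 0-based, half-open `[start, end)`.
#' Inputs in 1-based conventions must be converted by the caller.
#'
#' @param chroms Character vector of unique chromosome names.
#' @param sizes Integer vector of chromosome sizes in bp, same length.
#' @param bin_size Optional bin size in bp used for binned containers.
#' @return A `genome_model`: a tibble with columns `chrom` and `size`, plus a
#'   `bin_size` attribute.
#' @examples
#' genome_model(c("chr1", "chr2"), c(1e7, 8e6), bin_size = 25000)
#' @export
genome_model <- function(chroms, sizes, bin_size = NULL) {
  chroms <- as.character(chroms)
  sizes <- as.numeric(sizes)
  if (length(chroms) != length(sizes)) {
    stop("`chroms` and `sizes` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(chroms)) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    stop("chromosome sizes must be positive", call. = FALSE)
  }
  if (!is.null(bin_size)) {
    bin_size <- as.numeric(bin_size)
    if (length(bin_size) != 1 || !is.finite(bin_size) || bin_size <= 0) {
      stop("`bin_size` must be a single positive number", call. = FALSE)
    }
  }
  out <- tibble::tibble(chrom = chroms, size = sizes)
  attr(out, "bin_size") <- bin_size
  class(out) <- c("genome_model", class(out))
  out
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x), " chromosomes, ",
      format(sum(x$size), big.mark = ","), " bp",
      if (!is.null(attr(x, "bin_size"))) {
        paste0(", bin_size ", attr(x, "bin_size"))
      } else "",
      "\n", sep = "")
  NextMethod()
}

genome_size <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) {
    stop("chromosome(s) not in genome: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  genome$size[i]
}

genome_nbins <- function(genome, chrom, bin_size) {
  as.integer(ceiling(genome_size(genome, chrom) / bin_size))
}

#' Sort a genomic table by genome chromosome order, then start
#'
#' @param x A data frame with at least `chrom` and `start` columns.
#' @param genome A [genome_model()].
#' @return `x` sorted by (genome chromosome order, start, end).
#' @export
sort_genomic <- function(x, genome) {
  key <- match(x$chrom, genome$chrom)
  if (anyNA(key)) {
    stop("chromosome(s) not in genome: ",
         paste(unique(x$chrom[is.na(key)]), collapse = ", "), call. = FALSE)
  }
  end <- if ("end" %in% names(x)) x$end else x$start
  x[order(key, x$start, end), , drop = FALSE]
}

check_intervals <- function(x, genome, what = "interval") {
  if (nrow(x) == 0) return(invisible(x))
  sz <- genome_size(genome, x$chrom)
  bad <- x$start < 0 | x$start >= x$end | x$end > sz
  if (any(bad)) {
    stop(sum(bad), " ", what, "(s) fall outside their chromosome or have ",
         "start >= end (first offender: ", x$chrom[which(bad)[1]], ":",
         x$start[which(bad)[1]], "-", x$end[which(bad)[1]], ")", call. = FALSE)
  }
  invisible(x)
}

# Midpoint of half-open intervals, on the bp grid.
interval_mid <- function(start, end) floor((start + end) / 2)
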