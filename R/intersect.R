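#' Overlap two interval sets
#'
#' Overlap means at least one shared bp under half-open semantics, so
#' `[100,200)` and `[200,300)` do not overlap. Interval matching is done
#' with IRanges; results are returned per chromosome-matched pair.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`), sorted.
#' @return A list with `hits` — a logical vector, one element per row of
#'   `a`, `TRUE` where the interval overlaps any interval of `b` — and
#'   `pairs`, a tibble of overlapping index pairs (`a_idx`, `b_idx`) sorted
#'   by (`a_idx`, `b_idx`).
#' @export
intersect_peaks <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(hits = rep(FALSE, nrow(a)),
                pairs = tibble::tibble(a_idx = integer(), b_idx = integer())))
  }
  pairs <- overlap_pairs(a, b)
  hits <- rep(FALSE, nrow(a))
  hits[pairs$a_idx] <- TRUE
  list(hits = hits, pairs = pairs)
}

# Half-open interval overlap via IRanges (which is 1-based closed):
# [start, end) -> IRanges(start + 1, end).
overlap_pairs <- function(a, b) {
  ra <- IRanges::IRanges(a$start + 1, a$end)
  rb <- IRanges::IRanges(b$start + 1, b$end)
  hits <- IRanges::findOverlaps(ra, rb)
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  same <- a$chrom[ai] == b$chrom[bi]
  out <- tibble::tibble(a_idx = ai[same], b_idx = bi[same])
  out[order(out$a_idx, out$b_idx), ]
}

# TRUE per row of `a` overlapping any row of `b`.
overlaps_any <- function(a, b) intersect_peaks(a, b)$hits
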