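# Shared fixtures and brute-force oracles. Oracles are deliberately naive
# (quadratic scans, dictionary accumulation) and independent of the package
# internals they check.

tiny_genome <- function(sizes = c(chrA = 1e6, chrB = 8e5), bin_size = NULL) {
  genome_model(names(sizes), unname(sizes), bin_size = bin_size)
}

fixture_genome <- function() genome_model(c("chrS1", "chrS2"), c(1e7, 1e7),
                                          bin_size = 25000)

# random sparse symmetric raw matrix
random_matrix <- function(n_bins = 50, chrom = "chrA", bin_size = 1000,
                          density = 0.3, max_count = 20) {
  npx <- round(n_bins * (n_bins + 1) / 2 * density)
  i <- sample.int(n_bins, npx, replace = TRUE) - 1L
  j <- sample.int(n_bins, npx, replace = TRUE) - 1L
  contact_matrix(chrom, bin_size, n_bins,
                 tibble::tibble(bin1 = pmin(i, j), bin2 = pmax(i, j),
                                count = sample.int(max_count, npx,
                                                   replace = TRUE)))
}

# dense all-ones O/E matrix container (weights 1, every distance valid)
ones_oe <- function(n_bins = 40, chrom = "chrA", bin_size = 25000) {
  idx <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE),
               arr.ind = TRUE)
  m <- contact_matrix(chrom, bin_size, n_bins,
                      tibble::tibble(bin1 = idx[, 1] - 1L,
                                     bin2 = idx[, 2] - 1L, count = 1),
                      weights = rep(1, n_bins), state = "oe")
  m
}

# O/E container from an explicit dense symmetric matrix
oe_from_dense <- function(M, chrom = "chrA", bin_size = 25000) {
  n <- nrow(M)
  idx <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  v <- M[idx]
  keep <- v != 0
  contact_matrix(chrom, bin_size, n,
                 tibble::tibble(bin1 = idx[keep, 1] - 1L,
                                bin2 = idx[keep, 2] - 1L, count = v[keep]),
                 weights = rep(1, n), state = "oe")
}

# standard balance -> expected -> O/E chain
oe_chain <- function(mats, min_sep = 20000) {
  lapply(mats, function(m) {
    oe_transform(ice_balance(filter_min_distance(m, min_sep)))
  })
}

random_intervals <- function(n, genome, max_len = 5e4) {
  chrom <- sample(genome$chrom, n, replace = TRUE)
  start <- floor(stats::runif(n) * (genome_size(genome, chrom) - max_len))
  len <- ceiling(stats::runif(n) * max_len)
  sort_genomic(tibble::tibble(chrom = chrom, start = start,
                              end = start + len), genome)
}

# O(n^2) all-pairs half-open overlap oracle
oracle_overlap_pairs <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(a_idx = integer(), b_idx = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(a_idx = m[, 1], b_idx = m[, 2])
}

# dictionary-accumulation oracle for pixel sums
oracle_accumulate <- function(bin1, bin2, count) {
  d <- new.env()
  for (k in seq_along(bin1)) {
    key <- paste(min(bin1[k], bin2[k]), max(bin1[k], bin2[k]))
    d[[key]] <- (if (is.null(d[[key]])) 0 else d[[key]]) + count[k]
  }
  keys <- ls(d)
  parts <- do.call(rbind, strsplit(keys, " "))
  out <- tibble::tibble(bin1 = as.integer(parts[, 1]),
                        bin2 = as.integer(parts[, 2]),
                        count = vapply(keys, function(k) d[[k]],
                                       numeric(1)))
  out[order(out$bin1, out$bin2), ]
}

# naive per-diagonal average over a dense balanced matrix (zeros included
# between unmasked bins)
oracle_expected <- function(mat) {
  n <- mat$n_bins
  M <- matrix(0, n, n)
  if (nrow(mat$pixels)) {
    M[cbind(mat$pixels$bin1 + 1, mat$pixels$bin2 + 1)] <- mat$pixels$count
    M[cbind(mat$pixels$bin2 + 1, mat$pixels$bin1 + 1)] <- mat$pixels$count
  }
  unmasked <- which(!is.na(mat$weights))
  vapply(0:(n - 1), function(d) {
    i <- intersect(unmasked, seq_len(n - d))
    i <- i[(i + d) %in% unmasked]
    if (!length(i)) return(NA_real_)
    mean(M[cbind(i, i + d)])
  }, numeric(1))
}

# exhaustive predicate-and-sort oracle for responsive-loop classification
oracle_classify <- function(loops, tf_peaks, down_peaks, atac_peaks,
                            genome, min_length = 5e5, top_n = 500) {
  mid <- function(p) floor((p$start + p$end) / 2)
  contains <- function(lp_i, peaks) {
    any(peaks$chrom == loops$chrom[lp_i] &
          mid(peaks) >= loops$start1[lp_i] &
          mid(peaks) <= loops$end2[lp_i])
  }
  cand <- which(loops$length > min_length)
  score <- vapply(cand, function(i) {
    sel <- atac_peaks$chrom == loops$chrom[i] &
      mid(atac_peaks) >= loops$start1[i] & mid(atac_peaks) <= loops$end2[i]
    sum(atac_peaks$tf_signal[sel] + abs(atac_peaks$lfc[sel]))
  }, numeric(1))
  has_tf <- vapply(cand, contains, logical(1), peaks = tf_peaks)
  has_down <- vapply(cand, contains, logical(1), peaks = down_peaks)
  ckey <- match(loops$chrom[cand], genome$chrom)
  pool_r <- which(has_tf & has_down)
  pool_l <- which(!has_tf & !has_down)
  ord_r <- pool_r[order(-score[pool_r], ckey[pool_r],
                        loops$start1[cand][pool_r])]
  ord_l <- pool_l[order(score[pool_l], ckey[pool_l],
                        loops$start1[cand][pool_l])]
  list(responsive = cand[utils::head(ord_r, top_n)],
       less_responsive = cand[utils::head(ord_l, top_n)])
}

loop_key <- function(x) paste(x$chrom, x$start1, x$end1, x$start2, x$end2)

random_loops <- function(n, genome, len_range = c(1e5, 2e6),
                         anchor = 2.5e4) {
  chrom <- sample(genome$chrom, n, replace = TRUE)
  len <- stats::runif(n, len_range[1], len_range[2])
  start1 <- floor(stats::runif(n) *
                    (genome_size(genome, chrom) - len - 2 * anchor))
  loop_tbl(chrom, start1, start1 + anchor, start1 + len,
           start1 + len + anchor, genome = genome)
}

# constant-value signal track
const_track <- function(genome, bin_size, value = 1) {
  tr <- chromshift:::empty_track(genome, bin_size)
  tr$value <- value
  tr
}
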