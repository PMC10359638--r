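#' RPGC (1x genome coverage) scale factor
#'
#' `genome_size / total_coverage_bp`: multiplying a coverage track by this
#' factor sets its genome-wide mean per-bp coverage to 1.
#'
#' @param total_coverage_bp Total coverage mass in bp (sum of per-bp
#'   coverage; > 0).
#' @param genome_size Effective genome size in bp (> 0).
#' @return The scale factor (a single number).
#' @export
rpgc_scale <- function(total_coverage_bp, genome_size) {
  if (total_coverage_bp <= 0) stop("zero coverage", call. = FALSE)
  if (genome_size <= 0) stop("genome size must be positive", call. = FALSE)
  genome_size / total_coverage_bp
}

#' Spike-in scale factor
#'
#' Scales a sample's track by `reference_spike_reads / spike_reads` so that
#' exogenous spike-in material reads equally across samples, making
#' occupancy levels comparable between conditions.
#'
#' @param spike_reads Spike-in genome reads in this sample (> 0).
#' @param reference_spike_reads Spike-in reads in the reference sample.
#' @return The scale factor.
#' @export
spike_in_scale <- function(spike_reads, reference_spike_reads) {
  if (spike_reads <= 0) stop("zero spike-in reads", call. = FALSE)
  reference_spike_reads / spike_reads
}

#' Apply a scale factor to a track
#' @param track A `signal_track`.
#' @param factor Multiplicative factor.
#' @param normalization New normalization label.
#' @return The scaled track.
#' @export
scale_track <- function(track, factor, normalization = "scaled") {
  track$value <- track$value * factor
  attr(track, "normalization") <- normalization
  track
}

# mean track value over arbitrary bp intervals (length-weighted over the
# track's bins, clipped to the chromosome)
signal_at_intervals <- function(track, intervals) {
  bs <- track_bin_size(track)
  out <- rep(NA_real_, nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    sel <- track$chrom == ch
    if (!any(sel)) next
    v <- track$value[sel][order(track$bin[sel])]
    n <- length(v)
    ii <- which(intervals$chrom == ch)
    for (i in ii) {
      b0 <- max(0, floor(intervals$start[i] / bs))
      b1 <- min(n - 1, floor((intervals$end[i] - 1) / bs))
      if (b1 < b0) next
      bins <- b0:b1
      lo <- pmax(intervals$start[i], bins * bs)
      hi <- pmin(intervals$end[i], (bins + 1) * bs)
      w <- hi - lo
      out[i] <- sum(v[bins + 1] * w) / sum(w)
    }
  }
  out
}

#' Signal matrix around features
#'
#' One row per feature, one column per position bin, each cell the mean
#' track value over that bp window. For genes, rows are oriented 5'→3' (a
#' `-` strand gene's columns are flipped). `mode = "scale_region"`
#' rescales each feature body to `body_bins` columns between the flanks.
#'
#' @param track A `signal_track`.
#' @param features Interval tibble (`chrom`, `start`, `end`), or a gene
#'   tibble (`chrom`, `strand`, `tss`, `tes`) for `mode = "tss"` /
#'   `"scale_region"`.
#' @param flank Flank in bp on each side (multiple of `bin`).
#' @param bin Column width in bp.
#' @param mode `"center"` (feature midpoint), `"tss"`, or
#'   `"scale_region"`.
#' @param body_bins Number of body columns for `"scale_region"`
#'   (default 50).
#' @return A list: `matrix` (rows = features, `NA` where off-chromosome),
#'   `positions` (column centers in bp relative to the reference point),
#'   `profile` (column means ignoring `NA`), `row_key`.
#' @export
feature_matrix <- function(track, features, flank, bin,
                           mode = c("center", "tss", "scale_region"),
                           body_bins = 50) {
  mode <- match.arg(mode)
  if (flank %% bin != 0) stop("`flank` must be a multiple of `bin`",
                              call. = FALSE)
  nf <- as.integer(flank / bin)
  n <- nrow(features)
  strand <- if ("strand" %in% names(features)) features$strand else
    rep("+", n)
  if (mode == "center") {
    ref <- interval_mid(features$start, features$end)
  } else {
    ref <- features$tss
  }
  if (mode %in% c("center", "tss")) {
    ncol_ <- 2L * nf
    pos <- (seq_len(ncol_) - 1) * bin - flank + bin / 2
    M <- matrix(NA_real_, n, ncol_)
    for (i in seq_len(n)) {
      starts <- ref[i] - flank + (seq_len(ncol_) - 1) * bin
      iv <- tibble::tibble(chrom = features$chrom[i], start = starts,
                           end = starts + bin)
      ok <- iv$start >= 0
      vals <- rep(NA_real_, ncol_)
      if (any(ok)) vals[ok] <- signal_at_intervals(track, iv[ok, ])
      if (strand[i] == "-") vals <- rev(vals)
      M[i, ] <- vals
    }
  } else {
    ncol_ <- 2L * nf + as.integer(body_bins)
    pos <- seq_len(ncol_)
    M <- matrix(NA_real_, n, ncol_)
    for (i in seq_len(n)) {
      lo <- min(features$tss[i], features$tes[i])
      hi <- max(features$tss[i], features$tes[i])
      edges_body <- seq(lo, hi, length.out = body_bins + 1)
      up <- (ref[i] <= hi)  # tss side
      left <- tibble::tibble(
        chrom = features$chrom[i],
        start = lo - flank + (seq_len(nf) - 1) * bin)
      left$end <- left$start + bin
      right <- tibble::tibble(
        chrom = features$chrom[i],
        start = hi + (seq_len(nf) - 1) * bin)
      right$end <- right$start + bin
      body <- tibble::tibble(chrom = features$chrom[i],
                             start = edges_body[-length(edges_body)],
                             end = edges_body[-1])
      iv <- dplyr::bind_rows(left, body, right)
      ok <- iv$start >= 0 & iv$end > iv$start
      vals <- rep(NA_real_, ncol_)
      if (any(ok)) vals[ok] <- signal_at_intervals(track, iv[ok, ])
      if (strand[i] == "-") vals <- rev(vals)
      M[i, ] <- vals
    }
  }
  rk <- if ("id" %in% names(features)) features$id else
    paste0(features$chrom, ":", features$start %||% features$tss)
  list(matrix = M, positions = pos,
       profile = colMeans(M, na.rm = TRUE), row_key = rk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the prioritized cis-regulatory element sets
#'
#' Promoters are TSS +/- 1 kb; enhancers are active-chromatin peaks that do
#' not overlap promoters; CTCF sites are CTCF peaks that overlap neither
#' promoters nor enhancers; gene bodies span TSS to TES.
#'
#' @param genes Gene tibble.
#' @param active_peaks Active-chromatin (e.g. H3K27ac) peaks.
#' @param ctcf_peaks CTCF peaks.
#' @param promoter_flank Promoter half-width in bp (default 1000).
#' @return A named list of interval tibbles: `promoters`, `enhancers`,
#'   `ctcf_sites`, `gene_bodies`.
#' @export
build_elements <- function(genes, active_peaks, ctcf_peaks,
                           promoter_flank = 1000) {
  promoters <- tibble::tibble(
    chrom = genes$chrom,
    start = pmax(0, genes$tss - promoter_flank),
    end = genes$tss + promoter_flank)
  promoters <- promoters[order(promoters$chrom, promoters$start), ]
  enhancers <- active_peaks[!overlaps_any(active_peaks, promoters), ]
  ctcf_sites <- ctcf_peaks[!overlaps_any(ctcf_peaks, promoters) &
                             !overlaps_any(ctcf_peaks, enhancers), ]
  gene_bodies <- tibble::tibble(
    chrom = genes$chrom,
    start = pmin(genes$tss, genes$tes),
    end = pmax(genes$tss, genes$tes))
  gene_bodies <- gene_bodies[order(gene_bodies$chrom, gene_bodies$start), ]
  list(promoters = promoters, enhancers = enhancers,
       ctcf_sites = ctcf_sites, gene_bodies = gene_bodies)
}

#' Annotate peaks by element priority
#'
#' Each peak gets the first category it overlaps in the fixed priority
#' order promoter > enhancer > CTCF site > gene body > other; categories
#' are therefore mutually exclusive and exhaustive.
#'
#' @param peaks Peak tibble.
#' @param elements Named list from [build_elements()].
#' @return A list: `peaks` (with a `category` column) and `proportions`
#'   (tibble of category proportions; they sum to 1).
#' @export
annotate_peaks <- function(peaks, elements) {
  order_ <- c("promoter", "enhancer", "ctcf_site", "gene_body")
  sets <- list(elements$promoters, elements$enhancers, elements$ctcf_sites,
               elements$gene_bodies)
  cat_ <- rep("other", nrow(peaks))
  unassigned <- rep(TRUE, nrow(peaks))
  for (k in seq_along(order_)) {
    if (is.null(sets[[k]]) || nrow(sets[[k]]) == 0) next
    hit <- overlaps_any(peaks, sets[[k]])
    take <- unassigned & hit
    cat_[take] <- order_[k]
    unassigned[take] <- FALSE
  }
  peaks$category <- factor(cat_, levels = c(order_, "other"))
  prop <- as.data.frame(prop.table(table(peaks$category)))
  names(prop) <- c("category", "proportion")
  list(peaks = peaks, proportions = tibble::as_tibble(prop))
}

#' Define bound and unbound genes from promoter TF signal
#'
#' Bound genes are, among genes with at least one TF peak in their
#' promoter (TSS +/- 1 kb), the `top_n` by mean promoter signal; unbound
#' genes are, among genes with no promoter peak, the `top_n` with the
#' lowest promoter signal. Ties break by gene id.
#'
#' @param genes Gene tibble.
#' @param tf_peaks TF peaks.
#' @param tf_track TF `signal_track`.
#' @param top_n Class size (default 1000); a short class is returned whole
#'   with a warning.
#' @param promoter_flank Promoter half-width (default 1000).
#' @return A list: `bound` and `unbound` gene tibbles, each with
#'   `promoter_signal` and `has_peak` columns.
#' @export
bound_unbound_genes <- function(genes, tf_peaks, tf_track, top_n = 1000,
                                promoter_flank = 1000) {
  prom <- tibble::tibble(chrom = genes$chrom,
                         start = pmax(0, genes$tss - promoter_flank),
                         end = genes$tss + promoter_flank)
  genes$has_peak <- overlaps_any(prom, tf_peaks)
  genes$promoter_signal <- signal_at_intervals(tf_track, prom)
  with_ <- genes[genes$has_peak, ]
  without <- genes[!genes$has_peak, ]
  bound <- with_[order(-with_$promoter_signal, with_$id), ]
  unbound <- without[order(without$promoter_signal, without$id), ]
  if (nrow(bound) < top_n || nrow(unbound) < top_n) {
    warning("fewer than top_n genes in a class (bound: ", nrow(bound),
            ", unbound: ", nrow(unbound), ")", call. = FALSE)
  }
  list(bound = utils::head(bound, top_n),
       unbound = utils::head(unbound, top_n))
}

#' Row-wise z-scores
#'
#' `(x - mean) / SD` per row, with the sample SD (n-1). Constant rows are
#' returned as all-zero and flagged.
#'
#' @param m A numeric matrix (features x samples/timepoints).
#' @return The z-scored matrix with a logical attribute `flagged_rows`
#'   marking constant rows.
#' @export
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd_ <- apply(m, 1, stats::sd)
  flagged <- sd_ == 0 | !is.finite(sd_)
  z <- (m - mu) / ifelse(flagged, 1, sd_)
  z[flagged, ] <- 0
  attr(z, "flagged_rows") <- flagged
  z
}

#' Cluster differential-signal rows with an elbow-selected k
#'
#' Agglomerative hierarchical clustering (Ward's method on Euclidean
#' distance, via [stats::hclust()]) of z-scored rows; the tree is cut at
#' each candidate `k` and the elbow — the `k` maximizing the second
#' difference of the within-cluster dispersion curve — is selected.
#'
#' @param z A z-scored matrix (rows are peaks/features).
#' @param k_range Candidate cluster numbers (default `2:6`).
#' @return A list: `k` (chosen), `labels` (cluster id per row at the
#'   chosen k), `dispersion` (tibble `k`, `wss`), `degenerate` flag
#'   (all-identical rows), and the `hclust` tree.
#' @export
cluster_diff_signal <- function(z, k_range = 2:6) {
  n <- nrow(z)
  if (n < 3) stop("need at least 3 rows to cluster", call. = FALSE)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("`k_range` out of bounds", call. = FALSE)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  wss_at <- function(k) {
    lab <- stats::cutree(hc, k)
    sum(vapply(split(seq_len(n), lab), function(ix) {
      if (length(ix) < 2) return(0)
      sub <- z[ix, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }
  # extend one k on each side so second differences exist at the ends
  ks <- sort(unique(c(max(1, min(k_range) - 1), k_range,
                      min(n, max(k_range) + 1))))
  wss <- vapply(ks, wss_at, numeric(1))
  degenerate <- all(wss < 1e-12)
  if (degenerate) {
    k_sel <- min(k_range)
  } else {
    inner <- which(ks %in% k_range & ks > min(ks) & ks < max(ks))
    if (!length(inner)) inner <- which(ks %in% k_range)
    d2 <- vapply(inner, function(i) {
      if (i == 1 || i == length(ks)) return(-Inf)
      wss[i - 1] - 2 * wss[i] + wss[i + 1]
    }, numeric(1))
    k_sel <- ks[inner][which.max(d2)]
  }
  list(k = k_sel, labels = stats::cutree(hc, k_sel),
       dispersion = tibble::tibble(k = ks, wss = wss),
       degenerate = degenerate, tree = hc)
}

#' Co-occupancy categories across factors
#'
#' All peaks from the named sets are flattened into maximal merged
#' regions; each region is labeled by how many distinct factors have at
#' least one overlapping peak: `"1"`, `"2"`, `"3"`, `"4"` or `"4+"`
#' (more than four).
#'
#' @param peak_sets A named list of sorted peak tibbles, one per factor.
#' @return A tibble `chrom`, `start`, `end`, `n_factors`, `label`.
#' @export
cooccupancy_categories <- function(peak_sets) {
  all <- dplyr::bind_rows(peak_sets, .id = "factor")
  if (nrow(all) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_factors = integer(),
                          label = character()))
  }
  out <- list()
  for (ch in unique(all$chrom)) {
    sub <- all[all$chrom == ch, ]
    merged <- IRanges::reduce(IRanges::IRanges(sub$start + 1, sub$end))
    reg <- tibble::tibble(chrom = ch,
                          start = IRanges::start(merged) - 1,
                          end = IRanges::end(merged))
    nfac <- integer(nrow(reg))
    for (f in unique(sub$factor)) {
      hit <- overlaps_any(reg, sub[sub$factor == f, ])
      nfac <- nfac + as.integer(hit)
    }
    reg$n_factors <- nfac
    out[[ch]] <- reg
  }
  res <- dplyr::bind_rows(out)
  res$label <- ifelse(res$n_factors > 4, "4+", as.character(res$n_factors))
  res
}

#' ChIP-qPCR percent input
#'
#' `%Input = 100 * input_fraction * 2^(Ct_input - Ct_sample)`: with the
#' conventional 5% input aliquot, equal cycle thresholds read 5%.
#'
#' @param ct_input Ct of the input aliquot.
#' @param ct_sample Ct of the immunoprecipitated sample.
#' @param input_fraction Fraction of chromatin saved as input
#'   (default 0.05).
#' @return Percent input (vectorized).
#' @export
percent_input <- function(ct_input, ct_sample, input_fraction = 0.05) {
  stopifnot(all(is.finite(ct_input)), all(is.finite(ct_sample)))
  100 * input_fraction * 2^(ct_input - ct_sample)
}

#' Tissue-expression breadth and essentiality annotations
#'
#' The expression percentage is the share of tissues whose average TPM is
#' strictly greater than 10; a gene is essential iff its CRISPR score is
#' below 0 with p below 0.05.
#'
#' @param tpm A gene x tissue matrix of tissue-averaged TPM values (row
#'   names are gene ids).
#' @param crispr A tibble `gene`, `score`, `p`.
#' @return A tibble `gene`, `pct_tissues_expressed`, `essential` (genes
#'   missing from a table carry `NA` in that column).
#' @export
resource_annotations <- function(tpm, crispr) {
  genes <- union(rownames(tpm), crispr$gene)
  pct <- rep(NA_real_, length(genes))
  ix <- match(rownames(tpm), genes)
  pct[ix] <- 100 * rowMeans(tpm > 10)
  ess <- rep(NA, length(genes))
  jx <- match(crispr$gene, genes)
  ess[jx] <- crispr$score < 0 & crispr$p < 0.05
  tibble::tibble(gene = genes, pct_tissues_expressed = pct,
                 essential = ess)
}
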