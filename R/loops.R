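#' Merge loop calls from multiple resolutions
#'
#' Every anchor is extended to the enclosing bin at the coarsest
#' resolution (`base_resolution`, default 25 kb) and loops whose two
#' extended anchors coincide are collapsed to one record, keeping the
#' finest source resolution as provenance. Merging the merged set is the
#' identity.
#'
#' @param loop_sets A list of loop tibbles (e.g. 5/10/25 kb calls), each
#'   carrying its `resolution` column.
#' @param base_resolution Coarsest resolution in bp (default 25000).
#' @return A loop tibble on the base-resolution grid with columns
#'   `chrom`, `start1`, `end1`, `start2`, `end2`, `resolution`
#'   (= `base_resolution`), `source_resolution` (finest contributing call)
#'   and `length`.
#' @export
merge_multires_loops <- function(loop_sets, base_resolution = 25000) {
  if (is.data.frame(loop_sets)) loop_sets <- list(loop_sets)
  all <- dplyr::bind_rows(loop_sets)
  if (nrow(all) == 0) {
    return(tibble::tibble(chrom = character(), start1 = numeric(),
                          end1 = numeric(), start2 = numeric(),
                          end2 = numeric(), resolution = numeric(),
                          source_resolution = numeric(), length = numeric()))
  }
  b1 <- floor(interval_mid(all$start1, all$end1) / base_resolution)
  b2 <- floor(interval_mid(all$start2, all$end2) / base_resolution)
  lo <- pmin(b1, b2)
  hi <- pmax(b1, b2)
  src <- if ("resolution" %in% names(all)) all$resolution else
    rep(base_resolution, nrow(all))
  src[is.na(src)] <- base_resolution
  key <- paste(all$chrom, lo, hi)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(chrom = all$chrom, lo = lo, hi = hi,
                                   src = src, key = key), .data$key),
    chrom = dplyr::first(.data$chrom), lo = dplyr::first(.data$lo),
    hi = dplyr::first(.data$hi),
    source_resolution = min(.data$src), .groups = "drop")
  out <- tibble::tibble(
    chrom = agg$chrom,
    start1 = agg$lo * base_resolution,
    end1 = (agg$lo + 1) * base_resolution,
    start2 = agg$hi * base_resolution,
    end2 = (agg$hi + 1) * base_resolution,
    resolution = base_resolution,
    source_resolution = agg$source_resolution)
  out$length <- interval_mid(out$start2, out$end2) -
    interval_mid(out$start1, out$end1)
  out[order(out$chrom, out$start1, out$start2), ]
}

#' Strength of a single loop
#'
#' Mean O/E over the `center_bins x center_bins` block centered on the loop
#' pixel — the single-loop analogue of the APA central score. The log2
#' fold change of a loop between conditions is
#' `log2(strength_after / strength_before)`.
#'
#' @param mats `oe` contact matrices (named list or single).
#' @param loops A loop tibble; strengths are computed per row.
#' @param center_bins Side of the central block (default 3).
#' @return The loop tibble with a `strength` column (`NA` where the window
#'   falls off-chromosome or is fully masked).
#' @export
loop_strength <- function(mats, loops, center_bins = 3) {
  if (inherits(mats, "contact_matrix")) {
    mats <- stats::setNames(list(mats), mats$chrom)
  }
  h <- (as.integer(center_bins) - 1L) %/% 2L
  dense <- list()
  strength <- rep(NA_real_, nrow(loops))
  for (i in seq_len(nrow(loops))) {
    m <- mats[[loops$chrom[i]]]
    if (is.null(m)) next
    b1 <- floor(interval_mid(loops$start1[i], loops$end1[i]) / m$bin_size)
    b2 <- floor(interval_mid(loops$start2[i], loops$end2[i]) / m$bin_size)
    if (b1 - h < 0 || b2 - h < 0 || b1 + h >= m$n_bins || b2 + h >= m$n_bins)
      next
    if (is.null(dense[[m$chrom]])) dense[[m$chrom]] <- dense_oe(m)
    W <- dense[[m$chrom]][(b1 - h):(b1 + h) + 1L, (b2 - h):(b2 + h) + 1L]
    if (!all(is.na(W))) strength[i] <- mean(W, na.rm = TRUE)
  }
  loops$strength <- strength
  loops
}

# Classic (unweighted) GSEA enrichment statistic for a hit set at sorted
# ranks r (1-based, increasing) among N items: the running sum gains
# 1/nh at hits and loses 1/(N-nh) elsewhere; extrema can only occur at
# hit positions (top) or just before them (bottom), so ES is O(nh).
gsea_es <- function(r, N) {
  nh <- length(r)
  i <- seq_len(nh)
  up <- i / nh - (r - i) / (N - nh)
  dn <- (i - 1) / nh - (r - i) / (N - nh)
  hi <- max(up)
  lo <- min(c(dn, 0))
  if (hi >= -lo) hi else lo
}

#' Loop-length GSEA for a hit set
#'
#' Loops are ranked by decreasing length and a classic (unweighted)
#' running-sum enrichment statistic asks whether the hit set concentrates
#' among the longest loops. The null is built by permuting the hit labels;
#' the one-sided p-value uses the add-one correction
#' `(1 + #\{ES_null >= ES\}) / (1 + n_perm)`.
#'
#' @param loops A loop tibble with a `length` column.
#' @param hits Logical vector (one per loop) or integer indices marking the
#'   hit set; must be a non-empty proper subset.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return A `perm_test` result (observed ES, null mean/sd, p, seed) whose
#'   `running_sum` element carries the tibble `rank`, `length`, `hit`,
#'   `running_sum` for plotting.
#' @export
length_rank_gsea <- function(loops, hits, n_perm = 1000, seed = 1L) {
  N <- nrow(loops)
  if (is.logical(hits)) hits <- which(hits)
  nh <- length(hits)
  if (nh == 0 || nh >= N) {
    stop("hit set must be a non-empty proper subset of the loops",
         call. = FALSE)
  }
  ord <- order(-loops$length, seq_len(N))   # decreasing length, stable
  ishit <- logical(N)
  ishit[hits] <- TRUE
  h <- ishit[ord]
  r <- which(h)
  es <- gsea_es(r, N)
  inc <- ifelse(h, 1 / nh, -1 / (N - nh))
  running <- cumsum(inc)
  local_seed(seed)
  null <- vapply(seq_len(n_perm), function(k) {
    gsea_es(sort(sample.int(N, nh)), N)
  }, numeric(1))
  p <- (1 + sum(null >= es)) / (1 + n_perm)
  new_perm_test(
    observed = es, null = null, p_value = p, n_perm = n_perm, seed = seed,
    statistic = "gsea_es", alternative = "greater",
    extra = list(running_sum = tibble::tibble(
      rank = seq_len(N), length = loops$length[ord], hit = h,
      running_sum = running)))
}

new_perm_test <- function(observed, null, p_value, n_perm, seed, statistic,
                          alternative, extra = list()) {
  structure(
    c(list(observed = observed, null_mean = mean(null),
           null_sd = stats::sd(null), null = null, p_value = p_value,
           n_perm = n_perm, seed = seed, statistic = statistic,
           alternative = alternative), extra),
    class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$statistic, ": observed = ", signif(x$observed, 4),
      ", null ", signif(x$null_mean, 4), " +/- ", signif(x$null_sd, 4),
      ", p = ", signif(x$p_value, 4), " (", x$alternative, ", ",
      x$n_perm, " permutations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Uniform length-preserving relocation of loop spans on their own
# chromosome: returns new start1 values (anchor widths and the anchor
# separation are preserved).
relocate_loops <- function(loops, genome) {
  span <- loops$end2 - loops$start1
  size <- genome_size(genome, loops$chrom)
  room <- size - span
  ok <- room >= 0
  s <- rep(NA_real_, nrow(loops))
  s[ok] <- floor(stats::runif(sum(ok)) * (room[ok] + 1))
  s
}

#' Element enrichment at loop anchors
#'
#' Counts element peaks overlapping loop anchors and compares against a
#' null in which every loop is relocated uniformly on its own chromosome
#' (lengths and anchor widths preserved) `n_perm` times; the enrichment is
#' the observed count over the null mean, with a one-sided add-one
#' corrected p-value. Loops longer than their chromosome are skipped
#' (counted).
#'
#' @param loops A loop tibble.
#' @param elements A named list of interval tibbles (one per element
#'   class), each sorted.
#' @param genome A [genome_model()].
#' @param n_perm Permutations (default 1000).
#' @param seed Integer seed.
#' @return A tibble with one row per element class: `element`, `observed`,
#'   `null_mean`, `null_sd`, `enrichment`, `p_value`, `n_perm`, `seed`,
#'   `n_loops_skipped`. Enrichment is `NA` (flagged) when observed and
#'   null are both zero.
#' @export
anchor_element_enrichment <- function(loops, elements, genome,
                                      n_perm = 1000, seed = 1L) {
  span <- loops$end2 - loops$start1
  feasible <- span <= genome_size(genome, loops$chrom)
  skipped <- sum(!feasible)
  loops <- loops[feasible, ]
  anchors <- function(start1) {
    tibble::tibble(
      chrom = rep(loops$chrom, 2),
      start = c(start1, start1 + (loops$start2 - loops$start1)),
      end = c(start1 + (loops$end1 - loops$start1),
              start1 + (loops$end2 - loops$start1)))
  }
  count_hits <- function(el, anc) sum(overlaps_any(el, anc))
  obs <- vapply(elements, function(el) {
    count_hits(el, anchors(loops$start1))
  }, numeric(1))
  local_seed(seed)
  null <- matrix(0, n_perm, length(elements))
  for (k in seq_len(n_perm)) {
    s <- relocate_loops(loops, genome)
    anc <- anchors(s)
    null[k, ] <- vapply(elements, count_hits, numeric(1), anc = anc)
  }
  nm <- colMeans(null)
  tibble::tibble(
    element = names(elements),
    observed = obs,
    null_mean = nm,
    null_sd = apply(null, 2, stats::sd),
    enrichment = ifelse(obs == 0 & nm == 0, NA_real_, obs / nm),
    p_value = vapply(seq_along(elements), function(j) {
      (1 + sum(null[, j] >= obs[j])) / (1 + n_perm)
    }, numeric(1)),
    n_perm = n_perm, seed = seed, n_loops_skipped = skipped)
}

# peaks whose midpoint lies inside [start1, end2] of each loop; returns a
# list(count = per-loop counts, sum = per-loop sums of `value`)
midpoints_in_span <- function(loops, peaks, value = NULL) {
  cnt <- numeric(nrow(loops))
  tot <- numeric(nrow(loops))
  mid <- interval_mid(peaks$start, peaks$end)
  for (ch in unique(loops$chrom)) {
    li <- which(loops$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(li) || !length(pi)) next
    m <- sort(mid[pi])
    v <- if (is.null(value)) rep(1, length(pi)) else
      value[pi][order(mid[pi])]
    cv <- cumsum(v)
    # midpoint m inside closed [start1, end2]
    a <- findInterval(loops$start1[li] - 0.5, m)
    b <- findInterval(loops$end2[li] + 0.5 - 1e-9, m)
    cnt[li] <- b - a
    tot[li] <- ifelse(b > 0, cv[pmax(b, 1)], 0) -
      ifelse(a > 0, cv[pmax(a, 1)], 0)
    tot[li][b <= a] <- 0
  }
  list(count = cnt, sum = tot)
}

#' Classify depletion-responsive loops
#'
#' Long loops (`length > min_length`) are scored by the sum, over the ATAC
#' peaks inside each loop span, of the transcription-factor ChIP signal at
#' the peak plus the absolute cohesin log2 fold change at the peak.
#' Responsive loops are the `top_n` highest-scoring candidates that contain
#' at least one TF peak and at least one down-regulated cohesin peak;
#' less-responsive loops are the `top_n` lowest-scoring candidates that
#' contain neither. "Contains" means the peak midpoint lies within the
#' loop span `[start1, end2]`. Ties break deterministically by (score,
#' genome chromosome order, start).
#'
#' @param loops A loop tibble.
#' @param tf_peaks TF ChIP peaks (interval tibble).
#' @param down_cohesin_peaks Down-regulated cohesin peaks (interval
#'   tibble; a labeled differential-binding output, not computed here).
#' @param atac_peaks ATAC peaks with per-peak `tf_signal` (mean TF track
#'   value over the peak; computed when a `tf_track` is given) and `lfc`
#'   (cohesin log2FC) columns.
#' @param tf_track Optional `signal_track` used to fill `atac_peaks$tf_signal`.
#' @param genome A [genome_model()] (for deterministic ordering).
#' @param min_length Candidate threshold in bp (default 5e5; strictly
#'   greater).
#' @param top_n Class size (default 500); if fewer loops are eligible all
#'   are returned with a warning.
#' @return A list: `responsive` and `less_responsive` loop tibbles, and
#'   `scores` — all candidate loops with `score`, `has_tf`, `has_down`.
#' @export
classify_responsive_loops <- function(loops, tf_peaks, down_cohesin_peaks,
                                      atac_peaks, tf_track = NULL,
                                      genome = NULL, min_length = 5e5,
                                      top_n = 500) {
  cand <- loops[loops$length > min_length, ]
  if (nrow(cand) == 0) stop("no candidate loops above `min_length`",
                            call. = FALSE)
  if (!is.null(tf_track)) {
    atac_peaks$tf_signal <- signal_at_intervals(tf_track, atac_peaks)
  }
  if (!all(c("tf_signal", "lfc") %in% names(atac_peaks))) {
    stop("`atac_peaks` needs `tf_signal` and `lfc` columns (or pass ",
         "`tf_track`)", call. = FALSE)
  }
  per_atac <- atac_peaks$tf_signal + abs(atac_peaks$lfc)
  sc <- midpoints_in_span(cand, atac_peaks, value = per_atac)
  cand$score <- sc$sum
  cand$has_tf <- midpoints_in_span(cand, tf_peaks)$count >= 1
  cand$has_down <- midpoints_in_span(cand, down_cohesin_peaks)$count >= 1
  chrom_key <- if (is.null(genome)) {
    match(cand$chrom, unique(cand$chrom))
  } else {
    match(cand$chrom, genome$chrom)
  }
  resp_pool <- which(cand$has_tf & cand$has_down)
  less_pool <- which(!cand$has_tf & !cand$has_down)
  ord_resp <- resp_pool[order(-cand$score[resp_pool], chrom_key[resp_pool],
                              cand$start1[resp_pool])]
  ord_less <- less_pool[order(cand$score[less_pool], chrom_key[less_pool],
                              cand$start1[less_pool])]
  if (length(ord_resp) < top_n || length(ord_less) < top_n) {
    warning("fewer than top_n eligible loops (responsive: ",
            length(ord_resp), ", less-responsive: ", length(ord_less),
            "); returning all eligible", call. = FALSE)
  }
  list(
    responsive = cand[utils::head(ord_resp, top_n), ],
    less_responsive = cand[utils::head(ord_less, top_n), ],
    scores = cand)
}

#' Gene-category enrichment inside a loop set
#'
#' The fraction of loop-contained genes (TSS within a loop span) in each
#' expression category, divided by the genome-wide fraction — an
#' observed/expected ratio per category. Significance comes from
#' relocating the loop set uniformly (length-preserving, same chromosome)
#' `n_perm` times and recomputing the ratios; the two-sided add-one
#' corrected empirical p-value is reported per category.
#'
#' @param loops A loop tibble.
#' @param genes A gene tibble with a `category` column (e.g. `"down"`,
#'   `"unchanged"`, `"up"`); every gene must be categorized.
#' @param genome A [genome_model()].
#' @param n_perm Permutations (default 10000).
#' @param seed Integer seed.
#' @return A tibble, one row per category: `category`, `observed_frac`,
#'   `expected_frac`, `ratio`, `null_mean`, `null_sd`, `p_value`,
#'   `n_genes_in_loops`, `n_perm`, `seed`. Categories absent genome-wide
#'   get `NA` ratios.
#' @export
gene_category_enrichment <- function(loops, genes, genome, n_perm = 10000,
                                     seed = 1L) {
  if (anyNA(genes$category)) stop("every gene must be categorized",
                                  call. = FALSE)
  cats <- sort(unique(as.character(genes$category)))
  expected <- vapply(cats, function(cc) mean(genes$category == cc),
                     numeric(1))
  # sorted TSS per chromosome x category for O(log n) span counting
  tss_sorted <- list()
  for (ch in unique(genes$chrom)) {
    for (cc in cats) {
      tss_sorted[[paste(ch, cc)]] <-
        sort(genes$tss[genes$chrom == ch & genes$category == cc])
    }
  }
  count_in_spans <- function(start1) {
    end2 <- start1 + (loops$end2 - loops$start1)
    out <- stats::setNames(numeric(length(cats)), cats)
    for (ch in unique(loops$chrom)) {
      li <- which(loops$chrom == ch)
      for (cc in cats) {
        m <- tss_sorted[[paste(ch, cc)]]
        if (is.null(m) || !length(m)) next
        a <- findInterval(start1[li] - 0.5, m)
        b <- findInterval(end2[li] + 0.5 - 1e-9, m)
        out[cc] <- out[cc] + sum(b - a)
      }
    }
    out
  }
  ratio_of <- function(counts) {
    tot <- sum(counts)
    if (tot == 0) return(stats::setNames(rep(NA_real_, length(cats)), cats))
    (counts / tot) / expected
  }
  obs_counts <- count_in_spans(loops$start1)
  obs_ratio <- ratio_of(obs_counts)
  span <- loops$end2 - loops$start1
  size <- genome_size(genome, loops$chrom)
  room <- pmax(size - span, 0)
  local_seed(seed)
  null <- matrix(NA_real_, n_perm, length(cats),
                 dimnames = list(NULL, cats))
  for (k in seq_len(n_perm)) {
    s <- floor(stats::runif(nrow(loops)) * (room + 1))
    null[k, ] <- ratio_of(count_in_spans(s))
  }
  p <- vapply(seq_along(cats), function(j) {
    nj <- null[, j]
    nj <- nj[!is.na(nj)]
    o <- obs_ratio[j]
    if (is.na(o) || !length(nj)) return(NA_real_)
    hi <- (1 + sum(nj >= o)) / (1 + length(nj))
    lo <- (1 + sum(nj <= o)) / (1 + length(nj))
    min(1, 2 * min(hi, lo))
  }, numeric(1))
  tibble::tibble(
    category = cats,
    observed_frac = as.numeric(obs_counts / max(sum(obs_counts), 1)),
    expected_frac = as.numeric(expected),
    ratio = as.numeric(obs_ratio),
    null_mean = colMeans(null, na.rm = TRUE),
    null_sd = apply(null, 2, stats::sd, na.rm = TRUE),
    p_value = p,
    n_genes_in_loops = sum(obs_counts),
    n_perm = n_perm, seed = seed)
}
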