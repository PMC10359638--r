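#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with the package's
#' default desk-scale study conditions: two 10 Mb chromosomes at 25 kb
#' bins (400 bins each), 2 million contact pairs, power-law distance decay
#' with lognormal bin biases, plaid compartments, tiled TADs, focal loops,
#' a factor-binding landscape with co-occupancy structure, and a paired
#' untreated/depleted design in which cohesin signal drops at bound
#' promoters and planted responsive loops gain strength.
#'
#' @param seed Master integer seed; identical seeds give identical
#'   outputs.
#' @param chrom_sizes Named vector of chromosome sizes in bp.
#' @param bin_size Contact-map bin size in bp.
#' @param decay_exponent Power-law exponent of distance decay (> 0).
#' @param depth Total contact pairs across the genome.
#' @param bias_sd Lognormal sigma of multiplicative bin biases.
#' @param compartment_amplitude Plaid strength `A >= 0` (0 = no
#'   compartments).
#' @param compartment_block Compartment block length in bp.
#' @param tad_contrast Within-TAD contact multiplier `>= 1` (1 = no TADs).
#' @param tad_length_range TAD length range in bp.
#' @param loop_strength Focal loop multiplier `>= 1` (1 = no loops).
#' @param n_loops Planted loops per chromosome.
#' @param loop_length_range Loop length range in bp (log-uniform draw).
#' @param track_bin ChIP/ATAC track bin size in bp.
#' @param n_genes Genes across the genome.
#' @param peak_width Factor peak width in bp.
#' @param factor_background_rate Probability an ordinary promoter is
#'   TF-bound.
#' @param cohesin_reduction Multiplier applied to cohesin signal at
#'   TF-bound promoters after depletion (0.5 = halved).
#' @param responsive_gain Strength multiplier gained by responsive loops
#'   after depletion.
#' @param n_responsive,n_less_responsive Planted long-loop class sizes per
#'   genome.
#' @param responsive_length_range Length range in bp of the planted long
#'   class loops (all above the 500 kb classification threshold).
#' @param category_rates Named rates (`down`, `up`) for background gene
#'   expression categories; the rest are `unchanged`.
#' @param responsive_down_rate Probability a gene inside a responsive loop
#'   is down-regulated.
#' @param psm_background,psm_enriched Protein counts for the ChIP-MS
#'   table.
#' @param psm_ratio True ChIP/input abundance ratio of enriched proteins.
#' @param fourc_fold Planted 4C interaction fold at the target region.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_sizes = c(chrS1 = 1e7, chrS2 = 1e7),
                       bin_size = 25000,
                       decay_exponent = 1.0,
                       depth = 2e6,
                       bias_sd = 0.2,
                       compartment_amplitude = 0.5,
                       compartment_block = 5e5,
                       tad_contrast = 1.5,
                       tad_length_range = c(25e4, 75e4),
                       loop_strength = 2.0,
                       n_loops = 25,
                       loop_length_range = c(25e4, 5e5),
                       responsive_length_range = c(55e4, 1e6),
                       track_bin = 200,
                       n_genes = 300,
                       peak_width = 400,
                       factor_background_rate = 0.1,
                       cohesin_reduction = 0.5,
                       responsive_gain = 1.5,
                       n_responsive = 10,
                       n_less_responsive = 10,
                       category_rates = c(down = 0.1, up = 0.1),
                       responsive_down_rate = 0.6,
                       psm_background = 300,
                       psm_enriched = 30,
                       psm_ratio = 4,
                       fourc_fold = 2) {
  stopifnot(decay_exponent > 0, depth >= 0, bias_sd >= 0,
            compartment_amplitude >= 0, tad_contrast >= 1,
            loop_strength >= 1, cohesin_reduction > 0, responsive_gain >= 1,
            psm_ratio >= 1, fourc_fold >= 1,
            sum(category_rates) <= 1, all(category_rates >= 0))
  cfg <- as.list(environment())
  cfg$genome <- genome_model(names(chrom_sizes), unname(chrom_sizes),
                             bin_size = bin_size)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic sub-seed per generator stage
stage_seed <- function(config, offset) {
  (as.integer(config$seed) * 97L + offset) %% 2000000000L
}

# planted loop table on the bin grid: one row per loop with bin anchors
plant_loops <- function(config) {
  g <- config$genome
  bs <- config$bin_size
  rows <- list()
  for (ch in g$chrom) {
    n <- genome_nbins(g, ch, bs)
    len <- exp(stats::runif(config$n_loops,
                            log(config$loop_length_range[1]),
                            log(config$loop_length_range[2])))
    dbin <- pmax(1L, as.integer(round(len / bs)))
    b1 <- vapply(dbin, function(d) {
      sample.int(max(n - d - 4L, 1L), 1) + 1L
    }, integer(1))
    rows[[ch]] <- tibble::tibble(chrom = ch, bin1 = b1, bin2 = b1 + dbin)
  }
  dplyr::bind_rows(rows)
}

# dense Poisson-intensity model for one chromosome
chrom_lambda <- function(config, ch, loops, biases, comp, tad_id) {
  n <- length(biases)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- (D + 1)^(-config$decay_exponent)
  lam <- lam * outer(biases, biases)
  if (config$compartment_amplitude > 0) {
    lam <- lam * exp(config$compartment_amplitude * outer(comp, comp))
  }
  if (config$tad_contrast > 1) {
    same <- outer(tad_id, tad_id, "==")
    lam <- lam * ifelse(same, config$tad_contrast, 1)
  }
  if (nrow(loops)) {
    # Gaussian bump of radius 1 bin, amplitude-normalized so the planted
    # mean enrichment over the central 3x3 pixel block equals `strength`
    # (the APA readout currency); k_bar is the 3x3 mean of the kernel.
    k_bar <- mean(exp(-(outer((-1:1)^2, (-1:1)^2, "+")) / 2))
    for (i in seq_len(nrow(loops))) {
      s <- loops$strength[i]
      if (s <= 1) next
      for (di in -2:2) {
        for (dj in -2:2) {
          # planted bins are 0-based; matrix is 1-based
          a <- loops$bin1[i] + di + 1L
          b <- loops$bin2[i] + dj + 1L
          if (a >= 1 && b >= 1 && a <= n && b <= n) {
            f <- 1 + (s - 1) * exp(-(di^2 + dj^2) / 2) / k_bar
            lam[a, b] <- lam[a, b] * f
            lam[b, a] <- lam[a, b]
          }
        }
      }
    }
  }
  lam
}

# fixed structural draw (biases, compartments, TADs, loop positions)
plant_structure <- function(config) {
  local_seed(stage_seed(config, 11L))
  g <- config$genome
  bs <- config$bin_size
  str <- list()
  for (ch in g$chrom) {
    n <- genome_nbins(g, ch, bs)
    biases <- exp(stats::rnorm(n, 0, config$bias_sd))
    biases <- biases / mean(biases)
    blk <- max(1L, as.integer(round(config$compartment_block / bs)))
    comp <- rep(rep(c(1, -1), length.out = ceiling(n / blk)),
                each = blk)[seq_len(n)]
    tad_id <- integer(n)
    pos <- 0L
    k <- 0L
    bounds <- integer()
    while (pos < n) {
      k <- k + 1L
      len <- as.integer(round(stats::runif(1, config$tad_length_range[1],
                                           config$tad_length_range[2]) / bs))
      len <- max(len, 3L)
      tad_id[(pos + 1):min(pos + len, n)] <- k
      pos <- pos + len
      if (pos < n) bounds <- c(bounds, pos)  # boundary between bin pos-1,pos
    }
    str[[ch]] <- list(biases = biases, comp = comp, tad_id = tad_id,
                      boundaries = bounds)
  }
  loops <- plant_loops(config)
  loops$strength <- config$loop_strength
  list(chrom = str, loops = loops)
}

#' Simulate a raw Hi-C contact map with planted truth
#'
#' Counts are Poisson around an intensity combining power-law distance
#' decay, lognormal bin biases, a plaid compartment factor
#' `exp(A * e_i * e_j)`, a within-TAD contrast `tau`, and focal Gaussian
#' bumps (radius 1 bin) of tunable strength at planted loop pixels. The
#' planted structure (compartment labels, TAD boundaries, loop list,
#' biases) is returned alongside the matrices.
#'
#' @param config A [sim_config()].
#' @param structure Optional pre-drawn structure (internal reuse across
#'   paired conditions).
#' @param loop_strengths Optional per-loop strength vector overriding the
#'   config value (used by the perturbation generator).
#' @param noise_seed_offset Integer offset decorrelating the count noise
#'   between paired draws that share a structure.
#' @return A list: `mats` — named list of raw `contact_matrix` objects —
#'   and `truth` with `compartments`, `tad_boundaries`, `tads`, `loops`
#'   (bin anchors and strengths) and `biases`.
#' @export
simulate_contact_map <- function(config, structure = NULL,
                                 loop_strengths = NULL,
                                 noise_seed_offset = 0L) {
  if (is.null(structure)) structure <- plant_structure(config)
  loops <- structure$loops
  if (!is.null(loop_strengths)) loops$strength <- loop_strengths
  g <- config$genome
  bs <- config$bin_size
  depth_per <- config$depth * g$size / sum(g$size)
  local_seed(stage_seed(config, 23L + noise_seed_offset))
  mats <- list()
  comp_rows <- list()
  tad_rows <- list()
  for (ci in seq_len(nrow(g))) {
    ch <- g$chrom[ci]
    st <- structure$chrom[[ch]]
    n <- length(st$biases)
    lam <- chrom_lambda(config, ch, loops[loops$chrom == ch, ], st$biases,
                        st$comp, st$tad_id)
    ut <- upper.tri(lam, diag = TRUE)
    lam_ut <- lam[ut]
    tot <- sum(lam_ut)
    lam_ut <- if (tot > 0) lam_ut * depth_per[ci] / tot else lam_ut
    counts <- stats::rpois(length(lam_ut), lam_ut)
    idx <- which(ut, arr.ind = TRUE)
    keep <- counts > 0
    px <- tibble::tibble(bin1 = idx[keep, 1] - 1L, bin2 = idx[keep, 2] - 1L,
                         count = as.numeric(counts[keep]))
    mats[[ch]] <- contact_matrix(ch, bs, n, px)
    comp_rows[[ch]] <- tibble::tibble(chrom = ch, bin = 0:(n - 1),
                                      label = st$comp)
    bnd <- st$boundaries
    tid <- st$tad_id
    starts <- c(0L, bnd)
    ends <- c(bnd, n)
    tad_rows[[ch]] <- tibble::tibble(chrom = ch, start = starts * bs,
                                     end = ends * bs)
  }
  truth <- list(
    compartments = dplyr::bind_rows(comp_rows),
    tad_boundaries = dplyr::bind_rows(lapply(g$chrom, function(ch) {
      tibble::tibble(chrom = ch, bin = structure$chrom[[ch]]$boundaries)
    })),
    tads = dplyr::bind_rows(tad_rows),
    loops = loops,
    biases = lapply(structure$chrom, `[[`, "biases"))
  list(mats = mats, truth = truth)
}

# convert bin-anchored planted loops to a loop tibble in bp
planted_loop_tbl <- function(loops, bin_size, extra = NULL) {
  out <- loop_tbl(loops$chrom,
                  loops$bin1 * bin_size, (loops$bin1 + 1) * bin_size,
                  loops$bin2 * bin_size, (loops$bin2 + 1) * bin_size,
                  resolution = bin_size)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out
}

#' Simulate a factor-binding landscape
#'
#' Places genes, promoters, enhancer and CTCF sites on the configured
#' genome; binds five ZBTB-family-like factors plus cohesin, CTCF and ATAC
#' accessibility to those sites according to a co-occupancy scheme; and
#' renders per-factor coverage tracks (peak signal plus Poisson
#' background). The co-occupancy truth (which factor bound which site) is
#' recorded.
#'
#' @param config A [sim_config()].
#' @param cooccupancy Optional numeric matrix (factors x site classes
#'   `promoter`, `enhancer`, `ctcf`) of binding probabilities in `[0, 1]`;
#'   defaults to an independent-binding scheme.
#' @return A list: `genes` (with `active`), `sites`, `peaks` (named list
#'   of per-factor peak tibbles), `tracks` (named list of
#'   `signal_track`s), and `truth` (per-site factor membership matrix).
#' @export
simulate_chip_landscape <- function(config, cooccupancy = NULL) {
  local_seed(stage_seed(config, 37L))
  g <- config$genome
  factors <- c("zbtb_a", "zbtb_b", "zbtb_c", "zbtb_d", "zbtb_e")
  if (is.null(cooccupancy)) {
    cooccupancy <- matrix(0.35, length(factors), 3,
                          dimnames = list(factors,
                                          c("promoter", "enhancer", "ctcf")))
  }
  if (any(cooccupancy < 0 | cooccupancy > 1)) {
    stop("co-occupancy rates must lie in [0, 1]", call. = FALSE)
  }
  # genes: uniform TSS, 2-50 kb bodies, random strand
  n_per <- round(config$n_genes * g$size / sum(g$size))
  genes <- dplyr::bind_rows(lapply(seq_len(nrow(g)), function(ci) {
    n <- n_per[ci]
    tss <- sort(round(stats::runif(n, 5e4, g$size[ci] - 6e4)))
    len <- round(stats::runif(n, 2e3, 5e4))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tibble::tibble(
      id = sprintf("gene_%s_%03d", g$chrom[ci], seq_len(n)),
      chrom = g$chrom[ci], strand = strand,
      tss = tss, tes = ifelse(strand == "+", tss + len, tss - len))
  }))
  genes$tss <- pmax(genes$tss, 1)
  genes$tes <- pmax(genes$tes, 0)
  genes$active <- stats::runif(nrow(genes)) < 0.6
  w <- config$peak_width
  site_list <- list(
    promoter = tibble::tibble(chrom = genes$chrom,
                              start = pmax(0, genes$tss - w / 2),
                              end = genes$tss + w / 2),
    enhancer = dplyr::bind_rows(lapply(seq_len(nrow(g)), function(ci) {
      n <- 60
      s <- sort(round(stats::runif(n, 1e5, g$size[ci] - 1e5)))
      tibble::tibble(chrom = g$chrom[ci], start = s, end = s + w)
    })),
    ctcf = dplyr::bind_rows(lapply(seq_len(nrow(g)), function(ci) {
      n <- 50
      s <- sort(round(stats::runif(n, 1e5, g$size[ci] - 1e5)))
      tibble::tibble(chrom = g$chrom[ci], start = s, end = s + w)
    })))
  sites <- dplyr::bind_rows(site_list, .id = "site_class")
  member <- matrix(FALSE, nrow(sites), length(factors),
                   dimnames = list(NULL, factors))
  for (f in factors) {
    p <- cooccupancy[f, sites$site_class]
    member[, f] <- stats::runif(nrow(sites)) < p
  }
  peaks <- lapply(factors, function(f) {
    pk <- sites[member[, f], c("chrom", "start", "end")]
    pk$score <- round(stats::rgamma(nrow(pk), 4, 0.5), 3)
    peak_tbl(sort_genomic(pk, g))
  })
  names(peaks) <- factors
  tracks <- lapply(factors, function(f) {
    render_track(config, peaks[[f]], heights = peaks[[f]]$score)
  })
  names(tracks) <- factors
  list(genes = genes, sites = sites, peaks = peaks, tracks = tracks,
       truth = list(membership = member))
}

# coverage-style track: per-bin Poisson around (background + peak signal)
render_track <- function(config, peaks, heights, background = 0.2,
                         noisy = TRUE) {
  g <- config$genome
  tr <- empty_track(g, config$track_bin)
  lam <- rep(background, nrow(tr))
  if (nrow(peaks)) {
    bs <- config$track_bin
    for (i in seq_len(nrow(peaks))) {
      sel <- which(tr$chrom == peaks$chrom[i] &
                     tr$start < peaks$end[i] &
                     tr$start + bs > peaks$start[i])
      lam[sel] <- lam[sel] + heights[i]
    }
  }
  tr$value <- if (noisy) stats::rpois(length(lam), lam) else lam
  attr(tr, "normalization") <- "rpgc"
  tr
}

#' Simulate a paired untreated/depleted experiment
#'
#' The full planted-truth design: a factor landscape in which a
#' transcription factor binds a subset of promoters; paired Hi-C maps
#' where planted long responsive loops gain strength after depletion;
#' paired cohesin tracks where signal at TF-bound promoters is multiplied
#' by `cohesin_reduction` after depletion (emitting down-regulated peak
#' labels exactly where the reduction was applied); ATAC peaks with a
#' measured cohesin log2FC; and gene expression categories enriched for
#' down-regulation inside responsive loops.
#'
#' @param config A [sim_config()].
#' @return A list with `before`/`after` (each: `mats`), `tf_peaks`,
#'   `tf_track`, `cohesin_before`, `cohesin_after`, `cohesin_peaks`,
#'   `down_cohesin_peaks`, `atac_peaks` (with `lfc` and `tf_signal`),
#'   `genes` (with `category`), `loops` (bp-space planted loops with
#'   `strength_before`, `strength_after`, `responsive`,
#'   `less_responsive`), and `truth`.
#' @export
simulate_perturbation_experiment <- function(config) {
  g <- config$genome
  bs <- config$bin_size
  structure <- plant_structure(config)
  loops <- structure$loops
  # promote planted loops into the three classes: responsive loops must be
  # long (> 500 kb); regenerate anchors for the class loops deterministically
  local_seed(stage_seed(config, 53L))
  n_chrom <- nrow(g)
  # class loops live in non-overlapping territories so a responsive loop's
  # TF-bound genes cannot leak into a less-responsive span
  make_class_loops <- function() {
    per_r <- diff(round(seq(0, config$n_responsive,
                            length.out = n_chrom + 1)))
    per_l <- diff(round(seq(0, config$n_less_responsive,
                            length.out = n_chrom + 1)))
    dplyr::bind_rows(lapply(seq_len(n_chrom), function(ci) {
      nb <- genome_nbins(g, g$chrom[ci], bs)
      k <- per_r[ci] + per_l[ci]
      if (k == 0) return(NULL)
      d <- as.integer(round(stats::runif(
        k, config$responsive_length_range[1],
        config$responsive_length_range[2]) / bs))
      margin <- 4L
      free <- nb - 2L * margin - sum(d + 1L)
      if (free < 0) stop("class loops do not fit on ", g$chrom[ci],
                         "; reduce their number or length", call. = FALSE)
      gaps <- diff(c(0, sort(stats::runif(k)), 1)) * free
      b1 <- margin + cumsum(gaps[seq_len(k)]) +
        c(0, cumsum(d[-k] + 1L))
      b1 <- as.integer(round(b1))
      cls <- sample(rep(c("responsive", "less_responsive"),
                        c(per_r[ci], per_l[ci])))
      tibble::tibble(chrom = g$chrom[ci], bin1 = b1, bin2 = b1 + d,
                     class = cls)
    }))
  }
  cls_loops <- make_class_loops()
  loops$class <- "background"
  all_loops <- dplyr::bind_rows(loops[c("chrom", "bin1", "bin2", "class")],
                                cls_loops)
  all_loops <- all_loops[!duplicated(all_loops[c("chrom", "bin1", "bin2")]), ]
  structure$loops <- all_loops
  s_before <- ifelse(all_loops$class == "background",
                     config$loop_strength, config$loop_strength)
  s_after <- ifelse(all_loops$class == "responsive",
                    s_before * config$responsive_gain, s_before)
  before <- simulate_contact_map(config, structure,
                                 loop_strengths = s_before,
                                 noise_seed_offset = 0L)
  after <- simulate_contact_map(config, structure,
                                loop_strengths = s_after,
                                noise_seed_offset = 100L)
  land <- simulate_chip_landscape(config)
  genes <- land$genes
  local_seed(stage_seed(config, 71L))
  # gene placement relative to planted class loops (midpoint containment)
  span_of <- function(cls) {
    sel <- all_loops$class == cls
    tibble::tibble(chrom = all_loops$chrom[sel],
                   start = all_loops$bin1[sel] * bs,
                   end = (all_loops$bin2[sel] + 1) * bs)
  }
  resp_spans <- span_of("responsive")
  less_spans <- span_of("less_responsive")
  in_span <- function(chrom, pos, spans) {
    hit <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(spans))) {
      hit <- hit | (chrom == spans$chrom[i] & pos >= spans$start[i] &
                      pos <= spans$end[i])
    }
    hit
  }
  genes$in_responsive <- in_span(genes$chrom, genes$tss, resp_spans)
  genes$in_less <- in_span(genes$chrom, genes$tss, less_spans)
  # ensure every class loop holds genes: add dedicated genes inside each
  anchor_genes <- function(spans, tag, bound) {
    if (!nrow(spans)) return(NULL)
    dplyr::bind_rows(lapply(seq_len(nrow(spans)), function(i) {
      k <- 3
      tss <- round(stats::runif(k, spans$start[i] + 5e4,
                                spans$end[i] - 5e4))
      strand <- sample(c("+", "-"), k, replace = TRUE)
      len <- round(stats::runif(k, 2e3, 2e4))
      tibble::tibble(
        id = sprintf("gene_%s_%s_%02d_%d", tag, spans$chrom[i], i,
                     seq_len(k)),
        chrom = spans$chrom[i], strand = strand, tss = tss,
        tes = ifelse(strand == "+", tss + len, tss - len),
        active = TRUE, in_responsive = tag == "resp",
        in_less = tag == "less", tf_bound = bound)
    }))
  }
  genes$tf_bound <- !genes$in_responsive & !genes$in_less &
    stats::runif(nrow(genes)) < config$factor_background_rate
  genes <- dplyr::bind_rows(
    genes,
    anchor_genes(resp_spans, "resp", bound = TRUE),
    anchor_genes(less_spans, "less", bound = FALSE))
  genes <- genes[order(match(genes$chrom, g$chrom), genes$tss), ]
  # expression categories
  r <- stats::runif(nrow(genes))
  genes$category <- ifelse(
    genes$in_responsive,
    ifelse(r < config$responsive_down_rate, "down", "unchanged"),
    ifelse(r < config$category_rates["down"], "down",
           ifelse(r < sum(config$category_rates), "up", "unchanged")))
  w <- config$peak_width
  prom <- function(sel) tibble::tibble(
    chrom = genes$chrom[sel],
    start = pmax(0, genes$tss[sel] - w / 2),
    end = genes$tss[sel] + w / 2)
  tf_peaks <- prom(genes$tf_bound)
  tf_peaks$score <- round(stats::rgamma(nrow(tf_peaks), 20, 1), 3)
  tf_peaks <- peak_tbl(sort_genomic(tf_peaks, g))
  # cohesin binds all promoters; reduction applies at TF-bound ones
  cohesin_peaks <- prom(rep(TRUE, nrow(genes)))
  cohesin_peaks$score <- round(stats::rgamma(nrow(cohesin_peaks), 10, 1), 3)
  cohesin_peaks$tf_bound <- genes$tf_bound
  ord <- order(match(cohesin_peaks$chrom, g$chrom), cohesin_peaks$start)
  cohesin_peaks <- cohesin_peaks[ord, ]
  tf_track <- render_track(config, tf_peaks, heights = tf_peaks$score)
  h_before <- cohesin_peaks$score
  h_after <- ifelse(cohesin_peaks$tf_bound,
                    cohesin_peaks$score * config$cohesin_reduction,
                    cohesin_peaks$score)
  cohesin_before <- render_track(config, cohesin_peaks, heights = h_before)
  cohesin_after <- render_track(config, cohesin_peaks, heights = h_after)
  # down-regulated labels exist only where a reduction was actually applied
  down_cohesin_peaks <- peak_tbl(
    cohesin_peaks[cohesin_peaks$tf_bound & config$cohesin_reduction < 1,
                  c("chrom", "start", "end", "score")])
  # ATAC peaks at every promoter; measured cohesin log2FC at each
  atac_peaks <- cohesin_peaks[c("chrom", "start", "end")]
  atac_peaks$score <- 1
  pc <- 0.5
  b <- signal_at_intervals(cohesin_before, atac_peaks)
  a <- signal_at_intervals(cohesin_after, atac_peaks)
  atac_peaks$lfc <- log2((a + pc) / (b + pc))
  atac_peaks$tf_signal <- signal_at_intervals(tf_track, atac_peaks)
  atac_peaks <- peak_tbl(atac_peaks)
  loops_bp <- planted_loop_tbl(all_loops, bs)
  # planted_loop_tbl sorts; recover classes by anchor key
  key <- paste(all_loops$chrom, all_loops$bin1 * bs)
  kout <- paste(loops_bp$chrom, loops_bp$start1)
  loops_bp$class <- all_loops$class[match(kout, key)]
  loops_bp$strength_before <- s_before[match(kout, key)]
  loops_bp$strength_after <- s_after[match(kout, key)]
  list(
    before = before, after = after,
    tf_peaks = tf_peaks, tf_track = tf_track,
    cohesin_before = cohesin_before, cohesin_after = cohesin_after,
    cohesin_peaks = peak_tbl(cohesin_peaks),
    down_cohesin_peaks = down_cohesin_peaks,
    atac_peaks = atac_peaks,
    genes = genes,
    loops = loops_bp,
    truth = list(structure = before$truth,
                 responsive = loops_bp[loops_bp$class == "responsive", ],
                 less_responsive = loops_bp[loops_bp$class ==
                                              "less_responsive", ]))
}

#' Simulate a ChIP-MS PSM table
#'
#' Background proteins have matched Poisson PSM counts in ChIP and input
#' samples; enriched proteins have ChIP counts at `psm_ratio` times the
#' input intensity. Some proteins are split over two isoforms to exercise
#' aggregation. Sample roles: two ChIP, two input.
#'
#' @param config A [sim_config()].
#' @return A list: `psm` (isoform-level tibble), `isoform_map`,
#'   `chip_samples`, `input_samples`, `truth` (enriched protein ids).
#' @export
simulate_psm_table <- function(config) {
  local_seed(stage_seed(config, 83L))
  n_bg <- config$psm_background
  n_en <- config$psm_enriched
  prot <- sprintf("prot_%04d", seq_len(n_bg + n_en))
  enriched <- prot[seq_len(n_en)]
  mu <- stats::rgamma(n_bg + n_en, 2, 0.2) + 2
  ratio <- ifelse(prot %in% enriched, config$psm_ratio, 1)
  counts <- tibble::tibble(
    protein = prot,
    chip_1 = stats::rpois(length(mu), mu * ratio / 2),
    chip_2 = stats::rpois(length(mu), mu * ratio / 2),
    input_1 = stats::rpois(length(mu), mu / 2),
    input_2 = stats::rpois(length(mu), mu / 2))
  # split a third of proteins into two isoforms
  two <- stats::runif(length(prot)) < 1 / 3
  rows <- list()
  map <- list()
  for (i in seq_along(prot)) {
    if (two[i]) {
      f <- stats::runif(1, 0.2, 0.8)
      sp <- function(x) {
        a <- round(x * f)
        c(a, x - a)
      }
      rows[[i]] <- tibble::tibble(
        isoform = paste0(prot[i], c("-1", "-2")),
        chip_1 = sp(counts$chip_1[i]), chip_2 = sp(counts$chip_2[i]),
        input_1 = sp(counts$input_1[i]), input_2 = sp(counts$input_2[i]))
      map[[i]] <- tibble::tibble(isoform = paste0(prot[i], c("-1", "-2")),
                                 protein = prot[i])
    } else {
      rows[[i]] <- tibble::tibble(
        isoform = paste0(prot[i], "-1"),
        chip_1 = counts$chip_1[i], chip_2 = counts$chip_2[i],
        input_1 = counts$input_1[i], input_2 = counts$input_2[i])
      map[[i]] <- tibble::tibble(isoform = paste0(prot[i], "-1"),
                                 protein = prot[i])
    }
  }
  list(psm = dplyr::bind_rows(rows), isoform_map = dplyr::bind_rows(map),
       chip_samples = c("chip_1", "chip_2"),
       input_samples = c("input_1", "input_2"),
       truth = list(enriched = enriched))
}

#' Simulate a 4C near-cis profile
#'
#' A bait-anchored distance-decaying Poisson signal on 50 bp bins, with a
#' planted interacting region at fold `fourc_fold` and a decay-matched
#' background region placed symmetrically on the other side of the bait,
#' so the region/background quantification reads the planted fold.
#'
#' @param config A [sim_config()].
#' @param bait_pos Bait position in bp on the first chromosome.
#' @return A list: `track` (50 bp `signal_track` on the bait chromosome),
#'   `region`, `background` (interval tibbles), `truth` (planted fold).
#' @export
simulate_4c <- function(config, bait_pos = 6e6) {
  local_seed(stage_seed(config, 91L))
  g1 <- genome_model(config$genome$chrom[1], config$genome$size[1])
  bs <- 50
  tr <- empty_track(g1, bs)
  d <- abs(tr$start + bs / 2 - bait_pos)
  lam <- 3e5 * (d + 5e3)^(-0.9)
  off <- 15e5
  width <- 12e4
  region <- tibble::tibble(chrom = g1$chrom[1], start = bait_pos + off,
                           end = bait_pos + off + width)
  background <- tibble::tibble(chrom = g1$chrom[1],
                               start = bait_pos - off - width,
                               end = bait_pos - off)
  in_region <- tr$start >= region$start & tr$start < region$end
  lam[in_region] <- lam[in_region] * config$fourc_fold
  tr$value <- stats::rpois(length(lam), lam)
  attr(tr, "normalization") <- "rpgc"
  list(track = tr, region = region, background = background,
       truth = list(fold = config$fourc_fold))
}
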