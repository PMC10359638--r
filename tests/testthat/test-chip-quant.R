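test_that("RPGC scaling sets genome-wide mean coverage to 1", {
  expect_equal(rpgc_scale(5e6, 5e6), 1)
  expect_equal(rpgc_scale(1e7, 5e6), 0.5)
  expect_error(rpgc_scale(0, 5e6), "coverage")
  g <- tiny_genome(c(chrA = 1e5))
  set.seed(109)
  tr <- const_track(g, 100)
  tr$value <- stats::rgamma(nrow(tr), 2, 1)
  total_bp <- sum(tr$value) * 100
  sc <- scale_track(tr, rpgc_scale(total_bp, 1e5), "rpgc")
  expect_equal(mean(sc$value), 1, tolerance = 1e-12)
})

test_that("spike-in scaling removes planted depth differences", {
  expect_equal(spike_in_scale(1000, 1000), 1)
  expect_equal(spike_in_scale(2000, 1000), 0.5)
  expect_error(spike_in_scale(0, 1000), "spike")
  # two samples with the same truth at 2x depth difference agree after
  # scaling by their spike-in reads
  g <- tiny_genome(c(chrA = 2e5))
  set.seed(113)
  truth <- stats::rgamma(200, 3, 1) * 5
  t1 <- const_track(g, 1000)
  t2 <- const_track(g, 1000)
  t1$value <- stats::rpois(200, truth * 40)
  t2$value <- stats::rpois(200, truth * 80)   # double depth
  spike1 <- 1e4
  spike2 <- 2e4
  s1 <- scale_track(t1, spike_in_scale(spike1, spike1))
  s2 <- scale_track(t2, spike_in_scale(spike2, spike1))
  expect_equal(mean(s2$value) / mean(s1$value), 1, tolerance = 0.05)
})

test_that("feature matrices are strand-aware and match a naive gather", {
  g <- tiny_genome(c(chrA = 1e5))
  tr <- const_track(g, 100, value = 2.5)
  feats <- tibble::tibble(chrom = "chrA", start = c(1e4, 5e4),
                          end = c(1e4, 5e4) + 200)
  fm <- feature_matrix(tr, feats, flank = 2000, bin = 100)
  expect_true(all(fm$matrix == 2.5))
  expect_equal(dim(fm$matrix), c(2, 40))

  set.seed(127)
  tr$value <- stats::rnorm(nrow(tr))
  # minus-strand gene equals the column-reversed plus-strand construction
  gp <- tibble::tibble(id = "g+", chrom = "chrA", strand = "+",
                       tss = 5e4, tes = 6e4)
  gm <- dplyr::mutate(gp, id = "g-", strand = "-", tes = 4e4)
  mp <- feature_matrix(tr, gp, flank = 1000, bin = 100, mode = "tss")
  mm <- feature_matrix(tr, gm, flank = 1000, bin = 100, mode = "tss")
  expect_equal(mm$matrix[1, ], rev(mp$matrix[1, ]))
  # naive gather oracle at one feature
  want <- vapply(seq_len(20), function(k) {
    s <- 5e4 - 1000 + (k - 1) * 100
    mean(tr$value[tr$start >= s & tr$start < s + 100])
  }, numeric(1))
  expect_equal(mp$matrix[1, ], want)
  # scale-region mode rescales bodies of unequal length to equal columns
  sm <- feature_matrix(tr, dplyr::bind_rows(gp, gm), flank = 1000,
                       bin = 100, mode = "scale_region", body_bins = 20)
  expect_equal(dim(sm$matrix), c(2, 40))
  expect_false(anyNA(sm$matrix))
})

test_that("peak annotation follows the fixed priority order", {
  g <- tiny_genome(c(chrA = 1e6))
  genes <- tibble::tibble(id = "g1", chrom = "chrA", strand = "+",
                          tss = 1e5, tes = 2e5)
  active <- tibble::tibble(chrom = "chrA",
                           start = c(1e5 - 500, 5e5),
                           end = c(1e5 + 500, 5e5 + 1e3))
  ctcf <- tibble::tibble(chrom = "chrA", start = c(5e5 + 500, 7e5),
                         end = c(5e5 + 1500, 7e5 + 1e3))
  el <- build_elements(genes, active, ctcf)
  # the active peak overlapping the promoter is not an enhancer
  expect_equal(nrow(el$enhancers), 1)
  # the CTCF peak overlapping the enhancer is not a CTCF site
  expect_equal(nrow(el$ctcf_sites), 1)
  peaks <- tibble::tibble(chrom = "chrA",
                          start = c(1e5, 5e5, 7e5, 1.5e5, 9e5),
                          end = c(1e5, 5e5, 7e5, 1.5e5, 9e5) + 100)
  ann <- annotate_peaks(peaks, el)
  expect_equal(as.character(ann$peaks$category),
               c("promoter", "enhancer", "ctcf_site", "gene_body",
                 "other"))
  expect_equal(sum(ann$proportions$proportion), 1, tolerance = 1e-12)
})

test_that("priority annotation equals a sequential-predicate oracle", {
  g <- tiny_genome()
  set.seed(131)
  for (rep in 1:10) {
    el <- list(promoters = random_intervals(10, g, 2e3),
               enhancers = random_intervals(10, g, 2e3),
               ctcf_sites = random_intervals(10, g, 2e3),
               gene_bodies = random_intervals(10, g, 2e4))
    peaks <- random_intervals(50, g, 1e3)
    got <- annotate_peaks(peaks, el)$peaks$category
    order_ <- c("promoter", "enhancer", "ctcf_site", "gene_body")
    sets <- el[c("promoters", "enhancers", "ctcf_sites", "gene_bodies")]
    want <- vapply(seq_len(nrow(peaks)), function(i) {
      for (k in seq_along(order_)) {
        s <- sets[[k]]
        hit <- any(s$chrom == peaks$chrom[i] & s$start < peaks$end[i] &
                     peaks$start[i] < s$end)
        if (hit) return(order_[k])
      }
      "other"
    }, character(1))
    expect_equal(as.character(got), want)
  }
})

test_that("bound/unbound gene selection filters then sorts by signal", {
  g <- tiny_genome(c(chrA = 1e6))
  set.seed(137)
  genes <- tibble::tibble(id = sprintf("g%02d", 1:10), chrom = "chrA",
                          strand = "+",
                          tss = seq(5e4, 9.5e5, length.out = 10),
                          tes = seq(5e4, 9.5e5, length.out = 10) + 1e4)
  # peaks at the promoters of the first 5 genes
  tf <- tibble::tibble(chrom = "chrA", start = genes$tss[1:5] - 100,
                       end = genes$tss[1:5] + 100)
  tr <- const_track(g, 1000)
  tr$value <- stats::runif(nrow(tr), 0, 10)
  res <- bound_unbound_genes(genes, tf, tr, top_n = 3)
  expect_equal(nrow(res$bound), 3)
  expect_true(all(res$bound$id %in% genes$id[1:5]))
  # bound genes are the highest-signal peak-bearing ones
  prom <- tibble::tibble(chrom = "chrA", start = genes$tss - 1000,
                         end = genes$tss + 1000)
  sig <- chromshift:::signal_at_intervals(tr, prom)
  expect_equal(res$bound$id, genes$id[1:5][order(-sig[1:5])][1:3])
  # unbound genes are the lowest-signal peak-free ones
  expect_equal(res$unbound$id, genes$id[6:10][order(sig[6:10])][1:3])
  # a gene with no promoter peak can never be bound
  expect_false(any(res$bound$id %in% genes$id[6:10]))
  expect_warning(bound_unbound_genes(genes, tf, tr, top_n = 6), "fewer")
})

test_that("row z-scores use the sample SD and flag constant rows", {
  z <- zscore_rows(matrix(c(1, 2, 3), 1))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  set.seed(139)
  m <- matrix(stats::rnorm(60), 10)
  z2 <- zscore_rows(m)
  expect_true(all(abs(rowMeans(z2)) < 1e-12))
  expect_true(all(abs(apply(z2, 1, stats::sd) - 1) < 1e-12))
  # idempotence
  expect_equal(zscore_rows(z2), z2, ignore_attr = TRUE, tolerance = 1e-12)
  const <- rbind(m, 5)
  zc <- zscore_rows(const)
  expect_true(attr(zc, "flagged_rows")[11])
  expect_equal(zc[11, ], rep(0, 6))
})

test_that("elbow clustering recovers planted row groups", {
  set.seed(149)
  mk_groups <- function(centers, per = 20) {
    do.call(rbind, lapply(centers, function(mu) {
      matrix(stats::rnorm(per * 6, mean = rep(mu, each = per), sd = 0.3),
             per)
    }))
  }
  # three equally distinct change patterns -> elbow at k = 3, exact
  # partition
  m3 <- mk_groups(list(c(3, 0, 0, 0, 0, 0),
                       c(0, 3, 0, 0, 0, 0),
                       c(0, 0, 3, 0, 0, 0)))
  res3 <- cluster_diff_signal(zscore_rows(m3), k_range = 2:6)
  expect_equal(res3$k, 3)
  truth <- rep(1:3, each = 20)
  tab <- table(res3$labels, truth)
  expect_equal(sum(apply(tab, 2, max)), 60)   # pure clusters
  # two groups -> k = 2
  m2 <- mk_groups(list(c(3, 3, 3, -3, -3, -3), c(-3, -3, -3, 3, 3, 3)))
  expect_equal(cluster_diff_signal(zscore_rows(m2), k_range = 2:6)$k, 2)
  # identical rows: degenerate, smallest k with flag
  ident <- matrix(1, 10, 4)
  resd <- cluster_diff_signal(ident, k_range = 2:5)
  expect_true(resd$degenerate)
  expect_equal(resd$k, 2)
  expect_error(cluster_diff_signal(matrix(0, 2, 2)), "3 rows")
})

test_that("co-occupancy regions count distinct factors", {
  one <- tibble::tibble(chrom = "chrA", start = 100, end = 300)
  res <- cooccupancy_categories(list(f1 = one, f2 = one))
  expect_equal(nrow(res), 1)
  expect_equal(res$label, "2")
  # disjoint peaks from 5 factors: five singleton regions
  five <- lapply(0:4, function(k) {
    tibble::tibble(chrom = "chrA", start = k * 1e4, end = k * 1e4 + 100)
  })
  names(five) <- paste0("f", 1:5)
  res5 <- cooccupancy_categories(five)
  expect_equal(nrow(res5), 5)
  expect_true(all(res5$label == "1"))
  # all five sharing one site reads "4+"
  shared <- stats::setNames(rep(list(one), 5), paste0("f", 1:5))
  expect_equal(cooccupancy_categories(shared)$label, "4+")
})

test_that("co-occupancy matches an interval-union membership oracle", {
  g <- tiny_genome()
  set.seed(151)
  for (rep in 1:10) {
    sets <- lapply(1:4, function(k) random_intervals(15, g, 5e3))
    names(sets) <- paste0("f", 1:4)
    got <- cooccupancy_categories(sets)
    # oracle: flatten, merge overlapping/touching bp, count members
    all <- dplyr::bind_rows(sets, .id = "factor")
    for (ch in unique(all$chrom)) {
      sub <- all[all$chrom == ch, ]
      sub <- sub[order(sub$start), ]
      regions <- list()
      cur <- c(sub$start[1], sub$end[1])
      for (i in seq_len(nrow(sub))[-1]) {
        if (sub$start[i] <= cur[2]) {
          cur[2] <- max(cur[2], sub$end[i])
        } else {
          regions[[length(regions) + 1]] <- cur
          cur <- c(sub$start[i], sub$end[i])
        }
      }
      regions[[length(regions) + 1]] <- cur
      gch <- got[got$chrom == ch, ]
      expect_equal(nrow(gch), length(regions))
      for (r in seq_along(regions)) {
        expect_equal(gch$start[r], regions[[r]][1])
        expect_equal(gch$end[r], regions[[r]][2])
        nf <- sum(vapply(sets, function(s) {
          any(s$chrom == ch & s$start < regions[[r]][2] &
                regions[[r]][1] < s$end)
        }, logical(1)))
        expect_equal(gch$n_factors[r], nf)
      }
    }
  }
})

test_that("percent input follows the 5% baseline and Ct arithmetic", {
  expect_equal(percent_input(25, 25), 5)
  # one extra sample cycle halves the readout
  expect_equal(percent_input(25, 26), 2.5)
  # two fewer sample cycles quadruple it
  expect_equal(percent_input(25, 23), 20)
  expect_equal(percent_input(25, 25, input_fraction = 0.1), 10)
})

test_that("expression breadth and essentiality use strict thresholds", {
  tpm <- rbind(gA = c(50, 20, 11), gB = c(10, 9, 50), gC = c(1, 2, 3))
  crispr <- tibble::tibble(gene = c("gA", "gB", "gD"),
                           score = c(-0.5, -0.5, 0.3),
                           p = c(0.01, 0.2, 0.01))
  res <- resource_annotations(tpm, crispr)
  expect_equal(res$pct_tissues_expressed[res$gene == "gA"], 100)
  # TPM exactly 10 does not count (strict >)
  expect_equal(res$pct_tissues_expressed[res$gene == "gB"], 100 / 3)
  expect_equal(res$pct_tissues_expressed[res$gene == "gC"], 0)
  expect_true(res$essential[res$gene == "gA"])
  expect_false(res$essential[res$gene == "gB"])   # p too large
  expect_false(res$essential[res$gene == "gD"])   # positive score
  expect_true(is.na(res$pct_tissues_expressed[res$gene == "gD"]))
})
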