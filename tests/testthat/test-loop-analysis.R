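test_that("multi-resolution loops merge onto the coarsest bin grid", {
  g <- fixture_genome()
  # a 5 kb call and a 10 kb call landing in the same pair of 25 kb bins
  l5 <- loop_tbl("chrS1", 102000, 107000, 1003000, 1008000,
                 resolution = 5000)
  l10 <- loop_tbl("chrS1", 100000, 110000, 1000000, 1010000,
                  resolution = 10000)
  merged <- merge_multires_loops(list(l5, l10))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start1, 100000)   # 25 kb bin 4
  expect_equal(merged$end1, 125000)
  expect_equal(merged$source_resolution, 5000)
  # loops in distinct bin pairs are all preserved
  l25 <- loop_tbl("chrS1", c(0, 50e4), c(25e3, 52.5e4),
                  c(2e6, 3e6), c(2e6 + 25e3, 3e6 + 25e3),
                  resolution = 25000)
  expect_equal(nrow(merge_multires_loops(list(l25))), 2)
})

test_that("loop merging matches a bin-pair set oracle and is idempotent", {
  g <- fixture_genome()
  set.seed(73)
  for (rep in 1:10) {
    sets <- lapply(c(5000, 10000, 25000), function(res) {
      lp <- random_loops(30, g, len_range = c(2e5, 3e6), anchor = res)
      lp$resolution <- res
      lp
    })
    merged <- merge_multires_loops(sets)
    all <- dplyr::bind_rows(sets)
    key <- unique(paste(
      all$chrom,
      floor(floor((all$start1 + all$end1) / 2) / 25000),
      floor(floor((all$start2 + all$end2) / 2) / 25000)))
    expect_equal(nrow(merged), length(key))
    expect_setequal(paste(merged$chrom, merged$start1 / 25000,
                          merged$start2 / 25000), key)
    again <- merge_multires_loops(list(merged))
    expect_equal(loop_key(again), loop_key(merged))
  }
})

test_that("loop strength reads the central O/E block", {
  oe <- ones_oe(40)
  lp <- loop_tbl("chrA", 10 * 25000, 11 * 25000, 25 * 25000, 26 * 25000)
  expect_equal(loop_strength(oe, lp)$strength, 1)
  # identical matrices before and after give log2FC 0
  s1 <- loop_strength(oe, lp)$strength
  s2 <- loop_strength(oe, lp)$strength
  expect_equal(log2(s2 / s1), 0)
  # off-chromosome window is flagged NA
  edge <- loop_tbl("chrA", 0, 25000, 39 * 25000, 40 * 25000)
  expect_true(is.na(loop_strength(oe, edge)$strength))
})

test_that("GSEA running sum hits its extremes on concentrated hit sets", {
  set.seed(79)
  loops <- tibble::tibble(length = sort(stats::runif(100, 1e5, 3e6),
                                        decreasing = TRUE))
  # hits exactly the longest loops: maximal ES = 1
  res <- length_rank_gsea(loops, hits = 1:10, n_perm = 50, seed = 1)
  expect_equal(res$observed, 1, tolerance = 1e-12)
  expect_equal(res$p_value, (1 + sum(res$null >= 1)) / 51)
  # perfectly interleaved hits: ES near 0, p near 1
  even <- seq(5, 100, by = 10)
  res2 <- length_rank_gsea(loops, hits = even, n_perm = 200, seed = 1)
  expect_lt(abs(res2$observed), 0.12)
  expect_gt(res2$p_value, 0.5)
  expect_error(length_rank_gsea(loops, integer(0)), "subset")
  expect_error(length_rank_gsea(loops, 1:100), "subset")
})

test_that("GSEA ES equals the explicit running-sum maximum deviation", {
  set.seed(83)
  for (rep in 1:20) {
    N <- sample(20:60, 1)
    loops <- tibble::tibble(length = stats::runif(N, 1e5, 1e6))
    nh <- sample(3:(N - 3), 1)
    hits <- sample.int(N, nh)
    res <- length_rank_gsea(loops, hits, n_perm = 10, seed = rep)
    rs <- res$running_sum$running_sum
    es_oracle <- rs[which.max(abs(rs))]
    # ES compares the running-sum extreme against 0 as well
    if (abs(es_oracle) < 1e-15) es_oracle <- 0
    expect_equal(res$observed, es_oracle, tolerance = 1e-12)
  }
})

test_that("permutation results are bit-for-bit reproducible under a seed", {
  set.seed(89)
  loops <- tibble::tibble(length = stats::runif(200, 1e5, 3e6))
  hits <- sample.int(200, 20)
  a <- length_rank_gsea(loops, hits, n_perm = 100, seed = 42)
  b <- length_rank_gsea(loops, hits, n_perm = 100, seed = 42)
  expect_identical(a$null, b$null)
  expect_identical(a$p_value, b$p_value)
  g <- fixture_genome()
  lp <- random_loops(20, g)
  genes <- tibble::tibble(id = paste0("g", 1:100),
                          chrom = sample(g$chrom, 100, TRUE),
                          tss = round(stats::runif(100, 1e4, 9e6)),
                          category = sample(c("down", "up", "unchanged"),
                                            100, TRUE))
  r1 <- gene_category_enrichment(lp, genes, g, n_perm = 50, seed = 7)
  r2 <- gene_category_enrichment(lp, genes, g, n_perm = 50, seed = 7)
  expect_identical(r1, r2)
})

test_that("anchor-element enrichment handles saturation and planting", {
  g <- tiny_genome(c(chrA = 2e6), bin_size = NULL)
  set.seed(97)
  loops <- random_loops(10, g, len_range = c(2e5, 5e5), anchor = 2e4)
  # an element covering the whole chromosome is hit by every placement
  whole <- tibble::tibble(chrom = "chrA", start = 0, end = 2e6)
  sat <- anchor_element_enrichment(loops, list(all = whole), g,
                                   n_perm = 50, seed = 1)
  expect_equal(unname(sat$enrichment), 1)
  expect_equal(unname(sat$observed), 1)
  # elements planted exactly at the true anchors: enrichment well above 1
  # and the attainable minimum p
  planted <- tibble::tibble(
    chrom = rep(loops$chrom, 2),
    start = c(loops$start1, loops$start2),
    end = c(loops$end1, loops$end2))
  pl <- anchor_element_enrichment(loops, list(tf = planted), g,
                                  n_perm = 200, seed = 2)
  expect_gt(pl$enrichment, 2)
  expect_equal(unname(pl$p_value), 1 / 201)
  # nothing anywhere: flagged undefined
  nowhere <- tibble::tibble(chrom = "chrA", start = 1, end = 2)
  nw <- anchor_element_enrichment(loops, list(x = nowhere), g,
                                  n_perm = 20, seed = 3)
  if (nw$observed == 0 && nw$null_mean == 0) {
    expect_true(is.na(nw$enrichment))
  }
})

test_that("responsive-loop scores sum TF signal and |lfc| at inside peaks", {
  g <- fixture_genome()
  # loop with no ATAC peaks inside scores 0
  loops <- loop_tbl("chrS1", 1e6, 1.025e6, 1.8e6, 1.825e6, genome = g)
  atac <- peak_tbl(tibble::tibble(chrom = "chrS1", start = 5e6, end = 5e6 + 400,
                                  score = 1, tf_signal = 10, lfc = -1))
  tf <- tibble::tibble(chrom = "chrS1", start = 1.1e6, end = 1.1e6 + 400)
  down <- tf
  cl <- suppressWarnings(
    classify_responsive_loops(loops, tf, down, atac, genome = g,
                              min_length = 5e5, top_n = 5))
  expect_equal(cl$scores$score, 0)
  # forced partition: of two candidates, only the TF+down loop with the
  # higher score is responsive, the empty one is less-responsive
  loops2 <- loop_tbl("chrS1", c(1e6, 4e6), c(1.025e6, 4.025e6),
                     c(1.8e6, 4.8e6), c(1.825e6, 4.825e6), genome = g)
  atac2 <- peak_tbl(tibble::tibble(chrom = "chrS1",
                                   start = c(1.2e6, 1.4e6),
                                   end = c(1.2e6, 1.4e6) + 400, score = 1,
                                   tf_signal = c(8, 3), lfc = c(-2, -0.5)))
  cl2 <- suppressWarnings(
    classify_responsive_loops(loops2, tf, down, atac2, genome = g,
                              min_length = 5e5, top_n = 5))
  expect_equal(nrow(cl2$responsive), 1)
  expect_equal(cl2$responsive$start1, 1e6)
  expect_equal(cl2$responsive$score, 8 + 2 + 3 + 0.5)
  expect_equal(nrow(cl2$less_responsive), 1)
  expect_equal(cl2$less_responsive$start1, 4e6)
  # short loops are not candidates
  expect_error(
    classify_responsive_loops(
      loop_tbl("chrS1", 1e6, 1.025e6, 1.2e6, 1.225e6), tf, down, atac,
      genome = g),
    "candidate")
})

test_that("responsive-loop classification equals the brute-force oracle", {
  g <- fixture_genome()
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    loops <- random_loops(n, g, len_range = c(2e5, 3e6))
    tf <- random_intervals(15, g, max_len = 1e3)
    down <- random_intervals(15, g, max_len = 1e3)
    atac <- random_intervals(40, g, max_len = 1e3)
    atac$tf_signal <- stats::runif(40, 0, 20)
    atac$lfc <- stats::rnorm(40)
    got <- suppressWarnings(
      classify_responsive_loops(loops, tf, down, atac, genome = g,
                                top_n = 10))
    want <- oracle_classify(loops, tf, down, atac, g, top_n = 10)
    cand <- loops[loops$length > 5e5, ]
    expect_equal(loop_key(got$responsive),
                 loop_key(loops[want$responsive, , drop = FALSE]))
    expect_equal(loop_key(got$less_responsive),
                 loop_key(loops[want$less_responsive, , drop = FALSE]))
  }
})

test_that("gene-category ratios behave at the design extremes", {
  g <- fixture_genome()
  set.seed(103)
  # loop set covering (almost) the whole genome: observed = expected
  loops <- loop_tbl(g$chrom, c(0, 0), c(25e3, 25e3),
                    c(1e7 - 25e3, 1e7 - 25e3), c(1e7, 1e7), genome = g)
  genes <- tibble::tibble(id = paste0("g", 1:300),
                          chrom = sample(g$chrom, 300, TRUE),
                          tss = round(stats::runif(300, 1e5, 9.8e6)),
                          category = sample(c("down", "up", "unchanged"),
                                            300, TRUE, prob = c(.2, .2, .6)))
  r <- gene_category_enrichment(loops, genes, g, n_perm = 30, seed = 1)
  expect_equal(r$ratio, rep(1, 3), tolerance = 1e-12)
  expect_equal(r$n_genes_in_loops[1], 300)
  # uniformly random categories: ratios near 1, nothing significant
  lp <- random_loops(25, g, len_range = c(5e5, 2e6))
  r2 <- gene_category_enrichment(lp, genes, g, n_perm = 200, seed = 2)
  expect_true(all(abs(r2$ratio - 1) < 0.35))
  expect_true(all(r2$p_value > 0.05))
  expect_error(gene_category_enrichment(
    lp, dplyr::mutate(genes, category = NA), g, n_perm = 5), "categorized")
})

test_that("planted 2x up-enrichment inside loops is detected", {
  g <- fixture_genome()
  set.seed(107)
  # a sparse loop set, so in-loop enrichment is not diluted by coverage
  lp <- random_loops(4, g, len_range = c(5e5, 6e5))
  n <- 1500
  genes <- tibble::tibble(id = paste0("g", seq_len(n)),
                          chrom = sample(g$chrom, n, TRUE),
                          tss = round(stats::runif(n, 1e5, 9.8e6)))
  inside <- rep(FALSE, n)
  for (i in seq_len(nrow(lp))) {
    inside <- inside | (genes$chrom == lp$chrom[i] &
                          genes$tss >= lp$start1[i] &
                          genes$tss <= lp$end2[i])
  }
  # up-rate doubled inside the loops; "down" kept at a flat rate
  r <- stats::runif(n)
  rate_up <- ifelse(inside, 0.30, 0.15)
  genes$category <- ifelse(r < rate_up, "up",
                           ifelse(r > 0.8, "down", "unchanged"))
  res <- gene_category_enrichment(lp, genes, g, n_perm = 2000, seed = 3)
  up <- res[res$category == "up", ]
  # analytic expectation: ratio = r_in / (r_in * f + r_out * (1 - f))
  frac_in <- mean(inside)
  expected_ratio <- 0.30 / (0.30 * frac_in + 0.15 * (1 - frac_in))
  expect_equal(up$ratio, expected_ratio, tolerance = 0.15 * expected_ratio)
  expect_lte(up$p_value, 0.01)
})

test_that("perm_test tidiers and plots expose the null summary", {
  loops <- tibble::tibble(length = stats::runif(50, 1e5, 1e6))
  res <- length_rank_gsea(loops, 1:5, n_perm = 50, seed = 1)
  td <- generics::tidy(res)
  expect_equal(td$n_perm, 50)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(plot_gsea(res), "ggplot")
})
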