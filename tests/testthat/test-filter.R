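test_that("sigma_mask matches direct recomputation, including the masking effect", {
  x <- c(rep(1, 9), 100)
  expect_false(any(sigma_mask(x, 3)))  # sd ~ 31.3 masks the outlier
  mu <- mean(x); s <- sd(x)
  expect_equal(sigma_mask(x, 3), x < mu - 3 * s | x > mu + 3 * s)
  y <- c(rep(1, 1000), 100)
  m <- sigma_mask(y, 3)
  expect_equal(which(m), 1001L)
  expect_false(any(sigma_mask(rep(2.5, 10), 3)))  # sigma = 0, documented
  expect_error(sigma_mask(c(1, NA), 3), "at least 2")
})

test_that("tukey_mask follows the interpolated-quantile fence convention", {
  x <- c(1:9, 100)
  q <- quantile(x, c(0.25, 0.75), type = 7)
  expect_equal(unname(q), c(3.25, 7.75))
  expect_equal(which(tukey_mask(x, 1.5)), 10L)  # fences [-3.5, 14.5]
  expect_equal(which(tukey_mask(x, 8)), 10L)    # fences [-32.75, 43.75]
  expect_false(any(tukey_mask(x, 25)))          # fences [-109.25, 120.25]
  expect_false(any(tukey_mask(rep(1, 10))))     # IQR = 0, all equal Q1
  # outer fence doubles the multiplier
  expect_equal(tukey_mask(x, 4, fence = "inner"), tukey_mask(x, 2, fence = "outer"))
  # NA values never flagged
  expect_false(tail(tukey_mask(c(x, NA), 1.5), 1))
})

test_that("retained sets are nested as the fence parameter grows", {
  set.seed(21)
  for (rep in 1:10) {
    x <- c(rnorm(150, 0.03, 0.01), runif(8, 0.2, 1))
    masks_t <- lapply(c(1.5, 2, 4, 8), function(i) tukey_mask(x, i))
    for (j in 1:3) expect_true(all(masks_t[[j]] | !masks_t[[j + 1]]))
    masks_s <- lapply(c(1, 2, 3, 4), function(k) sigma_mask(x, k))
    for (j in 1:3) expect_true(all(masks_s[[j]] | !masks_s[[j + 1]]))
  }
})

test_that("slope_filter removes aberrant-slope blocks only when enough blocks exist", {
  blocks <- tibble::tibble(block_id = sprintf("b%02d", 1:10),
                           chrom_a = "chrA1", chrom_b = "chrB1",
                           n_anchors = 10L, orientation = "forward",
                           slope = c(rep(1, 9), 12))
  cfg <- filter_config(method = "tukey")
  out <- slope_filter(blocks, cfg)
  expect_equal(which(out$slope_outlier), 10L)
  expect_equal(out$slope_outlier, tukey_mask(blocks$slope, 1.5))
  ok <- slope_filter(blocks[blocks$slope == 1, ], cfg)
  expect_false(any(ok$slope_outlier))
  expect_warning(few <- slope_filter(blocks[1:3, ], cfg), "too few")
  expect_false(any(few$slope_outlier))
})

test_that("statuses partition all RBH pairs and report counts telescope", {
  sim <- small_sim()
  res <- identify_alleles(sim$genes_a, sim$genes_b, sim$chromosome_map)
  expect_false(anyNA(res$pairs$status))
  g <- glance(res)
  expect_true(g$n_rbh >= g$n_same_chrom)
  expect_true(g$n_same_chrom >= g$n_colinear)
  expect_true(g$n_colinear >= g$n_after_ks)
  expect_true(g$n_after_ks >= g$n_alleles)
  expect_equal(g$n_colinear - g$n_saturated_removed - g$n_ks_removed,
               g$n_after_ks)
  expect_equal(g$n_after_ks - g$n_slope_removed, g$n_alleles)
  rep <- res$report
  expect_equal(rep$retained[-1] + rep$removed[-1],
               rep$retained[-nrow(rep)])
})

test_that("a paralog-free simulation passes through with no removals", {
  sim <- simulate_diploid(sim_config(n_chrom_pairs = 1, genes_per_chrom = 80,
                                     n_paralogs = 0, n_inversions = 0),
                          seed = 4)
  res <- identify_alleles(sim$genes_a, sim$genes_b, sim$chromosome_map)
  g <- glance(res)
  expect_equal(g$n_rbh, 80L)
  expect_equal(g$n_alleles + g$n_ks_removed, 80L)
  expect_equal(g$n_rbh - g$n_colinear, 0L)
})

test_that("tukey retention at i = 1.5 is a subset of sigma retention on near-normal Ks", {
  sim <- small_sim()
  res_s <- identify_alleles(sim$genes_a, sim$genes_b, sim$chromosome_map,
                            config = filter_config(method = "sigma"))
  res_t <- identify_alleles(sim$genes_a, sim$genes_b, sim$chromosome_map,
                            config = filter_config(method = "tukey"))
  kept_s <- with(res_s$pairs, paste(gene_a, gene_b)[status == "allele"])
  kept_t <- with(res_t$pairs, paste(gene_a, gene_b)[status == "allele"])
  expect_true(all(kept_t %in% kept_s))
})

test_that("both filter-layer orders are available and counted consistently", {
  sim <- small_sim()
  res <- identify_alleles(sim$genes_a, sim$genes_b, sim$chromosome_map,
                          config = filter_config(slope_before_ks = TRUE))
  expect_equal(res$report$stage[5:6], c("slope_filtered", "ks_filtered"))
  expect_false(anyNA(res$pairs$status))
  g <- glance(res)
  expect_equal(g$n_colinear - g$n_saturated_removed - g$n_ks_removed -
                 g$n_slope_removed, g$n_alleles)
})

test_that("an empty survivor set is a valid result, not an error", {
  map <- tibble::tibble(chrom_a = "chrX", chrom_b = "chrY")  # nothing matches
  sim <- simulate_diploid(sim_config(n_chrom_pairs = 1, genes_per_chrom = 20,
                                     n_paralogs = 0, n_inversions = 0),
                          seed = 5)
  res <- identify_alleles(sim$genes_a, sim$genes_b, map)
  expect_equal(sum(res$pairs$status == "allele"), 0L)
  expect_true(all(res$pairs$status == "rejected_cross_chrom"))
})
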