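toy_counts <- function(a_rows, b_rows, samples = paste0("s", 1:3)) {
  m <- rbind(a_rows, b_rows)
  rownames(m) <- c(paste0("A", seq_len(nrow(a_rows))),
                   paste0("B", seq_len(nrow(b_rows))))
  colnames(m) <- samples
  m
}

toy_design <- function(samples = paste0("s", 1:3), condition = "c1") {
  tibble::tibble(sample_id = samples, condition = condition)
}

toy_pairs <- function(n) {
  tibble::tibble(gene_a = paste0("A", 1:n), gene_b = paste0("B", 1:n))
}

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 40, 50, 10, 20, 30, 40, 50), ncol = 2)
  rownames(m) <- paste0("g", 1:5); colnames(m) <- c("s1", "s2")
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- m; m2[, 2] <- 2 * m[, 1]
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)  # proportional 1 : 2
  # hand computation on the 5-gene toy: geomean_g = sqrt(2) * col1
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(size_factors(m[, 1, drop = FALSE])), 1)
  zero <- matrix(c(0, 5, 3, 0), 2)
  expect_error(size_factors(zero), "pseudo_reference")
  expect_silent(size_factors(zero, pseudo_reference = TRUE))
  # independent cross-check against the reference implementation
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(m2)
  expect_equal(unname(sf), unname(sf_ref))
})

test_that("TPM is length- and depth-normalized with columns summing to 1e6", {
  counts <- matrix(c(10, 20), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- compute_tpm(counts, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))
  expect_equal(compute_tpm(counts * 2, c(g1 = 1000, g2 = 2000)), tpm)
  z <- compute_tpm(matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "s1")),
                   c(g1 = 1000, g2 = 2000))
  expect_true(all(z == 0))
  set.seed(1)
  big <- matrix(rpois(300, 50), 100, 3,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:3)))
  expect_equal(unname(colSums(compute_tpm(big, rep(1500, 100)))), rep(1e6, 3))
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "lie in")
})

test_that("identical allele counts give log2fc 0 and p 1", {
  a <- matrix(rep(c(100, 110, 90), each = 4), 4, 3, byrow = FALSE)
  res <- test_allele_pairs(toy_counts(a, a), toy_design(), toy_pairs(4))
  expect_equal(res$log2fc, rep(0, 4))
  expect_equal(res$p, rep(1, 4))
  expect_equal(res$fc_magnitude, rep(1, 4))
})

test_that("a strong expression difference is detected with the stated estimator", {
  a <- matrix(c(100, 110, 90), 1)
  b <- matrix(c(10, 9, 11), 1)
  # constant filler rows force the median-of-ratios size factors to exactly 1
  filler <- rbind(matrix(50, 1, 3), matrix(70, 1, 3))
  counts <- toy_counts(rbind(a, filler), rbind(b, filler))
  expect_equal(unname(size_factors(counts)), rep(1, 3))
  res <- test_allele_pairs(counts, toy_design(), toy_pairs(3))
  r1 <- res[1, ]
  expect_equal(r1$fc_magnitude, 100.5 / 10.5, tolerance = 1e-9)  # ~ 10
  expect_lt(r1$p, 0.01)
  # oracle: exact recomputation per the estimator formulas
  alpha <- max((((var(c(100, 110, 90)) - 100) / 100^2) +
                  ((var(c(10, 9, 11)) - 10) / 10^2)) / 2, 1e-8)
  se <- sqrt(1 / (3 * 100.5) + alpha / 3 + 1 / (3 * 10.5) + alpha / 3)
  t_stat <- log(100.5 / 10.5) / se
  expect_equal(r1$p, 2 * pt(-abs(t_stat), df = 4), tolerance = 1e-12)
})

test_that("swapping alleles negates log2fc and preserves p and category", {
  set.seed(8)
  a <- matrix(rnbinom(60, mu = 80, size = 10), 20, 3)
  b <- matrix(rnbinom(60, mu = 40, size = 10), 20, 3)
  res <- test_allele_pairs(toy_counts(a, b), toy_design(), toy_pairs(20))
  swapped <- toy_pairs(20)[, c("gene_a", "gene_b")]
  names(swapped) <- c("gene_b", "gene_a")
  res_sw <- test_allele_pairs(toy_counts(a, b), toy_design(),
                              swapped[, c("gene_a", "gene_b")])
  expect_equal(res_sw$log2fc, -res$log2fc)
  expect_equal(res_sw$p, res$p)
  expect_equal(res_sw$padj, res$padj)
  expect_equal(res_sw$fc_magnitude, res$fc_magnitude)
  expect_equal(as.character(res_sw$category), as.character(res$category))
})

test_that("classification thresholds follow the five-category rules", {
  expect_equal(as.character(classify_ase(0.2, 3, FALSE)), "Diff00")
  expect_equal(as.character(classify_ase(0.04, 1.5, FALSE)), "Diff0")
  expect_equal(as.character(classify_ase(0.04, 2, FALSE)), "Diff0")   # |FC| = 2
  expect_equal(as.character(classify_ase(0.01, 5, FALSE)), "Diff2")
  expect_equal(as.character(classify_ase(0.01, 8, FALSE)), "Diff8")   # |FC| = 8
  expect_equal(as.character(classify_ase(0.01, 10, FALSE)), "Diff8")
  expect_equal(as.character(classify_ase(NA, NA, FALSE)), "Diff00")   # untestable
  expect_equal(as.character(classify_ase(0.01, 10, TRUE)), "No_expression")
})

test_that("fully silent pairs are No_expression and categories partition pairs", {
  a <- rbind(matrix(0, 2, 3), matrix(c(30, 35, 25), 2, 3, byrow = TRUE))
  b <- rbind(matrix(0, 2, 3), matrix(c(30, 28, 33), 2, 3, byrow = TRUE))
  res <- test_allele_pairs(toy_counts(a, b), toy_design(), toy_pairs(4))
  expect_equal(as.character(res$category[1:2]), rep("No_expression", 2))
  expect_false(anyNA(res$category))
  expect_equal(nrow(res), 4L)
})

test_that("too few replicates leaves pairs untestable with a warning", {
  a <- matrix(c(10, 12), 1, 2)
  counts <- toy_counts(a, a + 5, samples = c("s1", "s2"))
  expect_warning(
    res <- test_allele_pairs(counts, toy_design(samples = c("s1", "s2")),
                             toy_pairs(1)),
    "untestable")
  expect_true(is.na(res$p))
  expect_equal(as.character(res$category), "Diff00")
})

test_that("divergence and expression-gap summaries rank categories as simulated", {
  sim <- simulate_diploid(sim_config(n_chrom_pairs = 1, genes_per_chrom = 300,
                                     n_paralogs = 0, n_inversions = 0,
                                     fraction_ase = 0.3), seed = 6)
  cnt <- simulate_counts(sim, seed = 6)
  res <- test_allele_pairs(cnt$counts, cnt$design, sim$truth)
  div <- pair_divergence(sim$truth[, c("gene_a", "gene_b")],
                         sim$genes_a, sim$genes_b)
  summ <- divergence_by_category(div, res)
  expect_equal(nrow(summ$summary), 9L)
  expect_true(all(c("Diff0", "Diff2", "Diff8") %in% summ$summary$category))
  empty_rows <- summ$summary[summ$summary$n == 0, ]
  expect_true(all(is.na(empty_rows$median)))
  tpm <- compute_tpm(cnt$counts, cnt$gene_lengths)
  gap <- expression_gap_by_category(res, tpm, cnt$design)
  expect_equal(gap$category, c("Diff0", "Diff2", "Diff8"))
  # simulated Diff8 pairs have a 16-fold shift: their TPM gap dwarfs Diff0's
  if (!is.na(gap$median[gap$category == "Diff8"]) &&
      !is.na(gap$median[gap$category == "Diff0"])) {
    expect_gt(gap$median[3], gap$median[1])
  }
})

test_that("haplotype bias counts are symmetric under a null and exact when biased", {
  sim <- simulate_diploid(sim_config(n_chrom_pairs = 10, genes_per_chrom = 60,
                                     n_paralogs = 0, n_inversions = 0),
                          seed = 12)
  cnt <- simulate_counts(sim, seed = 12)
  res <- test_allele_pairs(cnt$counts, cnt$design, sim$truth)
  tpm <- compute_tpm(cnt$counts, cnt$gene_lengths)
  pairs_chrom <- dplyr::mutate(sim$truth,
                               chrom_a = substr(gene_a, 4, 9),
                               chrom_b = substr(gene_b, 4, 9))
  bias <- haplotype_bias_counts(res, tpm, cnt$design, pairs_chrom)
  expect_equal(nrow(bias), 10L)
  expect_gte(sum(bias$p_sign > 0.05), 9L)  # symmetric expression, no true bias
  # force every pair to favour haplotype A
  tpm_biased <- tpm
  tpm_biased[sim$truth$gene_a, ] <- tpm[sim$truth$gene_b, ] + 1
  bias2 <- haplotype_bias_counts(res, tpm_biased, cnt$design, pairs_chrom)
  expect_true(all(bias2$n_b_higher == 0))
  # no expressed pairs -> empty table
  empty <- haplotype_bias_counts(res[0, ], tpm, cnt$design, pairs_chrom)
  expect_equal(nrow(empty), 0L)
})
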