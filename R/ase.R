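#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with a positive geometric mean across samples) of the ratio of the
#' gene's count to its geometric mean. With `pseudo_reference = TRUE` the
#' geometric mean is taken over positive counts only, a fallback for sparse
#' matrices where no gene is positive in every sample.
#'
#' @param counts Numeric matrix, genes x samples.
#' @param pseudo_reference Use the positive-count geometric mean. Default
#'   `FALSE`.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  if (pseudo_reference) {
    lg <- apply(counts, 1L, function(x) {
      if (all(x == 0)) -Inf else mean(log(x[x > 0]))
    })
  } else {
    lg <- rowMeans(log(counts))
  }
  use <- is.finite(lg)
  if (!any(use)) {
    abort(paste0("no gene has a positive geometric mean across samples; ",
                 "consider pseudo_reference = TRUE"))
  }
  sf <- apply(counts[use, , drop = FALSE], 2L, function(x) {
    exp(median(log(x[x > 0]) - lg[use][x > 0]))
  })
  if (anyNA(sf) || any(sf <= 0)) abort("undefined size factor for some sample")
  sf
}

#' Transcripts per kilobase million
#'
#' `rate = count / (length/1000)`, scaled so each column sums to one
#' million. An all-zero column stays all-zero.
#'
#' @param counts Numeric matrix, genes x samples.
#' @param gene_lengths Named or positionally matched vector of gene lengths
#'   in bp (> 0).
#' @return Matrix of TPM values, same dimensions as `counts`.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0))
  rate <- counts / (gene_lengths / 1000)
  tot <- colSums(rate)
  tot[tot == 0] <- 1  # all-zero column stays zero
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Benjamini–Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1. `NA` p-values (untestable pairs) stay `NA` and do not enter
#' the ranking.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (!all(is.na(p) | (p >= 0 & p <= 1))) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Vectorized negative-binomial Wald test between two groups of normalized
# counts (rows = pairs). Method-of-moments dispersion pooled across the two
# groups with a floor; fold estimate stabilized with a pseudocount. The Wald
# statistic is referred to a t distribution with ra + rb - 2 df: with the
# dispersion estimated from as few as 3 replicates per group a normal
# reference is badly anticonservative.
nb_wald <- function(norm_a, norm_b, dispersion_floor = 1e-8, pseudocount = 0.5) {
  ra <- ncol(norm_a)
  rb <- ncol(norm_b)
  mean_a <- unname(rowMeans(norm_a))
  mean_b <- unname(rowMeans(norm_b))
  mom <- function(m, mu) {
    v <- unname(apply(m, 1L, stats::var))
    a <- (v - mu) / mu^2
    a[!is.finite(a)] <- 0
    a
  }
  alpha <- pmax((mom(norm_a, mean_a) + mom(norm_b, mean_b)) / 2, dispersion_floor)
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  w <- function(mu, r) 1 / (r * (mu + pseudocount)) + alpha / r
  se_ln <- sqrt(w(mean_a, ra) + w(mean_b, rb))
  z <- (log2fc * log(2)) / se_ln
  p <- 2 * stats::pt(-abs(z), df = ra + rb - 2L)
  tibble(mean_a = mean_a, mean_b = mean_b, log2fc = log2fc,
         fc_magnitude = 2^abs(log2fc), p = pmin(p, 1))
}

#' Differential expression test for allele pairs
#'
#' For each allele pair and condition, the two alleles are treated as two
#' count groups over the condition's replicates on size-factor-normalized
#' counts and compared with a negative-binomial Wald test: method-of-moments
#' dispersion per pair (floored), a pseudocount-stabilized log2 fold change
#' of allele A over allele B, and a two-sided p-value on the Wald statistic
#' referred to a t distribution with `r_a + r_b - 2` degrees of freedom
#' (small-sample correction for the estimated dispersion). P-values are Benjamini–Hochberg-adjusted across all pairs
#' within each condition. Conditions with fewer than `min_reps` replicates
#' leave their pairs untestable (`NA` p).
#'
#' @param counts Raw count matrix, genes x samples (rownames = gene ids).
#' @param design Tibble with `sample_id`, `condition`.
#' @param pairs Tibble with `gene_a`, `gene_b` (e.g. the allele rows of
#'   `tidy(allele_set)`).
#' @param min_reps Minimum replicates per condition. Default 3.
#' @param alpha Adjusted-p significance threshold used by the classifier.
#'   Default 0.05.
#' @param aggregate Classify on the minimum adjusted p across conditions
#'   instead of per condition. Default `FALSE` (per condition).
#' @param dispersion_floor,pseudocount Estimator constants.
#' @return Object of class `ase_result`: tibble with one row per pair per
#'   condition (`gene_a`, `gene_b`, `condition`, `mean_a`, `mean_b`,
#'   `log2fc`, `fc_magnitude`, `p`, `padj`, `category`) plus attributes.
#'   `tidy()` returns it as a plain tibble; `glance()` gives per-condition
#'   category counts.
#' @export
test_allele_pairs <- function(counts, design, pairs, min_reps = 3L,
                              alpha = 0.05, aggregate = FALSE,
                              dispersion_floor = 1e-8, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  missing <- setdiff(c(pairs$gene_a, pairs$gene_b), rownames(counts))
  if (length(missing) > 0L) {
    abort(paste0("pairs reference genes absent from the count matrix: ",
                 paste(head(missing, 10L), collapse = ", ")))
  }
  if (!all(design$sample_id %in% colnames(counts))) {
    abort("design references samples absent from the count matrix")
  }
  sf <- size_factors(counts[, design$sample_id, drop = FALSE])
  res <- purrr::map_dfr(split(design, design$condition), function(d) {
    cols <- d$sample_id
    raw_a <- counts[pairs$gene_a, cols, drop = FALSE]
    raw_b <- counts[pairs$gene_b, cols, drop = FALSE]
    norm_a <- sweep(raw_a, 2L, sf[cols], "/")
    norm_b <- sweep(raw_b, 2L, sf[cols], "/")
    if (length(cols) < min_reps) {
      warn(sprintf("condition '%s' has %d replicate(s) (< %d): pairs untestable",
                   d$condition[1], length(cols), min_reps))
      out <- tibble(mean_a = unname(rowMeans(norm_a)),
                    mean_b = unname(rowMeans(norm_b)),
                    log2fc = NA_real_, fc_magnitude = NA_real_, p = NA_real_)
    } else {
      out <- nb_wald(norm_a, norm_b, dispersion_floor, pseudocount)
    }
    out$no_expression <- unname(rowSums(raw_a) == 0 & rowSums(raw_b) == 0)
    out$padj <- bh_adjust(out$p)
    bind_cols(pairs[, c("gene_a", "gene_b")],
              tibble(condition = d$condition[1]), out)
  })
  if (aggregate) {
    agg <- res |>
      group_by(.data$gene_a, .data$gene_b) |>
      mutate(padj_cls = suppressWarnings(min(.data$padj, na.rm = TRUE)),
             no_expression = all(.data$no_expression)) |>
      ungroup()
    agg$padj_cls[!is.finite(agg$padj_cls)] <- NA_real_
    res$category <- classify_ase(agg$padj_cls, res$fc_magnitude,
                                 agg$no_expression, alpha = alpha)
    res$no_expression <- agg$no_expression
  } else {
    res$category <- classify_ase(res$padj, res$fc_magnitude,
                                 res$no_expression, alpha = alpha)
  }
  res <- relocate(res, "condition", .after = "gene_b")
  structure(res, class = c("ase_result", class(tibble())),
            alpha = alpha, min_reps = min_reps)
}

#' Classify allele-specific expression into the five categories
#'
#' `No_expression` when neither allele has a single read in any replicate of
#' the condition; otherwise `Diff00` when the pair is not significantly
#' differentially expressed (adjusted p above `alpha`, or untestable);
#' otherwise by linear fold-change magnitude `2^|log2FC|`: `Diff0` when
#' `|FC| <= 2`, `Diff2` when `2 < |FC| < 8`, `Diff8` when `|FC| >= 8`.
#'
#' @param padj Adjusted p-values (`NA` = untestable).
#' @param fc_magnitude Linear fold-change magnitudes (>= 1).
#' @param no_expression Logical: both alleles fully silent.
#' @param alpha Significance threshold. Default 0.05.
#' @return Factor with levels `No_expression`, `Diff00`, `Diff0`, `Diff2`,
#'   `Diff8`.
#' @export
classify_ase <- function(padj, fc_magnitude, no_expression, alpha = 0.05) {
  cat <- rep("Diff00", length(padj))
  sig <- !is.na(padj) & padj <= alpha
  cat[sig & fc_magnitude <= 2] <- "Diff0"
  cat[sig & fc_magnitude > 2 & fc_magnitude < 8] <- "Diff2"
  cat[sig & fc_magnitude >= 8] <- "Diff8"
  cat[no_expression] <- "No_expression"
  factor(cat, levels = c("No_expression", "Diff00", "Diff0", "Diff2", "Diff8"))
}

#' @rdname test_allele_pairs
#' @param x An `ase_result`.
#' @param ... Unused.
#' @export
tidy.ase_result <- function(x, ...) {
  as_tibble(x)
}

#' @rdname test_allele_pairs
#' @export
glance.ase_result <- function(x, ...) {
  as_tibble(x) |>
    count(.data$condition, .data$category, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
}

#' Divergence summaries per ASE category
#'
#' For each differentially expressed category (Diff0, Diff2, Diff8):
#' n and the quartiles of Ka, Ks and Ka/Ks, plus pairwise two-sided
#' Wilcoxon rank-sum p-values between categories on each statistic.
#'
#' @param pair_divergence Tibble with `gene_a`, `gene_b`, `ka`, `ks`,
#'   `ka_ks` (e.g. `tidy(allele_set)` restricted to alleles).
#' @param ase An `ase_result` (or its tibble).
#' @return List with `summary` (one row per category x statistic) and
#'   `tests` (pairwise rank-sum p-values).
#' @export
divergence_by_category <- function(pair_divergence, ase) {
  d <- as_tibble(ase) |>
    inner_join(pair_divergence[, c("gene_a", "gene_b", "ka", "ks", "ka_ks")],
               by = c("gene_a", "gene_b")) |>
    filter(.data$category %in% c("Diff0", "Diff2", "Diff8")) |>
    tidyr::pivot_longer(c("ka", "ks", "ka_ks"), names_to = "statistic",
                        values_to = "value")
  cats <- c("Diff0", "Diff2", "Diff8")
  summary <- tidyr::expand_grid(category = cats,
                                statistic = c("ka", "ks", "ka_ks")) |>
    left_join(d |> group_by(.data$category, .data$statistic) |>
                summarise(n = sum(!is.na(.data$value)),
                          q1 = quantile(.data$value, 0.25, na.rm = TRUE),
                          median = median(.data$value, na.rm = TRUE),
                          q3 = quantile(.data$value, 0.75, na.rm = TRUE),
                          .groups = "drop") |>
                mutate(category = as.character(.data$category)),
              by = c("category", "statistic")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
  combos <- utils::combn(cats, 2L, simplify = FALSE)
  tests <- purrr::map_dfr(c("ka", "ks", "ka_ks"), function(stat) {
    purrr::map_dfr(combos, function(cc) {
      x <- d$value[d$category == cc[1] & d$statistic == stat]
      y <- d$value[d$category == cc[2] & d$statistic == stat]
      p <- if (sum(!is.na(x)) > 0L && sum(!is.na(y)) > 0L) {
        suppressWarnings(wilcox.test(x, y)$p.value)
      } else NA_real_
      tibble(statistic = stat, group1 = cc[1], group2 = cc[2], p = p)
    })
  })
  list(summary = summary, tests = tests)
}

#' Haplotype expression-bias counts per chromosome pair
#'
#' For each corresponding chromosome pair and condition, counts the allele
#' pairs whose haplotype-A allele has the higher mean TPM and those where B
#' is higher (ties and fully silent pairs excluded), with a two-sided sign
#' test per chromosome pair.
#'
#' @param ase An `ase_result`.
#' @param tpm TPM matrix (genes x samples).
#' @param design Tibble `sample_id`, `condition`.
#' @param pairs Tibble with `gene_a`, `gene_b`, `chrom_a`, `chrom_b`.
#' @return Tibble: `chrom_a`, `chrom_b`, `condition`, `n_a_higher`,
#'   `n_b_higher`, `p_sign`.
#' @export
haplotype_bias_counts <- function(ase, tpm, design, pairs) {
  df <- as_tibble(ase) |>
    inner_join(pairs[, c("gene_a", "gene_b", "chrom_a", "chrom_b")],
               by = c("gene_a", "gene_b"))
  if (nrow(df) == 0L) {
    return(tibble(chrom_a = character(), chrom_b = character(),
                  condition = character(), n_a_higher = integer(),
                  n_b_higher = integer(), p_sign = numeric()))
  }
  df$tpm_a <- mean_tpm(tpm, design, df$gene_a, df$condition)
  df$tpm_b <- mean_tpm(tpm, design, df$gene_b, df$condition)
  df |>
    filter(.data$tpm_a != .data$tpm_b) |>
    group_by(.data$chrom_a, .data$chrom_b, .data$condition) |>
    summarise(n_a_higher = sum(.data$tpm_a > .data$tpm_b),
              n_b_higher = sum(.data$tpm_b > .data$tpm_a),
              .groups = "drop") |>
    rowwise() |>
    mutate(p_sign = binom.test(.data$n_a_higher,
                               .data$n_a_higher + .data$n_b_higher)$p.value) |>
    ungroup()
}

mean_tpm <- function(tpm, design, gene, condition) {
  vapply(seq_along(gene), function(i) {
    cols <- design$sample_id[design$condition == condition[i]]
    mean(tpm[gene[i], cols])
  }, numeric(1))
}

#' Absolute expression gap per ASE category
#'
#' Distribution summary of `|TPM_A - TPM_B|` (condition means) for the three
#' differentially expressed categories.
#'
#' @inheritParams haplotype_bias_counts
#' @return Tibble: `category`, `n`, `q1`, `median`, `q3`, `mean`.
#' @export
expression_gap_by_category <- function(ase, tpm, design) {
  df <- as_tibble(ase) |>
    filter(.data$category %in% c("Diff0", "Diff2", "Diff8"))
  gap <- if (nrow(df) > 0L) {
    abs(mean_tpm(tpm, design, df$gene_a, df$condition) -
          mean_tpm(tpm, design, df$gene_b, df$condition))
  } else numeric()
  tibble(category = c("Diff0", "Diff2", "Diff8")) |>
    left_join(tibble(category = as.character(df$category), gap = gap) |>
                group_by(.data$category) |>
                summarise(n = n(), q1 = quantile(.data$gap, 0.25),
                          median = median(.data$gap),
                          q3 = quantile(.data$gap, 0.75),
                          mean = mean(.data$gap), .groups = "drop"),
              by = "category") |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
}
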