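#' Colinearity dot plot of candidate allele pairs
#'
#' One panel per corresponding chromosome pair; each point is an RBH pair at
#' the bp midpoints of its two genes, coloured by filter status. A clean
#' diagonal of retained alleles with rejected classes off-diagonal is the
#' expected quality-control picture.
#'
#' @param allele_set An `allele_set` from [identify_alleles()].
#' @param path Optional output path (`.svg` or `.pdf`); when given the plot
#'   is also written there.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(allele_set, path = NULL) {
  df <- allele_set$pairs |>
    filter(!is.na(.data$mid_a) & !is.na(.data$mid_b))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_a, y = .data$mid_b,
                                        colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::facet_wrap(~ paste(chrom_a, "/", chrom_b), scales = "free") +
    ggplot2::labs(x = "haplotype A position (bp)",
                  y = "haplotype B position (bp)", colour = "status") +
    ggplot2::theme_bw()
  if (!is.null(path)) ggsave_vector(path, p, width = 8, height = 6)
  p
}

# vector output via the base svg/pdf devices (no extra device packages)
ggsave_vector <- function(path, plot, width, height) {
  dev <- if (grepl("\\.pdf$", path)) grDevices::pdf else grDevices::svg
  ggplot2::ggsave(path, plot, device = dev, width = width, height = height)
}

#' @rdname identify_alleles
#' @param object An `allele_set`.
#' @export
autoplot.allele_set <- function(object, ...) {
  plot_dotplot(object)
}

#' Summary plots of allele-specific expression
#'
#' Produces the standard ASE panels: stacked category counts per condition,
#' boxplots of Ka, Ks and Ka/Ks by category, the absolute TPM gap by
#' category, and haplotype-bias counts per chromosome pair (mean +/- sd
#' across conditions when several are present).
#'
#' @param ase An `ase_result`.
#' @param pair_divergence Tibble with `gene_a`, `gene_b`, `ka`, `ks`,
#'   `ka_ks`, `chrom_a`, `chrom_b` (e.g. `tidy(allele_set)`).
#' @param tpm TPM matrix.
#' @param design Design tibble.
#' @param dir Optional directory; when given each plot is written there as
#'   SVG.
#' @return Named list of ggplot objects.
#' @export
plot_ase_summaries <- function(ase, pair_divergence, tpm, design, dir = NULL) {
  df <- as_tibble(ase)
  p_cat <- ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                            fill = .data$category)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = NULL, y = "allele pairs", fill = NULL) +
    ggplot2::theme_bw()
  div <- df |>
    inner_join(pair_divergence[, c("gene_a", "gene_b", "ka", "ks", "ka_ks")],
               by = c("gene_a", "gene_b")) |>
    filter(.data$category %in% c("Diff0", "Diff2", "Diff8")) |>
    tidyr::pivot_longer(c("ka", "ks", "ka_ks"), names_to = "statistic",
                        values_to = "value")
  p_div <- ggplot2::ggplot(div, ggplot2::aes(x = .data$category,
                                             y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
  gap_df <- df |> filter(.data$category %in% c("Diff0", "Diff2", "Diff8"))
  gap_df$gap <- abs(mean_tpm(tpm, design, gap_df$gene_a, gap_df$condition) -
                      mean_tpm(tpm, design, gap_df$gene_b, gap_df$condition))
  p_gap <- ggplot2::ggplot(gap_df, ggplot2::aes(x = .data$category,
                                                y = .data$gap)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "|TPM A - TPM B|") +
    ggplot2::theme_bw()
  bias <- haplotype_bias_counts(ase, tpm, design,
                                pair_divergence[, c("gene_a", "gene_b",
                                                    "chrom_a", "chrom_b")]) |>
    tidyr::pivot_longer(c("n_a_higher", "n_b_higher"),
                        names_to = "haplotype", values_to = "n") |>
    mutate(haplotype = ifelse(.data$haplotype == "n_a_higher", "A", "B")) |>
    group_by(.data$chrom_a, .data$chrom_b, .data$haplotype) |>
    summarise(mean_n = mean(.data$n), sd_n = sd(.data$n), .groups = "drop")
  p_bias <- ggplot2::ggplot(bias, ggplot2::aes(x = paste(.data$chrom_a, "/",
                                                         .data$chrom_b),
                                               y = .data$mean_n,
                                               fill = .data$haplotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_n - .data$sd_n,
                                        ymax = .data$mean_n + .data$sd_n),
                           position = "dodge", width = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "pairs with higher-expressed allele",
                  fill = "haplotype") +
    ggplot2::theme_bw()
  plots <- list(categories = p_cat, divergence = p_div, expression_gap = p_gap,
                haplotype_bias = p_bias)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(plots)) {
      ggsave_vector(file.path(dir, paste0("ase_", nm, ".svg")), plots[[nm]],
                    width = 7, height = 5)
    }
  }
  plots
}

#' @rdname test_allele_pairs
#' @param object An `ase_result`.
#' @export
autoplot.ase_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, fill = .data$category)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = NULL, y = "allele pairs", fill = NULL) +
    ggplot2::theme_bw()
}
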