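#' Three-sigma outlier mask
#'
#' Flags values beyond `k` sample standard deviations from the mean
#' (`x < mu - k*sigma` or `x > mu + k*sigma`). The mean and standard
#' deviation (n-1 denominator) are computed over the finite values;
#' non-finite values are never flagged here (saturated estimates are
#' handled upstream). When all values are identical `sigma = 0` and nothing
#' is flagged.
#'
#' @param values Numeric vector; may contain `NA`.
#' @param k Multiplier, default 3.
#' @return Logical mask, `TRUE` = outlier.
#' @export
sigma_mask <- function(values, k = 3) {
  stopifnot(k > 0)
  fin <- is.finite(values)
  if (sum(fin) < 2L) abort("sigma_mask needs at least 2 finite values")
  mu <- mean(values[fin])
  sig <- sd(values[fin])
  out <- fin & (values < mu - k * sig | values > mu + k * sig)
  out[!fin] <- FALSE
  out
}

#' Tukey-fence outlier mask
#'
#' Quartiles Q1 and Q3 are computed by linear interpolation between order
#' statistics at rank `1 + (n-1)p` (R's default quantile convention);
#' `IQR = Q3 - Q1`. Values strictly outside `[Q1 - m*IQR, Q3 + m*IQR]` are
#' flagged, with `m = i` for the inner fence and `m = 2i` for the outer.
#' A smaller `i` narrows the acceptance window (stricter); a larger `i`
#' widens it. When `IQR = 0` the fences collapse to `Q1`, so only values
#' different from `Q1` are flagged.
#'
#' @param values Numeric vector; may contain `NA`.
#' @param i Fence multiplier, default 1.5.
#' @param fence `"inner"` (default) or `"outer"`.
#' @return Logical mask, `TRUE` = outlier.
#' @export
tukey_mask <- function(values, i = 1.5, fence = c("inner", "outer")) {
  stopifnot(i > 0)
  fence <- match.arg(fence)
  fin <- is.finite(values)
  if (sum(fin) < 4L) abort("tukey_mask needs at least 4 finite values")
  q <- unname(quantile(values[fin], c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  m <- if (fence == "inner") i else 2 * i
  out <- fin & (values < q[1] - m * iqr | values > q[2] + m * iqr)
  out[!fin] <- FALSE
  out
}

outlier_mask <- function(values, config) {
  if (config$method == "sigma") sigma_mask(values, config$sigma_k)
  else tukey_mask(values, config$tukey_i, config$fence)
}

#' Filtering configuration
#'
#' @param method Outlier rule for the Ks and slope layers: `"sigma"`
#'   (parametric, suits near-normal Ks distributions) or `"tukey"`
#'   (distribution-free fences, tunable via `tukey_i`).
#' @param sigma_k Sigma multiplier, default 3.
#' @param tukey_i Tukey fence multiplier, default 1.5.
#' @param fence `"inner"` or `"outer"` Tukey fence.
#' @param apply_slope_filter Apply the block-slope layer. Default `TRUE`.
#' @param slope_before_ks Run the slope layer before the Ks mask instead of
#'   after. Default `FALSE` (Ks first).
#' @param min_block_size,max_gap Forwarded to [chain_anchors()].
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(method = c("sigma", "tukey"), sigma_k = 3,
                          tukey_i = 1.5, fence = c("inner", "outer"),
                          apply_slope_filter = TRUE, slope_before_ks = FALSE,
                          min_block_size = 5L, max_gap = 25L) {
  stopifnot(sigma_k > 0, tukey_i > 0)
  structure(list(method = match.arg(method), sigma_k = sigma_k,
                 tukey_i = tukey_i, fence = match.arg(fence),
                 apply_slope_filter = apply_slope_filter,
                 slope_before_ks = slope_before_ks,
                 min_block_size = as.integer(min_block_size),
                 max_gap = as.integer(max_gap)),
            class = "filter_config")
}

#' Remove synteny blocks with aberrant slope
#'
#' Applies the configured outlier mask (same rule and parameters as the Ks
#' layer) to the vector of block slopes. With too few blocks for the rule
#' (fewer than 2 for sigma, 4 for Tukey) nothing is removed and a warning is
#' issued.
#'
#' @param blocks Block tibble from [synteny_blocks()].
#' @param config A [filter_config()].
#' @return `blocks` with a logical `slope_outlier` column.
#' @export
slope_filter <- function(blocks, config = filter_config()) {
  need <- if (config$method == "sigma") 2L else 4L
  if (nrow(blocks) < need) {
    if (nrow(blocks) > 0L) {
      warn(sprintf("only %d block(s): too few for the %s slope filter; none removed",
                   nrow(blocks), config$method))
    }
    blocks$slope_outlier <- rep(FALSE, nrow(blocks))
    return(blocks)
  }
  blocks$slope_outlier <- outlier_mask(blocks$slope, config)
  blocks
}

#' Identify allele pairs between two haplotypes
#'
#' Runs the full identification workflow: reciprocal best hits, rejection of
#' pairs off the corresponding chromosomes, colinearity chaining, Ka/Ks
#' estimation, then the dual statistical layer — an outlier mask on the Ks
#' values of surviving pairs followed by removal of synteny blocks with
#' aberrant slope (order switchable via `config$slope_before_ks`). Pairs
#' whose Ks is saturated cannot pass a Ks filter and are removed and counted
#' separately. Ka is reported but never filtered on.
#'
#' @param genes_a,genes_b Gene-model tibbles (see [build_gene_models()]).
#' @param chromosome_map Tibble `chrom_a`/`chrom_b` of corresponding
#'   chromosomes.
#' @param hits Optional precomputed hit tibble (both directions); when `NULL`
#'   the builtin scorer is used.
#' @param config A [filter_config()].
#' @return Object of class `allele_set`: list with `pairs` (one row per RBH
#'   pair with its `status`), `report` (per-stage retained/removed counts),
#'   `blocks`, `anchors`, and `config`. `tidy()` returns the pair table,
#'   `glance()` the one-row report, `autoplot()` the colinearity dot plot.
#' @export
identify_alleles <- function(genes_a, genes_b, chromosome_map, hits = NULL,
                             config = filter_config()) {
  chromosome_map <- validate_chromosome_map(chromosome_map)
  if (is.null(hits)) hits <- score_all_vs_all(genes_a, genes_b, mode = "builtin")
  gene_index <- bind_rows(genes_a[, c("gene_id", "haplotype", "chromosome")],
                          genes_b[, c("gene_id", "haplotype", "chromosome")])
  rbh <- find_rbh(hits, chromosome_map, gene_index)

  pairs <- rbh |>
    mutate(status = ifelse(.data$same_chrom_pair, NA_character_,
                           "rejected_cross_chrom"))

  anchors <- make_anchors(rbh, genes_a, genes_b) |>
    chain_anchors(config$min_block_size, config$max_gap)
  blocks <- synteny_blocks(anchors)
  pairs <- pairs |>
    left_join(anchors[, c("gene_a", "gene_b", "block_id", "rank_a", "rank_b",
                          "mid_a", "mid_b")],
              by = c("gene_a", "gene_b")) |>
    mutate(status = case_when(
      !is.na(.data$status) ~ .data$status,
      is.na(.data$block_id) ~ "rejected_non_colinear",
      TRUE ~ NA_character_))

  alive <- is.na(pairs$status)
  div <- pair_divergence(pairs[alive, c("gene_a", "gene_b")], genes_a, genes_b)
  pairs$ka <- pairs$ks <- pairs$ka_ks <- NA_real_
  pairs$ka[alive] <- div$ka
  pairs$ks[alive] <- div$ks
  pairs$ka_ks[alive] <- div$ka_ks
  pairs$status[which(alive)[div$saturated_ks | div$too_short]] <- "rejected_saturated"

  ks_layer <- function(pairs) {
    alive <- is.na(pairs$status)
    if (sum(alive) >= if (config$method == "sigma") 2L else 4L) {
      out <- outlier_mask(pairs$ks[alive], config)
      pairs$status[which(alive)[out]] <- "rejected_ks_outlier"
    } else if (any(alive)) {
      warn("too few pairs for the Ks outlier mask; none removed")
    }
    pairs
  }
  slope_layer <- function(pairs, blocks) {
    if (!config$apply_slope_filter) {
      blocks$slope_outlier <- rep(FALSE, nrow(blocks))
      return(list(pairs = pairs, blocks = blocks))
    }
    blocks <- slope_filter(blocks, config)
    bad_blocks <- blocks$block_id[blocks$slope_outlier]
    hit <- is.na(pairs$status) & !is.na(pairs$block_id) &
      pairs$block_id %in% bad_blocks
    pairs$status[hit] <- "rejected_slope"
    list(pairs = pairs, blocks = blocks)
  }
  if (config$slope_before_ks) {
    res <- slope_layer(pairs, blocks)
    pairs <- ks_layer(res$pairs)
    blocks <- res$blocks
  } else {
    pairs <- ks_layer(pairs)
    res <- slope_layer(pairs, blocks)
    pairs <- res$pairs
    blocks <- res$blocks
  }
  pairs$status[is.na(pairs$status)] <- "allele"
  pairs$status <- factor(pairs$status, levels = c(
    "allele", "rejected_cross_chrom", "rejected_non_colinear",
    "rejected_saturated", "rejected_ks_outlier", "rejected_slope"))

  removal_order <- c("rejected_cross_chrom", "rejected_non_colinear",
                     "rejected_saturated",
                     if (config$slope_before_ks) c("rejected_slope", "rejected_ks_outlier")
                     else c("rejected_ks_outlier", "rejected_slope"))
  stage_names <- c("same_chromosome", "colinear", "ks_estimable",
                   if (config$slope_before_ks) c("slope_filtered", "ks_filtered")
                   else c("ks_filtered", "slope_filtered"))
  removed <- vapply(removal_order, function(s) sum(pairs$status == s), integer(1))
  report <- tibble(
    stage = c("rbh", stage_names),
    retained = nrow(pairs) - unname(cumsum(c(0L, removed))),
    removed = c(0L, unname(removed))
  )

  structure(list(pairs = select(pairs, -"same_chrom_pair"),
                 report = report, blocks = blocks, anchors = anchors,
                 config = config,
                 n_saturated_removed = sum(pairs$status == "rejected_saturated")),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat("<allele_set>\n")
  cat(sprintf("  %d RBH pairs -> %d alleles (method %s)\n",
              nrow(x$pairs), sum(x$pairs$status == "allele"), x$config$method))
  print(x$report)
  invisible(x)
}

#' @rdname identify_alleles
#' @param x An `allele_set`.
#' @param ... Unused.
#' @export
tidy.allele_set <- function(x, ...) {
  x$pairs
}

#' @rdname identify_alleles
#' @export
glance.allele_set <- function(x, ...) {
  st <- x$pairs$status
  tibble(
    n_rbh = length(st),
    n_same_chrom = sum(st != "rejected_cross_chrom"),
    n_colinear = sum(!st %in% c("rejected_cross_chrom", "rejected_non_colinear")),
    n_saturated_removed = sum(st == "rejected_saturated"),
    n_ks_removed = sum(st == "rejected_ks_outlier"),
    n_after_ks = sum(st %in% c("allele", "rejected_slope")),
    n_slope_removed = sum(st == "rejected_slope"),
    n_alleles = sum(st == "allele"),
    method = x$config$method,
    sigma_k = x$config$sigma_k,
    tukey_i = x$config$tukey_i,
    fence = x$config$fence
  )
}

#' Write the tables of an allele set to a directory
#'
#' Writes `allele_pairs.tsv`, `filter_report.tsv`, `blocks.tsv`,
#' `anchors.tsv` and a `run_metadata.txt` echoing the configuration.
#'
#' @param x An `allele_set`.
#' @param dir Output directory (created if needed).
#' @param seed Optional seed to echo into the metadata.
#' @return Invisibly, `dir`.
#' @export
write_allele_set <- function(x, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(x$pairs, file.path(dir, "allele_pairs.tsv"))
  readr::write_tsv(x$report, file.path(dir, "filter_report.tsv"))
  readr::write_tsv(x$blocks, file.path(dir, "blocks.tsv"))
  readr::write_tsv(mutate(x$anchors, block_id = ifelse(is.na(.data$block_id),
                                                       "none", .data$block_id)),
                   file.path(dir, "anchors.tsv"))
  write_run_metadata(dir, c(unclass(x$config)), seed = seed)
  invisible(dir)
}
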