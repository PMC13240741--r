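#' Build synteny anchors from RBH pairs
#'
#' Each RBH pair on a corresponding chromosome pair becomes an anchor with
#' the gene-order rank of each gene on its chromosome (rank of the start
#' coordinate, robust to gene length) and the bp midpoint (kept for dot
#' plots). Ranks are computed over all genes of the haplotype, not just
#' anchored ones.
#'
#' @param rbh RBH tibble from [find_rbh()].
#' @param genes_a,genes_b Gene-model tibbles.
#' @return Tibble: `gene_a`, `gene_b`, `chrom_a`, `chrom_b`, `rank_a`,
#'   `rank_b`, `mid_a`, `mid_b`; only pairs with `same_chrom_pair = TRUE`.
#' @export
make_anchors <- function(rbh, genes_a, genes_b) {
  pos <- function(genes) {
    genes |>
      group_by(.data$chromosome) |>
      mutate(rank = rank(.data$start, ties.method = "first"),
             mid = (.data$start + .data$end) / 2) |>
      ungroup() |>
      select("gene_id", "rank", "mid")
  }
  rbh |>
    filter(.data$same_chrom_pair) |>
    left_join(rename(pos(genes_a), rank_a = "rank", mid_a = "mid"),
              by = c(gene_a = "gene_id")) |>
    left_join(rename(pos(genes_b), rank_b = "rank", mid_b = "mid"),
              by = c(gene_b = "gene_id")) |>
    select("gene_a", "gene_b", "chrom_a", "chrom_b",
           "rank_a", "rank_b", "mid_a", "mid_b")
}

#' Chain anchors into colinear synteny blocks
#'
#' Within each corresponding chromosome pair, anchors are chained by a
#' weighted longest-increasing/decreasing-subsequence dynamic program:
#' anchor j may follow i iff `0 < rank_a(j) - rank_a(i) <= max_gap` and
#' `0 < |rank_b(j) - rank_b(i)| <= max_gap` with a consistent sign along the
#' chain. The highest-scoring (longest) chain is extracted first, its anchors
#' removed, and the program repeated, so each anchor belongs to at most one
#' block; chains shorter than `min_block_size` are discarded and their
#' anchors marked non-colinear (`block_id` NA).
#'
#' @param anchors Anchor tibble from [make_anchors()].
#' @param min_block_size Minimum anchors per block. Default 5.
#' @param max_gap Maximum rank gap between consecutive anchors. Default 25.
#' @return The anchor tibble with a `block_id` column (`NA` = non-colinear),
#'   independent of input row order.
#' @export
chain_anchors <- function(anchors, min_block_size = 5L, max_gap = 25L) {
  anchors <- arrange(anchors, .data$chrom_a, .data$chrom_b,
                     .data$rank_a, .data$rank_b)
  anchors$block_id <- NA_character_
  n_block <- 0L
  for (grp in split(seq_len(nrow(anchors)),
                    paste(anchors$chrom_a, anchors$chrom_b))[
                      unique(paste(anchors$chrom_a, anchors$chrom_b))]) {
    free <- grp
    repeat {
      if (length(free) < min_block_size) break
      chain <- best_chain(anchors$rank_a[free], anchors$rank_b[free], max_gap)
      if (length(chain) < min_block_size) break
      n_block <- n_block + 1L
      anchors$block_id[free[chain]] <- sprintf("blk%04d", n_block)
      free <- free[-chain]
    }
  }
  anchors
}

# best chain among anchors sorted by rank_a; returns indices into ra/rb.
# Forward and inverted chains are scored separately, the longer one wins
# (forward on a tie).
best_chain <- function(ra, rb, max_gap) {
  n <- length(ra)
  run <- function(sign) {
    dp <- rep(1L, n)
    prev <- rep(NA_integer_, n)
    for (j in seq_len(n)) {
      da <- ra[j] - ra
      db <- sign * (rb[j] - rb)
      ok <- which(da > 0L & da <= max_gap & db > 0L & db <= max_gap)
      if (length(ok) > 0L) {
        i <- ok[which.max(dp[ok])]
        dp[j] <- dp[i] + 1L
        prev[j] <- i
      }
    }
    list(dp = dp, prev = prev)
  }
  fwd <- run(1L)
  inv <- run(-1L)
  use <- if (max(inv$dp) > max(fwd$dp)) inv else fwd
  j <- which.max(use$dp)
  chain <- integer(use$dp[j])
  for (k in rev(seq_along(chain))) {
    chain[k] <- j
    j <- use$prev[j]
  }
  chain
}

#' Summarise synteny blocks
#'
#' @param anchors Anchor tibble with `block_id` (from [chain_anchors()]).
#' @return One row per block: `block_id`, `chrom_a`, `chrom_b`, `n_anchors`,
#'   `orientation` (`forward`/`inverted`), `slope` (OLS of `rank_b` on
#'   `rank_a`).
#' @export
synteny_blocks <- function(anchors) {
  if (sum(!is.na(anchors$block_id)) == 0L) {
    return(tibble(block_id = character(), chrom_a = character(),
                  chrom_b = character(), n_anchors = integer(),
                  orientation = character(), slope = numeric()))
  }
  anchors |>
    filter(!is.na(.data$block_id)) |>
    group_by(.data$block_id, .data$chrom_a, .data$chrom_b) |>
    summarise(n_anchors = n(),
              slope = block_slope(.data$rank_a, .data$rank_b),
              .groups = "drop") |>
    mutate(orientation = ifelse(.data$slope < 0, "inverted", "forward")) |>
    select("block_id", "chrom_a", "chrom_b", "n_anchors", "orientation", "slope") |>
    arrange(.data$block_id)
}

#' Ordinary-least-squares slope of a block
#'
#' Slope of `rank_b` regressed on `rank_a`; for perfectly colinear 1:1
#' blocks this is +1 (forward) or -1 (inverted) regardless of gene density.
#'
#' @param rank_a,rank_b Anchor gene-order ranks (length >= 2).
#' @return The OLS slope.
#' @export
block_slope <- function(rank_a, rank_b) {
  if (length(rank_a) < 2L) abort("block slope needs at least 2 anchors")
  sum((rank_a - mean(rank_a)) * (rank_b - mean(rank_b))) /
    sum((rank_a - mean(rank_a))^2)
}
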