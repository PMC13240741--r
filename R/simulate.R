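#' Simulation configuration
#'
#' Defaults describe the reference validation scenario used throughout the
#' package: a diploid with two corresponding chromosome pairs of 1000 genes
#' each, allelic synonymous divergence drawn from Normal(0.03, 0.01) —
#' typical of a heterozygous outcrossing plant — 100 paralog decoys with Ks
#' in \[0.3, 1\] emulating retained duplicates from ancient whole-genome or
#' segmental duplication, and one 50-gene inversion between the haplotypes.
#'
#' @param n_chrom_pairs Corresponding chromosome pairs. Default 2.
#' @param genes_per_chrom Genes per chromosome. Default 1000.
#' @param allelic_ks_mean,allelic_ks_sd Target allelic Ks distribution.
#'   Defaults 0.03 and 0.01.
#' @param ka_ks_ratio Target Ka/Ks of simulated pairs (purifying selection).
#'   Default 0.3.
#' @param n_paralogs Paralog decoys replacing true haplotype-B alleles.
#'   Default 100.
#' @param paralog_ks_range Ks range of decoys. Default `c(0.3, 1)`.
#' @param n_inversions Contiguous gene runs reversed on haplotype B.
#'   Default 1.
#' @param inversion_length Genes per inversion. Default 50.
#' @param gene_length_codons Range of gene lengths in codons.
#'   Default `c(100, 300)`.
#' @param n_conditions,reps_per_condition Expression design. Defaults 1, 3.
#' @param base_mean Mean of the expression base-mean distribution
#'   (log-normal). Default 100.
#' @param base_mean_sdlog Log-sd of base means; 0 = constant. Default 0.
#' @param dispersion Negative-binomial dispersion. Default 0.1.
#' @param fraction_ase Fraction of allelic pairs with a true expression
#'   shift on allele A. Default 0.
#' @param ase_log2fc Magnitude of the true log2 fold change (random sign).
#'   Default 4.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chrom_pairs = 2L, genes_per_chrom = 1000L,
                       allelic_ks_mean = 0.03, allelic_ks_sd = 0.01,
                       ka_ks_ratio = 0.3, n_paralogs = 100L,
                       paralog_ks_range = c(0.3, 1), n_inversions = 1L,
                       inversion_length = 50L,
                       gene_length_codons = c(100L, 300L),
                       n_conditions = 1L, reps_per_condition = 3L,
                       base_mean = 100, base_mean_sdlog = 0,
                       dispersion = 0.1, fraction_ase = 0, ase_log2fc = 4) {
  cfg <- as.list(environment())
  if (cfg$n_paralogs > cfg$n_chrom_pairs * cfg$genes_per_chrom) {
    abort("more paralogs requested than genes simulated")
  }
  structure(cfg, class = "sim_config")
}

# codon-aware mutation toward target synonymous / non-synonymous divergence.
# The number of changed codons is the expected count p * (available sites),
# allocated by weighted sampling without replacement rather than per-codon
# Bernoulli draws: this keeps the realized per-gene NG86 p-distances tight
# around the Jukes-Cantor-inverted targets, so the realized Ks distribution
# across genes tracks the drawn (near-normal) target distribution instead of
# being broadened and right-skewed by counting noise
mutate_codons <- function(codons, ks, ka) {
  tab <- codon_tables()
  p_syn <- 0.75 * (1 - exp(-4 * ks / 3))
  p_non <- 0.75 * (1 - exp(-4 * ka / 3))
  pick_one <- function(nbs) nbs[[sample.int(length(nbs), 1L)]]
  # non-synonymous changes first (synonymous sites are re-read afterwards)
  n_w <- 3 - tab$syn_sites[codons]
  m_n <- min(round(p_non * sum(n_w)), sum(n_w > 0))
  if (m_n > 0L) {
    pick <- sample.int(length(codons), m_n, prob = n_w)
    codons[pick] <- vapply(codons[pick], function(cod) {
      pick_one(tab$nonsyn_neighbours[[cod]])
    }, character(1))
  }
  s_w <- tab$syn_sites[codons]
  s_w[lengths(tab$syn_neighbours[codons]) == 0L] <- 0
  m_s <- min(round(p_syn * sum(s_w)), sum(s_w > 0))
  if (m_s > 0L) {
    pick <- sample.int(length(codons), m_s, prob = s_w)
    codons[pick] <- vapply(codons[pick], function(cod) {
      pick_one(tab$syn_neighbours[[cod]])
    }, character(1))
  }
  codons
}

random_cds <- function(n_codons) {
  tab <- codon_tables()
  body <- setdiff(tab$sense, c("ATG"))
  paste0("ATG", paste0(sample(body, n_codons - 1L, replace = TRUE),
                       collapse = ""))
}

#' Simulate a truth-labelled diploid gene complement
#'
#' Builds an ancestral gene set, derives haplotype B from haplotype A by
#' codon-aware mutation calibrated to the target allelic Ks, then plants
#' paralog decoys: for each chosen donor gene the true haplotype-B allele is
#' replaced by a heavily diverged duplicate of the donor inserted at a
#' random position on the corresponding B chromosome, so reciprocal-best-hit
#' search genuinely mis-pairs donor and decoy — the failure mode the
#' statistical filters exist to remove. Optionally, contiguous runs of genes
#' on B are inverted.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the simulation is fully reproducible.
#' @return List of class `diploid_sim`: `genes_a`, `genes_b` (gene-model
#'   tibbles), `chromosome_map`, and `truth` (tibble `gene_a`, `gene_b`,
#'   `label` in `allelic`/`paralog`).
#' @export
simulate_diploid <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  n_genes <- cfg$n_chrom_pairs * cfg$genes_per_chrom
  chrom_a <- rep(sprintf("chrA%02d", seq_len(cfg$n_chrom_pairs)),
                 each = cfg$genes_per_chrom)
  chrom_b <- sub("chrA", "chrB", chrom_a)
  lens <- sample(seq(cfg$gene_length_codons[1], cfg$gene_length_codons[2]),
                 n_genes, replace = TRUE)
  cds_a <- vapply(lens, random_cds, character(1))
  ks <- pmax(rnorm(n_genes, cfg$allelic_ks_mean, cfg$allelic_ks_sd), 1e-4)
  cds_b <- vapply(seq_len(n_genes), function(i) {
    paste0(mutate_codons(split_codons(cds_a[i]), ks[i],
                         ks[i] * cfg$ka_ks_ratio), collapse = "")
  }, character(1))

  ids_a <- sprintf("gA_%s_%04d", chrom_a, sequence(rep(cfg$genes_per_chrom,
                                                       cfg$n_chrom_pairs)))
  ids_b <- sub("gA_chrA", "gB_chrB", ids_a)
  truth <- tibble(gene_a = ids_a, gene_b = ids_b, label = "allelic")

  # haplotype-B gene order, one list of (id, cds) per chromosome
  b_order <- split(seq_len(n_genes), chrom_b)

  # paralog decoys: replace the true B allele of each donor with a heavily
  # mutated duplicate of the donor at a random position on the same B chrom
  if (cfg$n_paralogs > 0L) {
    donors <- sort(sample.int(n_genes, cfg$n_paralogs))
    par_ks <- runif(cfg$n_paralogs, cfg$paralog_ks_range[1], cfg$paralog_ks_range[2])
    for (k in seq_along(donors)) {
      i <- donors[k]
      cds_b[i] <- paste0(mutate_codons(split_codons(cds_a[i]), par_ks[k],
                                       par_ks[k] * cfg$ka_ks_ratio),
                         collapse = "")
      ids_b[i] <- sub("^gB", "pB", ids_b[i])
      ord <- b_order[[chrom_b[i]]]
      pos_old <- which(ord == i)
      pos_new <- sample(setdiff(seq_along(ord), pos_old), 1L)
      b_order[[chrom_b[i]]] <- append(ord[-pos_old], i,
                                      after = pos_new - (pos_new > pos_old))
    }
    truth$gene_b[donors] <- ids_b[donors]
    truth$label[donors] <- "paralog"
  }

  # inversions: reverse contiguous runs of the B gene order
  if (cfg$n_inversions > 0L) {
    for (chr in sample(names(b_order), cfg$n_inversions,
                       replace = cfg$n_inversions > length(b_order))) {
      ord <- b_order[[chr]]
      len <- min(cfg$inversion_length, length(ord))
      s <- sample.int(length(ord) - len + 1L, 1L)
      ord[s:(s + len - 1L)] <- rev(ord[s:(s + len - 1L)])
      b_order[[chr]] <- ord
    }
  }

  layout <- function(ids, cds, chrom) {
    gaps <- sample(500:2000, length(ids), replace = TRUE)
    widths <- nchar(cds)
    start <- cumsum(gaps) + c(0L, cumsum(widths))[seq_along(ids)]
    tibble(gene_id = ids, chromosome = chrom, start = start,
           end = start + widths - 1L,
           strand = sample(c("+", "-"), length(ids), replace = TRUE),
           cds = cds, protein = translate_cds(cds))
  }
  genes_a <- layout(ids_a, cds_a, chrom_a) |> mutate(haplotype = "A")
  ord_b <- unlist(b_order[unique(chrom_b)], use.names = FALSE)
  genes_b <- layout(ids_b[ord_b], cds_b[ord_b], chrom_b[ord_b]) |>
    mutate(haplotype = "B")
  cols <- c("gene_id", "haplotype", "chromosome", "start", "end", "strand",
            "cds", "protein")
  structure(list(
    genes_a = genes_a[, cols], genes_b = genes_b[, cols],
    chromosome_map = tibble(chrom_a = sprintf("chrA%02d", seq_len(cfg$n_chrom_pairs)),
                            chrom_b = sprintf("chrB%02d", seq_len(cfg$n_chrom_pairs))),
    truth = truth, config = cfg, seed = seed
  ), class = "diploid_sim")
}

#' Write a simulated diploid to disk
#'
#' Writes the exact file set the identification step consumes: per-haplotype
#' GFF3 + CDS/protein FASTA, the chromosome map, and `truth.tsv`.
#'
#' @param sim A `diploid_sim`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_models(sim$genes_a, file.path(dir, "hapA"))
  write_gene_models(sim$genes_b, file.path(dir, "hapB"))
  readr::write_tsv(sim$chromosome_map, file.path(dir, "chrom_map.tsv"),
                   col_names = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Simulate replicate count matrices for the allele pairs
#'
#' Counts are negative-binomial with a per-pair base mean; a fraction of
#' allelic pairs receive a true expression shift by multiplying the
#' haplotype-A allele's mean by `2^l2fc` with `l2fc = +/- ase_log2fc`.
#' Paralog-decoy pairs are simulated like non-ASE pairs.
#'
#' @param sim A `diploid_sim`.
#' @param seed Integer seed.
#' @return List: `counts` (matrix genes x samples), `design` tibble,
#'   `gene_lengths`, and `truth_expression` (per pair: `base_mean`,
#'   `is_ase`, `l2fc`, per-allele means).
#' @export
simulate_counts <- function(sim, seed = 1L) {
  set.seed(seed + 1e6L)
  cfg <- sim$config
  truth <- sim$truth
  n_pairs <- nrow(truth)
  base <- if (cfg$base_mean_sdlog > 0) {
    rlnorm(n_pairs, log(cfg$base_mean), cfg$base_mean_sdlog)
  } else rep(cfg$base_mean, n_pairs)
  is_ase <- runif(n_pairs) < cfg$fraction_ase & truth$label == "allelic"
  l2fc <- ifelse(is_ase, sample(c(-1, 1), n_pairs, replace = TRUE) * cfg$ase_log2fc, 0)
  mean_a <- base * 2^l2fc
  mean_b <- base
  design <- tibble(
    sample_id = sprintf("cond%02d_rep%d",
                        rep(seq_len(cfg$n_conditions), each = cfg$reps_per_condition),
                        rep(seq_len(cfg$reps_per_condition), cfg$n_conditions)),
    condition = sprintf("cond%02d",
                        rep(seq_len(cfg$n_conditions), each = cfg$reps_per_condition))
  )
  n_samp <- nrow(design)
  draw <- function(mu) {
    t(vapply(mu, function(m) rnbinom(n_samp, mu = m, size = 1 / cfg$dispersion),
             numeric(n_samp)))
  }
  counts <- rbind(draw(mean_a), draw(mean_b))
  rownames(counts) <- c(truth$gene_a, truth$gene_b)
  colnames(counts) <- design$sample_id
  lens <- setNames(c(nchar(sim$genes_a$cds)[match(truth$gene_a, sim$genes_a$gene_id)],
                     nchar(sim$genes_b$cds)[match(truth$gene_b, sim$genes_b$gene_id)]),
                   rownames(counts))
  list(counts = counts, design = design, gene_lengths = lens,
       truth_expression = tibble(gene_a = truth$gene_a, gene_b = truth$gene_b,
                                 base_mean = base, is_ase = is_ase,
                                 l2fc = l2fc, mean_a = mean_a, mean_b = mean_b))
}
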