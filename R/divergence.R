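# Codon bookkeeping for the NG86 estimator ----------------------------------
#
# All per-codon quantities are precomputed once and cached: synonymous site
# counts per sense codon, and for every ordered pair of sense codons the
# pathway-averaged synonymous / non-synonymous difference counts.

BASES <- c("A", "C", "G", "T")

codon_tables <- function() {
  if (!is.null(the$codon)) return(the$codon)
  codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  code <- Biostrings::GENETIC_CODE[codons]
  is_stop <- code == "*"
  sense <- codons[!is_stop]

  # synonymous sites per codon: at each position, the fraction of the three
  # single-base changes that are synonymous; changes creating a stop codon
  # are excluded from the denominator
  syn_sites <- setNames(numeric(length(codons)), codons)
  neighbours <- function(codon, pos) {
    alt <- setdiff(BASES, substr(codon, pos, pos))
    vapply(alt, function(b) `substr<-`(codon, pos, pos, b), character(1))
  }
  for (cod in sense) {
    s <- 0
    for (pos in 1:3) {
      nb <- neighbours(cod, pos)
      nb <- nb[Biostrings::GENETIC_CODE[nb] != "*"]
      if (length(nb) > 0L) {
        s <- s + sum(Biostrings::GENETIC_CODE[nb] == code[cod]) / length(nb)
      }
    }
    syn_sites[cod] <- s
  }

  # pathway-averaged Sd / Nd contributions for every sense-codon pair
  perms <- list(list(1L), list(c(1L, 2L), c(2L, 1L)),
                list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  ns <- length(sense)
  sd_mat <- matrix(0, ns, ns, dimnames = list(sense, sense))
  nd_mat <- sd_mat
  step_syn <- function(from, to) Biostrings::GENETIC_CODE[from] == Biostrings::GENETIC_CODE[to]
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i == j) next
      x <- sense[i]; y <- sense[j]
      diffpos <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
      paths <- perms[[length(diffpos)]]
      tot_s <- 0; tot_n <- 0; n_valid <- 0L
      for (ord in paths) {
        cur <- x; s <- 0; n <- 0; valid <- TRUE
        for (p in diffpos[ord]) {
          nxt <- `substr<-`(cur, p, p, substr(y, p, p))
          if (Biostrings::GENETIC_CODE[nxt] == "*") { valid <- FALSE; break }
          if (step_syn(cur, nxt)) s <- s + 1 else n <- n + 1
          cur <- nxt
        }
        if (valid) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_valid <- n_valid + 1L }
      }
      if (n_valid > 0L) {
        sd_mat[i, j] <- tot_s / n_valid
        nd_mat[i, j] <- tot_n / n_valid
      } else {
        # every pathway passes through a stop codon: fall back to classifying
        # each differing position by its direct single-base change, averaged
        # over the two codon contexts that yield sense codons
        for (p in diffpos) {
          cls <- c()
          xa <- `substr<-`(x, p, p, substr(y, p, p))
          if (Biostrings::GENETIC_CODE[xa] != "*") cls <- c(cls, step_syn(x, xa))
          yb <- `substr<-`(y, p, p, substr(x, p, p))
          if (Biostrings::GENETIC_CODE[yb] != "*") cls <- c(cls, step_syn(y, yb))
          if (length(cls) > 0L) {
            sd_mat[i, j] <- sd_mat[i, j] + mean(cls)
            nd_mat[i, j] <- nd_mat[i, j] + mean(!cls)
          }
        }
      }
    }
  }
  # synonymous single-base sense neighbours per sense codon (used by the
  # simulator's codon-aware mutation process)
  syn_nb <- lapply(sense, function(cod) {
    nb <- unlist(lapply(1:3, neighbours, codon = cod))
    nb[Biostrings::GENETIC_CODE[nb] == code[cod]]
  })
  non_nb <- lapply(sense, function(cod) {
    nb <- unlist(lapply(1:3, neighbours, codon = cod))
    nb[Biostrings::GENETIC_CODE[nb] != "*" & Biostrings::GENETIC_CODE[nb] != code[cod]]
  })
  the$codon <- list(codons = codons, sense = sense, is_stop = is_stop,
                    syn_sites = syn_sites, sd_mat = sd_mat, nd_mat = nd_mat,
                    syn_neighbours = setNames(syn_nb, sense),
                    nonsyn_neighbours = setNames(non_nb, sense))
  the$codon
}

split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Codon-align two coding sequences via their proteins
#'
#' Globally aligns the two proteins (BLOSUM62, affine gaps) and
#' back-translates the alignment to codons. Columns containing a gap, an
#' ambiguous base, or a stop codon in either sequence are dropped and
#' counted.
#'
#' @param cds_a,cds_b Coding sequences, lengths divisible by 3.
#' @param protein_a,protein_b Optional proteins; translated from the CDS when
#'   omitted, validated against it when supplied.
#' @return Object of class `codon_alignment`: list with `codons_a`,
#'   `codons_b` (equal-length codon vectors), `n_codons`, `n_dropped`.
#' @export
align_codons <- function(cds_a, cds_b, protein_a = NULL, protein_b = NULL) {
  check <- function(cds, prot) {
    if (nchar(cds) %% 3L != 0L) abort("CDS length not divisible by 3")
    tr <- translate_cds(cds)
    if (!is.null(prot) && toupper(sub("\\*$", "", prot)) != tr) {
      abort("CDS does not translate to the supplied protein")
    }
    tr
  }
  pa <- check(cds_a, protein_a)
  pb <- check(cds_b, protein_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  backtranslate_alignment(as.character(Biostrings::alignedPattern(aln)),
                          as.character(Biostrings::alignedSubject(aln)),
                          cds_a, cds_b)
}

backtranslate_alignment <- function(aln_a, aln_b, cds_a, cds_b) {
  cha <- strsplit(aln_a, "")[[1]]
  chb <- strsplit(aln_b, "")[[1]]
  cod_a <- split_codons(cds_a)
  cod_b <- split_codons(cds_b)
  ia <- cumsum(cha != "-")
  ib <- cumsum(chb != "-")
  keep <- cha != "-" & chb != "-"
  ca <- cod_a[ia[keep]]
  cb <- cod_b[ib[keep]]
  tab <- codon_tables()
  ok <- ca %in% tab$sense & cb %in% tab$sense  # drops ambiguity and stops
  structure(list(codons_a = ca[ok], codons_b = cb[ok],
                 n_codons = sum(ok), n_dropped = length(cha) - sum(ok)),
            class = "codon_alignment")
}

#' Nei–Gojobori (NG86) divergence estimate for a codon alignment
#'
#' Synonymous site counts use the stop-excluded denominator convention;
#' observed synonymous/non-synonymous differences average equally over all
#' minimal substitution pathways between differing codons, excluding
#' pathways through stop codons. Proportions are corrected with the
#' Jukes–Cantor formula `d = -(3/4) log(1 - 4p/3)`; a proportion at or above
#' 3/4 is flagged saturated and the corresponding rate left undefined.
#'
#' @param alignment A `codon_alignment` from [align_codons()].
#' @return One-row tibble: `ka`, `ks`, `ka_ks`, `s_sites`, `n_sites`, `sd`,
#'   `nd`, `n_codons`, `n_dropped`, and logical flags `saturated_ka`,
#'   `saturated_ks`, `too_short`. Undefined values are `NA`.
#' @export
ng86 <- function(alignment) {
  tab <- codon_tables()
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  if (length(ca) == 0L) {
    return(tibble(ka = NA_real_, ks = NA_real_, ka_ks = NA_real_,
                  s_sites = NA_real_, n_sites = NA_real_, sd = NA_real_,
                  nd = NA_real_, n_codons = 0L, n_dropped = alignment$n_dropped,
                  saturated_ka = FALSE, saturated_ks = FALSE, too_short = TRUE))
  }
  s_sites <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  n_sites <- 3 * length(ca) - s_sites
  idx <- cbind(match(ca, tab$sense), match(cb, tab$sense))
  sd_obs <- sum(tab$sd_mat[idx])
  nd_obs <- sum(tab$nd_mat[idx])
  ps <- sd_obs / s_sites
  pn <- nd_obs / n_sites
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  ks <- jc(ps)
  ka <- jc(pn)
  tibble(ka = ka, ks = ks,
         ka_ks = if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_,
         s_sites = s_sites, n_sites = n_sites, sd = sd_obs, nd = nd_obs,
         n_codons = length(ca), n_dropped = alignment$n_dropped,
         saturated_ka = is.na(ka), saturated_ks = is.na(ks),
         too_short = FALSE)
}

#' Ka/Ks for a table of gene pairs
#'
#' Codon-aligns and scores every pair with [align_codons()] + [ng86()].
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @param genes_a,genes_b Gene-model tibbles supplying `cds` per gene id.
#' @return `pairs` with the [ng86()] columns appended.
#' @export
pair_divergence <- function(pairs, genes_a, genes_b) {
  if (nrow(pairs) == 0L) {
    return(bind_cols(pairs, ng86(structure(list(codons_a = character(),
                                                codons_b = character(),
                                                n_codons = 0L, n_dropped = 0L),
                                           class = "codon_alignment"))[0, ]))
  }
  cds_a <- setNames(genes_a$cds, genes_a$gene_id)[pairs$gene_a]
  cds_b <- setNames(genes_b$cds, genes_b$gene_id)[pairs$gene_b]
  prot_a <- translate_cds(cds_a)
  prot_b <- translate_cds(cds_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(prot_a), Biostrings::AAStringSet(prot_b),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  est <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    ng86(backtranslate_alignment(pat[i], sub[i], cds_a[i], cds_b[i]))
  })
  bind_cols(pairs, est)
}
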