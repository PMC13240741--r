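#' All-vs-all protein similarity between haplotypes
#'
#' Builtin mode computes local pairwise protein alignment scores (BLOSUM62,
#' affine gaps) over a candidate set prefiltered by shared amino-acid k-mers;
#' every scored ordered pair is emitted in both directions with the same
#' score, giving one-best-alignment semantics per pair. Import mode reads a
#' user-supplied 12-column tabular hit file (e.g. from an external aligner).
#'
#' @param genes_a,genes_b Gene-model tibbles for haplotypes A and B.
#' @param mode `"builtin"` or `"import"`.
#' @param hits_path Path to the tabular hit file (import mode).
#' @param kmer K-mer length for the candidate prefilter. Default 5.
#' @param prefilter_min_n Candidate prefiltering is skipped when both sets
#'   have at most this many proteins (all pairs are aligned). Default 50.
#' @return Tibble of hits: `query_id`, `subject_id`, `identity_pct`,
#'   `alignment_length`, `evalue`, `bit_score`.
#' @export
score_all_vs_all <- function(genes_a, genes_b, mode = c("builtin", "import"),
                             hits_path = NULL, kmer = 5L, prefilter_min_n = 50L) {
  mode <- match.arg(mode)
  if (nrow(genes_a) == 0L || nrow(genes_b) == 0L) abort("empty protein set")
  if (mode == "import") {
    hits <- read_hits(hits_path)
    known <- c(genes_a$gene_id, genes_b$gene_id)
    unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), known)
    if (length(unknown) > 0L) {
      abort(paste0("hit file references unknown gene ids: ",
                   paste(head(unknown, 10L), collapse = ", ")))
    }
    return(hits)
  }
  pa <- setNames(genes_a$protein, genes_a$gene_id)
  pb <- setNames(genes_b$protein, genes_b$gene_id)
  if (length(pa) <= prefilter_min_n && length(pb) <= prefilter_min_n) {
    cand <- expand.grid(ia = seq_along(pa), ib = seq_along(pb))
  } else {
    cand <- kmer_candidates(pa, pb, kmer)
  }
  if (nrow(cand) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  identity_pct = numeric(), alignment_length = integer(),
                  evalue = numeric(), bit_score = numeric()))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(pa[cand$ia]), Biostrings::AAStringSet(pb[cand$ib]),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "local")
  sc <- Biostrings::score(aln)
  pid <- Biostrings::pid(aln)
  len <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  fwd <- tibble(query_id = names(pa)[cand$ia], subject_id = names(pb)[cand$ib],
                identity_pct = pid, alignment_length = as.integer(len),
                evalue = 0, bit_score = sc)
  rev <- fwd
  rev$query_id <- fwd$subject_id
  rev$subject_id <- fwd$query_id
  out <- bind_rows(fwd, rev)
  out[out$bit_score > 0, , drop = FALSE]
}

blosum62 <- function() {
  if (is.null(the$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    the$blosum62 <- e$BLOSUM62
  }
  the$blosum62
}

# candidate ordered pairs (indices into a, b) sharing at least one k-mer
kmer_candidates <- function(pa, pb, k) {
  kmers <- function(seqs) {
    n <- nchar(seqs)
    idx <- rep.int(seq_along(seqs), pmax(n - k + 1L, 0L))
    starts <- unlist(lapply(pmax(n - k + 1L, 0L), seq_len), use.names = FALSE)
    tibble(idx = idx, kmer = substring(seqs[idx], starts, starts + k - 1L)) |>
      distinct()
  }
  ka <- kmers(unname(pa))
  kb <- kmers(unname(pb))
  inner_join(ka, kb, by = "kmer", relationship = "many-to-many") |>
    distinct(ia = .data$idx.x, ib = .data$idx.y)
}

#' Select reciprocal best hits between haplotypes
#'
#' A pair (a, b) is a reciprocal best hit (RBH) when b is a's best
#' cross-haplotype hit by bit score and a is b's. Ties on bit score are
#' broken by longer alignment, then lower e-value, then lexicographically
#' smaller subject id, so the choice is deterministic. Pairs whose
#' chromosomes are not a corresponding pair are flagged, not dropped —
#' rejection happens downstream where it is counted.
#'
#' @param hits Hit tibble covering both directions (see [score_all_vs_all()]).
#' @param chromosome_map Tibble with `chrom_a`, `chrom_b`.
#' @param gene_index Tibble with `gene_id`, `haplotype`, `chromosome` for all
#'   genes (e.g. `bind_rows(genes_a, genes_b)`).
#' @return Tibble of RBH pairs: `gene_a`, `gene_b`, `score_ab`, `score_ba`,
#'   `chrom_a`, `chrom_b`, `same_chrom_pair`.
#' @export
find_rbh <- function(hits, chromosome_map, gene_index) {
  chromosome_map <- validate_chromosome_map(chromosome_map)
  idx <- gene_index[, c("gene_id", "haplotype", "chromosome")]
  hits <- hits |>
    left_join(rename(idx, q_hap = "haplotype", q_chrom = "chromosome"),
              by = c(query_id = "gene_id")) |>
    left_join(rename(idx, s_hap = "haplotype", s_chrom = "chromosome"),
              by = c(subject_id = "gene_id"))
  if (anyNA(hits$q_hap) || anyNA(hits$s_hap)) {
    abort("hits reference gene ids absent from gene_index")
  }
  hits <- hits[hits$q_hap != hits$s_hap, , drop = FALSE]
  best <- hits |>
    group_by(.data$query_id) |>
    arrange(desc(.data$bit_score), desc(.data$alignment_length),
            .data$evalue, .data$subject_id, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  best_of <- setNames(best$subject_id, best$query_id)
  a_best <- best[best$q_hap == "A", , drop = FALSE]
  mutual <- a_best[!is.na(best_of[a_best$subject_id]) &
                     best_of[a_best$subject_id] == a_best$query_id, , drop = FALSE]
  score_ba <- setNames(best$bit_score, best$query_id)
  pair_key <- paste(mutual$q_chrom, mutual$s_chrom)
  map_key <- paste(chromosome_map$chrom_a, chromosome_map$chrom_b)
  out <- tibble(
    gene_a = mutual$query_id,
    gene_b = mutual$subject_id,
    score_ab = mutual$bit_score,
    score_ba = unname(score_ba[mutual$subject_id]),
    chrom_a = mutual$q_chrom,
    chrom_b = mutual$s_chrom,
    same_chrom_pair = pair_key %in% map_key
  )
  arrange(out, .data$gene_a)
}
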