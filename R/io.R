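#' Read gene features from a GFF3 file
#'
#' Parses a GFF3 annotation and returns one row per feature of the requested
#' type. Coordinates are kept 1-based inclusive, the GFF3 convention, and are
#' never converted in any table this package writes.
#'
#' @param path Path to a GFF3 file. Lines starting with `#` are ignored.
#' @param feature_type Feature type (column 3) to extract. Default `"gene"`.
#'   Use `"CDS"` together with [splice_cds()] to assemble coding sequence from
#'   a genome FASTA.
#' @param id_attribute Attribute key holding the feature identifier. Default
#'   `"ID"`; for CDS features `"Parent"` is the usual choice.
#'
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand` (and `phase` for CDS features), ordered as in the file.
#' @export
read_gff3 <- function(path, feature_type = "gene", id_attribute = "ID") {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) abort(paste0("no feature lines in ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated columns, got %d",
                  line_no[bad[1]], path, lengths(fields)[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  sel <- m[, 3L] == feature_type
  if (!any(sel)) {
    return(tibble(gene_id = character(), chromosome = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  m <- m[sel, , drop = FALSE]
  ln <- line_no[sel]
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(sprintf("malformed GFF3 line %d in %s: non-numeric coordinates", ln[bad[1]], path))
  }
  bad <- which(end < start)
  if (length(bad) > 0L) {
    abort(sprintf("malformed GFF3 line %d in %s: end < start", ln[bad[1]], path))
  }
  ids <- gff3_attribute(m[, 9L], id_attribute)
  bad <- which(is.na(ids))
  if (length(bad) > 0L) {
    abort(sprintf("GFF3 line %d in %s: missing attribute '%s'", ln[bad[1]], path, id_attribute))
  }
  out <- tibble(gene_id = ids, chromosome = m[, 1L], start = start, end = end,
                strand = m[, 7L])
  if (feature_type == "CDS") {
    out$phase <- m[, 8L]
  } else {
    dup <- unique(ids[duplicated(ids)])
    if (length(dup) > 0L) {
      abort(paste0("duplicate ", feature_type, " IDs in ", path, ": ",
                   paste(head(dup, 10L), collapse = ", ")))
    }
  }
  out
}

gff3_attribute <- function(attrs, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]+)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a (possibly line-wrapped) FASTA file.
#' @return Named character vector of upper-case sequences, whitespace
#'   stripped, in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate FASTA ids in ", path, ": ", paste(head(dup, 10L), collapse = ", ")))
  }
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  setNames(seqs, ids)
}

#' Read an all-vs-all hit table (12-column BLAST tabular dialect)
#'
#' Expects the standard 12 tab-separated columns: query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score.
#'
#' @param path Path to the tab-separated hit file.
#' @return A tibble with columns `query_id`, `subject_id`, `identity_pct`,
#'   `alignment_length`, `evalue`, `bit_score`, in file order.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0L) {
    abort(sprintf("hit file %s line %d: expected 12 columns, got %d",
                  path, line_no[bad[1]], lengths(fields)[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(col, name) {
    x <- suppressWarnings(as.numeric(m[, col]))
    bad <- which(is.na(x))
    if (length(bad) > 0L) {
      abort(sprintf("hit file %s line %d: non-numeric %s '%s'",
                    path, line_no[bad[1]], name, m[bad[1], col]))
    }
    x
  }
  tibble(
    query_id = m[, 1L], subject_id = m[, 2L],
    identity_pct = num(3L, "identity"),
    alignment_length = as.integer(num(4L, "alignment length")),
    evalue = num(11L, "e-value"),
    bit_score = num(12L, "bit score")
  )
}

#' Read a chromosome-correspondence table
#'
#' Two tab-separated columns pairing each haplotype-A chromosome with its
#' haplotype-B homolog; `#` comment lines allowed.
#'
#' @param path Path to the two-column TSV.
#' @return Tibble with columns `chrom_a`, `chrom_b`.
#' @export
read_chromosome_map <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", col_names = c("chrom_a", "chrom_b"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_chromosome_map(tab)
}

validate_chromosome_map <- function(tab) {
  tab <- as_tibble(tab)
  if (ncol(tab) < 2L) abort("chromosome map needs two columns (chrom_a, chrom_b)")
  names(tab)[1:2] <- c("chrom_a", "chrom_b")
  tab <- tab[, 1:2]
  if (any(!nzchar(tab$chrom_a)) || any(!nzchar(tab$chrom_b)) || anyNA(tab)) {
    abort("chromosome map has empty entries")
  }
  if (anyDuplicated(tab$chrom_a) || anyDuplicated(tab$chrom_b)) {
    abort("each chromosome may appear in at most one correspondence pair")
  }
  tab
}

#' Read a raw count matrix
#'
#' First column is the gene id; remaining columns are per-sample non-negative
#' integer counts.
#'
#' @param path Path to the TSV.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  tab <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat) || any(mat < 0)) abort("count matrix has missing or negative entries")
  rownames(mat) <- ids
  mat
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample` (or `sample_id`) and `condition`.
#' @return Tibble with columns `sample_id`, `condition`.
#' @export
read_design <- function(path) {
  tab <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  names(tab)[1:2] <- c("sample_id", "condition")
  if (anyDuplicated(tab$sample_id)) abort("duplicate sample ids in design")
  tab[, 1:2]
}

#' Assemble spliced, strand-corrected CDS from GFF3 CDS features
#'
#' Exons of each gene are sorted by coordinate, their genomic sequence
#' concatenated, and the result reverse-complemented for minus-strand genes.
#' A trailing incomplete codon is trimmed with a warning.
#'
#' @param cds_features Tibble from `read_gff3(path, "CDS", "Parent")`.
#' @param genome Named character vector of chromosome sequences
#'   (from [read_fasta()]).
#' @return Named character vector of spliced CDS, one per parent id.
#' @export
splice_cds <- function(cds_features, genome) {
  missing_chrom <- setdiff(unique(cds_features$chromosome), names(genome))
  if (length(missing_chrom) > 0L) {
    abort(paste0("chromosomes absent from genome FASTA: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  by_gene <- split(cds_features, cds_features$gene_id)
  out <- vapply(by_gene, function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    seq <- paste0(substring(genome[[ex$chromosome[1]]], ex$start, ex$end),
                  collapse = "")
    if (ex$strand[1] == "-") {
      seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    seq
  }, character(1))
  extra <- nchar(out) %% 3L
  if (any(extra > 0L)) {
    warn(paste0(sum(extra > 0L), " CDS with incomplete terminal codon; trimmed"))
    out[extra > 0L] <- substr(out[extra > 0L], 1L,
                              nchar(out[extra > 0L]) - extra[extra > 0L])
  }
  out[unique(cds_features$gene_id)]
}

#' Build the gene-model table for one haplotype
#'
#' Combines annotation skeletons with coding and protein sequences into the
#' table every downstream step consumes. If proteins are not supplied they
#' are translated from the CDS (standard code); a terminal stop is dropped.
#' When several sequences map to one gene id (isoforms), the longest is kept
#' with a message.
#'
#' @param features Tibble from [read_gff3()].
#' @param cds Named character vector of spliced CDS (names = gene ids).
#' @param proteins Optional named character vector of protein sequences.
#' @param haplotype `"A"` or `"B"`.
#' @return Tibble with columns `gene_id`, `haplotype`, `chromosome`, `start`,
#'   `end`, `strand`, `cds`, `protein`.
#' @export
build_gene_models <- function(features, cds, proteins = NULL, haplotype = c("A", "B")) {
  haplotype <- match.arg(haplotype)
  missing_cds <- setdiff(features$gene_id, names(cds))
  if (length(missing_cds) > 0L) {
    abort(paste0("genes without CDS sequence: ", paste(head(missing_cds, 10L), collapse = ", ")))
  }
  if (anyDuplicated(names(cds))) {
    # isoforms: keep the longest sequence per id
    ord <- order(nchar(cds), decreasing = TRUE)
    cds <- cds[ord][!duplicated(names(cds)[ord])]
    inform("multiple sequences per gene id; keeping the longest")
  }
  cds <- cds[features$gene_id]
  extra <- nchar(cds) %% 3L
  if (any(extra > 0L)) {
    warn(paste0(sum(extra > 0L), " CDS with incomplete terminal codon; trimmed"))
    cds[extra > 0L] <- substr(cds[extra > 0L], 1L, nchar(cds[extra > 0L]) - extra[extra > 0L])
  }
  prot <- translate_cds(cds)
  if (!is.null(proteins)) {
    supplied <- toupper(sub("\\*$", "", proteins[features$gene_id]))
    mismatch <- which(!is.na(supplied) & supplied != prot)
    if (length(mismatch) > 0L) {
      abort(paste0("CDS does not translate to the supplied protein for: ",
                   paste(head(features$gene_id[mismatch], 10L), collapse = ", ")))
    }
  }
  tibble(
    gene_id = features$gene_id,
    haplotype = haplotype,
    chromosome = features$chromosome,
    start = features$start,
    end = features$end,
    strand = features$strand,
    cds = unname(cds),
    protein = unname(prot)
  )
}

# translate spliced CDS, dropping a terminal stop; internal stops are kept
# as '*' so that validation downstream can flag them
translate_cds <- function(cds) {
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds), if.fuzzy.codon = "solve"))
  sub("\\*$", "", prot)
}

#' Write a gene-model table as GFF3 + FASTA
#'
#' @param genes Gene-model tibble (see [build_gene_models()]).
#' @param prefix Output path prefix; writes `<prefix>.gff3`,
#'   `<prefix>.cds.fa`, `<prefix>.prot.fa`.
#' @return Invisibly, the three paths written.
#' @export
write_gene_models <- function(genes, prefix) {
  gff <- paste0(prefix, ".gff3")
  lines <- sprintf("%s\thaplopair\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chromosome, genes$start, genes$end, genes$strand,
                   genes$gene_id)
  writeLines(c("##gff-version 3", lines), gff)
  cds_fa <- paste0(prefix, ".cds.fa")
  prot_fa <- paste0(prefix, ".prot.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(genes$cds, genes$gene_id)), cds_fa)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(genes$protein, genes$gene_id)), prot_fa)
  invisible(c(gff, cds_fa, prot_fa))
}
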