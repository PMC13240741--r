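# In-code fixtures: tiny annotation / sequence files and toy gene tables.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

three_gene_gff3 <- function() {
  write_lines_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1;Name=first",
    "chr1\tsrc\tgene\t601\t900\t.\t-\t.\tID=g2",
    "chr2\tsrc\tgene\t51\t350\t.\t+\t.\tID=g3"
  ), ".gff3")
}

# toy gene table straight from CDS strings (single-exon layout)
toy_genes <- function(cds, haplotype, chromosome = "chr1") {
  n <- length(cds)
  start <- cumsum(c(1, head(nchar(cds), -1) + 1000))
  tibble::tibble(
    gene_id = names(cds),
    haplotype = haplotype,
    chromosome = rep_len(chromosome, n),
    start = start,
    end = start + nchar(cds) - 1,
    strand = "+",
    cds = unname(cds),
    protein = unname(sub("\\*$", "", as.character(
      Biostrings::translate(Biostrings::DNAStringSet(cds)))))
  )
}

random_sense_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0("ATG", paste0(sample(setdiff(SENSE_CODONS, "ATG"), n_codons - 1,
                              replace = TRUE), collapse = ""))
}

# small simulated diploid reused across tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_diploid(
        sim_config(n_chrom_pairs = 2, genes_per_chrom = 120, n_paralogs = 12,
                   inversion_length = 20), seed = 11)
    }
    cache
  }
})
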