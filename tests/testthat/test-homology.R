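make_index <- function(...) {
  # gene_id -> haplotype/chromosome index from "A" / "B" prefixed ids
  ids <- c(...)
  tibble::tibble(gene_id = ids,
                 haplotype = substr(ids, 1, 1),
                 chromosome = paste0("chr", substr(ids, 1, 1), "1"))
}

one_map <- tibble::tibble(chrom_a = "chrA1", chrom_b = "chrB1")

hit_row <- function(q, s, score, len = 100L, ev = 0) {
  tibble::tibble(query_id = q, subject_id = s, identity_pct = 90,
                 alignment_length = len, evalue = ev, bit_score = score)
}

test_that("mutual unique maxima become RBH pairs", {
  hits <- dplyr::bind_rows(hit_row("A1", "B1", 100), hit_row("B1", "A1", 100),
                           hit_row("A1", "B2", 50), hit_row("B2", "A1", 50))
  rbh <- find_rbh(hits, one_map, make_index("A1", "B1", "B2"))
  expect_equal(nrow(rbh), 1L)
  expect_equal(rbh$gene_a, "A1")
  expect_equal(rbh$gene_b, "B1")
  expect_true(rbh$same_chrom_pair)
})

test_that("score ties resolve by length, e-value, then subject id", {
  hits <- dplyr::bind_rows(
    hit_row("A1", "B2", 100), hit_row("A1", "B1", 100),
    hit_row("B1", "A1", 90), hit_row("B2", "A1", 10))
  rbh <- find_rbh(hits, one_map, make_index("A1", "B1", "B2"))
  expect_equal(rbh$gene_b, "B1")  # lexicographically smaller subject wins
  hits2 <- dplyr::bind_rows(
    hit_row("A1", "B2", 100, len = 150L), hit_row("A1", "B1", 100, len = 100L),
    hit_row("B2", "A1", 90), hit_row("B1", "A1", 90))
  rbh2 <- find_rbh(hits2, one_map, make_index("A1", "B1", "B2"))
  expect_equal(rbh2$gene_b, "B2")  # longer alignment beats subject order
})

test_that("find_rbh equals the exhaustive mutual-argmax oracle on random matrices", {
  set.seed(101)
  for (rep in 1:20) {
    na <- sample(3:20, 1)
    nb <- sample(3:20, 1)
    ids_a <- sprintf("A%02d", 1:na)
    ids_b <- sprintf("B%02d", 1:nb)
    grid <- expand.grid(q = ids_a, s = ids_b, stringsAsFactors = FALSE)
    score <- sample(1:15, nrow(grid), replace = TRUE)  # many deliberate ties
    hits <- dplyr::bind_rows(
      tibble::tibble(query_id = grid$q, subject_id = grid$s, identity_pct = 90,
                     alignment_length = sample(50:60, nrow(grid), TRUE),
                     evalue = 0, bit_score = score),
      tibble::tibble(query_id = grid$s, subject_id = grid$q, identity_pct = 90,
                     alignment_length = sample(50:60, nrow(grid), TRUE),
                     evalue = 0, bit_score = score))
    idx <- make_index(ids_a, ids_b)
    got <- find_rbh(hits, one_map, idx)
    hap_of <- setNames(idx$haplotype, idx$gene_id)
    want <- oracle_rbh(hits, hap_of)
    expect_equal(got$gene_a, want$gene_a)
    expect_equal(got$gene_b, want$gene_b)
  }
})

test_that("RBH output is a partial injection, order-invariant, and mirror-symmetric", {
  set.seed(7)
  grid <- expand.grid(q = sprintf("A%02d", 1:15), s = sprintf("B%02d", 1:15),
                      stringsAsFactors = FALSE)
  sc <- sample(1:40, nrow(grid), replace = TRUE)
  fwd <- tibble::tibble(query_id = grid$q, subject_id = grid$s,
                        identity_pct = 90, alignment_length = 100L,
                        evalue = 0, bit_score = sc)
  rev <- dplyr::rename(fwd, query_id = "subject_id", subject_id = "query_id")
  hits <- dplyr::bind_rows(fwd, rev)
  idx <- make_index(sprintf("A%02d", 1:15), sprintf("B%02d", 1:15))
  rbh <- find_rbh(hits, one_map, idx)
  expect_false(anyDuplicated(rbh$gene_a) > 0)
  expect_false(anyDuplicated(rbh$gene_b) > 0)
  shuffled <- find_rbh(hits[sample(nrow(hits)), ], one_map, idx)
  expect_equal(rbh, shuffled)
  # swap haplotype labels: pairs mirror
  idx_sw <- idx
  idx_sw$haplotype <- ifelse(idx$haplotype == "A", "B", "A")
  map_sw <- tibble::tibble(chrom_a = "chrB1", chrom_b = "chrA1")
  idx_sw$chromosome <- idx$chromosome
  rbh_sw <- find_rbh(hits, map_sw, idx_sw)
  expect_equal(sort(paste(rbh$gene_a, rbh$gene_b)),
               sort(paste(rbh_sw$gene_b, rbh_sw$gene_a)))
})

test_that("builtin scorer matches exhaustive pairwise alignment on toy proteins", {
  set.seed(5)
  cds_a <- setNames(vapply(1:5, function(i) random_sense_cds(40), ""),
                    paste0("A", 1:5))
  cds_b <- setNames(vapply(1:5, function(i) random_sense_cds(40), ""),
                    paste0("B", 1:5))
  ga <- toy_genes(cds_a, "A", "chrA1")
  gb <- toy_genes(cds_b, "B", "chrB1")
  hits <- score_all_vs_all(ga, gb, mode = "builtin")
  # oracle: direct alignment of every ordered pair
  b62 <- haplopair:::blosum62()
  for (i in 1:5) {
    for (j in 1:5) {
      sc <- Biostrings::score(Biostrings::pairwiseAlignment(
        Biostrings::AAString(ga$protein[i]), Biostrings::AAString(gb$protein[j]),
        substitutionMatrix = b62, gapOpening = 10, gapExtension = 0.5,
        type = "local"))
      row <- hits[hits$query_id == ga$gene_id[i] &
                    hits$subject_id == gb$gene_id[j], ]
      if (sc > 0) expect_equal(row$bit_score, sc) else expect_equal(nrow(row), 0L)
    }
  }
  # symmetric coverage
  fwd <- hits[startsWith(hits$query_id, "A"), ]
  expect_true(all(paste(fwd$subject_id, fwd$query_id) %in%
                    paste(hits$query_id, hits$subject_id)))
})

test_that("identical protein sets self-pair and import mode validates ids", {
  cds <- setNames(vapply(1:2, function(i) random_sense_cds(30, seed = i), ""),
                  c("g1", "g2"))
  ga <- toy_genes(cds, "A", "chrA1")
  gb <- toy_genes(setNames(cds, c("h1", "h2")), "B", "chrB1")
  hits <- score_all_vs_all(ga, gb, mode = "builtin")
  rbh <- find_rbh(hits, one_map, dplyr::bind_rows(ga, gb))
  expect_equal(rbh$gene_b[rbh$gene_a == "g1"], "h1")
  expect_equal(rbh$gene_b[rbh$gene_a == "g2"], "h2")
  p <- write_lines_tmp("gX\th1\t90\t100\t1\t0\t1\t100\t1\t100\t1e-10\t200", ".tsv")
  expect_error(score_all_vs_all(ga, gb, mode = "import", hits_path = p),
               "unknown gene ids.*gX")
})
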