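# Independent brute-force oracles used to freeze expected values.

GC_TABLE <- Biostrings::GENETIC_CODE
NT <- c("A", "C", "G", "T")

# all single-base variants of a codon at one position
variants_at <- function(codon, pos) {
  out <- character(0)
  for (b in NT) {
    if (b != substr(codon, pos, pos)) {
      v <- codon
      substr(v, pos, pos) <- b
      out <- c(out, v)
    }
  }
  out
}

# synonymous site count of one codon, stop-excluded denominators
oracle_syn_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    vs <- variants_at(codon, pos)
    vs <- vs[GC_TABLE[vs] != "*"]
    if (length(vs) > 0) s <- s + sum(GC_TABLE[vs] == GC_TABLE[codon]) / length(vs)
  }
  s
}

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# pathway-averaged (Sd, Nd) contribution of one codon pair
oracle_sd_nd <- function(x, y) {
  diffpos <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  if (length(diffpos) == 0) return(c(0, 0))
  sums <- c(0, 0)
  n_valid <- 0
  for (ord in perms_of(diffpos)) {
    cur <- x
    step <- c(0, 0)
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(y, p, p)
      if (GC_TABLE[nxt] == "*") { ok <- FALSE; break }
      if (GC_TABLE[cur] == GC_TABLE[nxt]) step[1] <- step[1] + 1
      else step[2] <- step[2] + 1
      cur <- nxt
    }
    if (ok) { sums <- sums + step; n_valid <- n_valid + 1 }
  }
  if (n_valid > 0) return(sums / n_valid)
  # documented fallback: classify each differing position by its direct
  # change, averaged over the sense-codon contexts
  sums <- c(0, 0)
  for (p in diffpos) {
    cls <- logical(0)
    xa <- x; substr(xa, p, p) <- substr(y, p, p)
    if (GC_TABLE[xa] != "*") cls <- c(cls, GC_TABLE[x] == GC_TABLE[xa])
    yb <- y; substr(yb, p, p) <- substr(x, p, p)
    if (GC_TABLE[yb] != "*") cls <- c(cls, GC_TABLE[y] == GC_TABLE[yb])
    if (length(cls) > 0) sums <- sums + c(mean(cls), mean(!cls))
  }
  sums
}

# full NG86 estimate for two codon vectors (no alignment step)
oracle_ng86 <- function(ca, cb) {
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) +
          sum(vapply(cb, oracle_syn_sites, 0))) / 2
  N <- 3 * length(ca) - S
  sdnd <- rowSums(vapply(seq_along(ca),
                         function(i) oracle_sd_nd(ca[i], cb[i]), c(0, 0)))
  ps <- sdnd[1] / S
  pn <- sdnd[2] / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(s_sites = S, n_sites = N, sd = sdnd[1], nd = sdnd[2],
       ks = jc(ps), ka = jc(pn))
}

# independent codon splitter (regmatches, not the package's substring math)
split_codons_oracle <- function(cds) {
  regmatches(cds, gregexpr("...", cds))[[1]]
}

codon_alignment <- function(ca, cb) {
  structure(list(codons_a = ca, codons_b = cb, n_codons = length(ca),
                 n_dropped = 0L), class = "codon_alignment")
}

SENSE_CODONS <- {
  all <- as.vector(outer(outer(NT, NT, paste0), NT, paste0))
  all[GC_TABLE[all] != "*"]
}

# mutual-argmax RBH oracle on a hit table; ties broken by score desc,
# alignment length desc, evalue asc, subject id asc
oracle_rbh <- function(hits, hap_of) {
  best <- list()
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q & hap_of[hits$subject_id] != hap_of[q], ]
    if (nrow(h) == 0) next
    h <- h[order(-h$bit_score, -h$alignment_length, h$evalue, h$subject_id), ]
    best[[q]] <- h$subject_id[1]
  }
  out <- NULL
  for (a in names(best)) {
    if (hap_of[a] != "A") next
    b <- best[[a]]
    if (!is.null(best[[b]]) && best[[b]] == a) {
      out <- rbind(out, data.frame(gene_a = a, gene_b = b))
    }
  }
  if (is.null(out)) data.frame(gene_a = character(), gene_b = character())
  else out[order(out$gene_a), , drop = FALSE]
}

# exhaustive maximal-chain search over few anchors (subset enumeration)
oracle_best_chain_size <- function(ra, rb, max_gap) {
  n <- length(ra)
  ord <- order(ra)
  ra <- ra[ord]; rb <- rb[ord]
  best <- 0
  for (mask in seq_len(2^n) - 1) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    da <- diff(ra[idx])
    db <- diff(rb[idx])
    ok_f <- all(da > 0 & da <= max_gap) && all(db > 0 & db <= max_gap)
    ok_r <- all(da > 0 & da <= max_gap) && all(-db > 0 & -db <= max_gap)
    if (ok_f || ok_r) best <- length(idx)
  }
  best
}
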