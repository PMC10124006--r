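# Independent oracles and fixture builders shared across test files.

# All-pairs O(n^2) positional classifier, deliberately independent of the
# interval-index implementation: plain loops over data.frame rows using
# the gap definition max(0, max(starts) - min(ends) - 1).
brute_force_classify <- function(pcg, lnc, window = 50000) {
  res <- data.frame(gene_id = lnc$gene_id, category = NA_character_,
                    nearest_pcg_id = NA_character_, gap_nt = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lnc))) {
    p <- pcg[pcg$chrom == lnc$chrom[i], , drop = FALSE]
    if (nrow(p) == 0) {
      res$category[i] <- "desert"
      next
    }
    overlaps <- p$start <= lnc$end[i] & lnc$start[i] <= p$end
    if (any(overlaps)) {
      res$category[i] <- "overlapped"
      res$nearest_pcg_id[i] <- min(p$gene_id[overlaps])
    } else {
      gap <- pmax(0L, pmax(p$start, lnc$start[i]) -
                        pmin(p$end, lnc$end[i]) - 1L)
      g <- min(gap)
      res$nearest_pcg_id[i] <- min(p$gene_id[gap == g])
      res$gap_nt[i] <- g
      res$category[i] <- if (g <= window) "proximal" else "desert"
    }
  }
  res
}

# Fully random gene layout (unlike the generator's slotted placement):
# uniform starts on short chromosomes so all three classes and plenty of
# near-boundary geometry arise.
random_gene_table <- function(seed, n_pcg, n_lnc, n_chrom = 3,
                              chrom_len = 5e6) {
  withr::with_seed(seed, {
    mk <- function(n, prefix, biotype) {
      start <- sample.int(chrom_len, n, replace = TRUE)
      len <- sample(500:5000, n, replace = TRUE)
      data.frame(
        gene_id = sprintf("%s%04d", prefix, seq_len(n)),
        gene_name = sprintf("%s%d", prefix, seq_len(n)),
        biotype = biotype,
        chrom = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
        start = start, end = start + len - 1L,
        strand = sample(c("+", "-"), n, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    list(pcg = mk(n_pcg, "RPCG", "protein_coding"),
         lnc = mk(n_lnc, "RLNC", "lncRNA"))
  })
}

random_annotation <- function(seed, n_pcg, n_lnc, n_chrom = 3,
                              chrom_len = 5e6) {
  tabs <- random_gene_table(seed, n_pcg, n_lnc, n_chrom, chrom_len)
  list(annot = annotation_set(rbind(tabs$pcg, tabs$lnc)),
       pcg = tabs$pcg, lnc = tabs$lnc)
}

# random counts fixture
random_counts <- function(seed, n_gene = 200, n_sample = 6) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_gene * n_sample, mu = 200, size = 10),
                nrow = n_gene,
                dimnames = list(sprintf("g%03d", seq_len(n_gene)),
                                sprintf("s%d", seq_len(n_sample))))
    expression_matrix(m, "counts",
                      gene_lengths = sample(500:5000, n_gene, replace = TRUE))
  })
}

# direct two-KL-sum evaluation of the base-2 Jensen-Shannon divergence,
# used as the independent oracle for the specificity score
kl_sum_jsd <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log2(q[i] / m[i])
  }
  s
}

write_mini_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}
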