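make_gene_line <- function(chrom, start, end, id, biotype, feature = "gene",
                           attr_key = "gene_type") {
  sprintf('%s\tsrc\t%s\t%d\t%d\t.\t+\t.\tgene_id "%s"; %s "%s"; gene_name "%s";',
          chrom, feature, start, end, id, attr_key, biotype, id)
}

test_that("read_gtf keeps gene rows of the requested biotypes and ignores exons", {
  path <- write_mini_gtf(c(
    "## a comment line",
    make_gene_line("chr1", 1000, 2000, "PCG1", "protein_coding"),
    make_gene_line("chr1", 5000, 6000, "LNC1", "lncRNA"),
    make_gene_line("chr1", 9000, 9500, "MIR1", "miRNA"),
    vapply(1:10, function(i) {
      make_gene_line("chr1", 1000 + i, 1100 + i, "PCG1", "protein_coding",
                     feature = "exon")
    }, character(1))
  ))
  annot <- read_gtf(path)
  expect_equal(nrow(annot$genes), 2)  # miRNA row dropped, exons ignored
  expect_setequal(annot$genes$gene_id, c("PCG1", "LNC1"))
  expect_equal(annot$genes$start[annot$genes$gene_id == "PCG1"], 1000)
  expect_equal(annot$genes$end[annot$genes$gene_id == "PCG1"], 2000)
})

test_that("read_gtf accepts the Ensembl gene_biotype dialect identically", {
  mk <- function(key) write_mini_gtf(c(
    make_gene_line("chr1", 1000, 2000, "PCG1", "protein_coding", attr_key = key),
    make_gene_line("chr1", 5000, 6000, "LNC1", "lncRNA", attr_key = key)
  ))
  a1 <- read_gtf(mk("gene_type"))
  a2 <- read_gtf(mk("gene_biotype"))
  expect_equal(a1$genes, a2$genes)
})

test_that("read_gtf errors on malformed lines (naming the line) and empty annotations", {
  bad <- write_mini_gtf(c(
    make_gene_line("chr1", 1000, 2000, "PCG1", "protein_coding"),
    "chr1\tonly three\tfields"
  ))
  expect_error(read_gtf(bad), "line 2")
  empty <- write_mini_gtf(
    make_gene_line("chr1", 1, 100, "X1", "snoRNA", feature = "exon"))
  expect_error(read_gtf(empty), "no 'gene'")
  expect_error(read_gtf(tempfile()), "not found")
})

toy_annotation <- function(pcg, lnc) {
  df <- function(x, biotype) {
    data.frame(gene_id = x$id, gene_name = x$id, biotype = biotype,
               chrom = x$chrom %||% "chr1", start = x$start, end = x$end,
               strand = x$strand %||% "+", stringsAsFactors = FALSE)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  annotation_set(rbind(
    do.call(rbind, lapply(pcg, df, biotype = "protein_coding")),
    do.call(rbind, lapply(lnc, df, biotype = "lncRNA"))
  ))
}

test_that("classification respects the overlap and 50 kb boundary rules exactly", {
  annot <- toy_annotation(
    pcg = list(list(id = "P1", start = 1000, end = 2000)),
    lnc = list(
      list(id = "L_overlap", start = 1500, end = 2500),
      list(id = "L_edge_in", start = 52001, end = 53000),  # gap 50000
      list(id = "L_edge_out", start = 52002, end = 53001), # gap 50001
      list(id = "L_adjacent", start = 2001, end = 2600)    # gap 0
    )
  )
  cl <- classify_lncrnas(annot)
  got <- setNames(cl$category, cl$gene_id)
  expect_equal(got[["L_overlap"]], "overlapped")
  expect_equal(got[["L_edge_in"]], "proximal")
  expect_equal(got[["L_edge_out"]], "desert")
  expect_equal(got[["L_adjacent"]], "proximal")
  gaps <- setNames(cl$gap_nt, cl$gene_id)
  expect_equal(gaps[["L_edge_in"]], 50000L)
  expect_equal(gaps[["L_edge_out"]], 50001L)
  expect_equal(gaps[["L_adjacent"]], 0L)
  expect_true(is.na(gaps[["L_overlap"]]))
  expect_error(classify_lncrnas(annot, window_nt = 0), "positive")
})

test_that("classification is strand-blind and errors/warns on degenerate annotations", {
  base <- toy_annotation(
    pcg = list(list(id = "P1", start = 1000, end = 2000, strand = "+")),
    lnc = list(list(id = "L1", start = 1500, end = 2500, strand = "+"))
  )
  flipped <- base
  flipped$genes$strand <- ifelse(flipped$genes$strand == "+", "-", "+")
  flipped <- annotation_set(flipped$genes)
  expect_equal(classify_lncrnas(base)$category,
               classify_lncrnas(flipped)$category)

  # lncRNA on a chromosome without any PCG: desert, with a warning
  annot <- toy_annotation(
    pcg = list(list(id = "P1", start = 1000, end = 2000)),
    lnc = list(list(id = "L1", start = 100, end = 600, chrom = "chr9"))
  )
  expect_warning(cl <- classify_lncrnas(annot), "without any protein-coding")
  expect_equal(cl$category, "desert")
  expect_true(is.na(cl$gap_nt))
})

test_that("nearest-PCG ties resolve to the lexicographically smaller gene id", {
  annot <- toy_annotation(
    pcg = list(list(id = "P_b", start = 1000, end = 2000),
               list(id = "P_a", start = 13000, end = 14000)),
    lnc = list(list(id = "L1", start = 7001, end = 7999))  # gap 5000 both sides
  )
  cl <- classify_lncrnas(annot)
  expect_equal(cl$gap_nt, 5000L)
  expect_equal(cl$nearest_pcg_id, "P_a")
})

test_that("classification matches the all-pairs brute-force oracle on random layouts", {
  for (seed in c(11, 42, 99)) {
    ra <- random_annotation(seed, n_pcg = 150, n_lnc = 150)
    got <- classify_lncrnas(ra$annot)
    want <- brute_force_classify(ra$pcg, ra$lnc)
    want <- want[match(got$gene_id, want$gene_id), ]
    expect_equal(got$category, want$category)
    expect_equal(got$gap_nt, want$gap_nt)
    expect_equal(got$nearest_pcg_id, want$nearest_pcg_id)
    # partition: exactly one category per lncRNA
    expect_equal(nrow(got), nrow(ra$lnc))
    expect_true(all(got$category %in% c("overlapped", "proximal", "desert")))
  }
})

test_that("adding a PCG farther than the current nearest changes no category", {
  ra <- random_annotation(7, n_pcg = 80, n_lnc = 80)
  before <- classify_lncrnas(ra$annot)
  far <- data.frame(gene_id = "PFAR", gene_name = "PFAR",
                    biotype = "protein_coding", chrom = "chr1",
                    start = 98e6, end = 98e6 + 999, strand = "+",
                    stringsAsFactors = FALSE)
  after <- classify_lncrnas(annotation_set(rbind(ra$annot$genes, far)))
  expect_equal(setNames(after$category, after$gene_id)[before$gene_id],
               setNames(before$category, before$gene_id))
})

test_that("category proportions are exact fractions summing to one", {
  cl <- data.frame(gene_id = letters[1:4],
                   category = c("overlapped", "overlapped", "proximal",
                                "desert"))
  p <- category_proportions(cl)
  expect_equal(unname(p), c(0.5, 0.25, 0.25))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(category_proportions(cl[0, ]), "empty")
})
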