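#' Default lncRNA biotypes
#'
#' GENCODE collapsed most long-noncoding biotypes into a single `lncRNA`
#' biotype from release 29 onward; earlier releases and Ensembl GTFs spell
#' them out. Both vocabularies are accepted by default. The set is a
#' configuration choice, not a fixed truth: category proportions shift with
#' it, which is why every classification entry point takes it as an
#' argument.
#'
#' @return Character vector of biotype strings.
#' @export
gencode_lnc_biotypes <- function() {
  c("lncRNA", "lincRNA", "antisense", "sense_intronic", "sense_overlapping",
    "bidirectional_promoter_lncRNA", "3prime_overlapping_ncRNA",
    "macro_lncRNA", "non_coding")
}

#' Construct an annotation set
#'
#' @param genes data.frame with columns `gene_id`, `gene_name`, `biotype`,
#'   `chrom`, `start`, `end`, `strand` (1-based inclusive coordinates, as
#'   in GTF).
#' @param pcg_biotypes Biotypes treated as protein-coding.
#' @param lnc_biotypes Biotypes treated as lncRNA. Must be disjoint from
#'   `pcg_biotypes`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(genes,
                           pcg_biotypes = "protein_coding",
                           lnc_biotypes = gencode_lnc_biotypes()) {
  required <- c("gene_id", "gene_name", "biotype", "chrom", "start", "end",
                "strand")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) {
    stop("annotation is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(genes) == 0) {
    stop("annotation contains no gene records")
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    stop("duplicated gene_id in annotation: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(genes$start < 1) || any(genes$end < genes$start)) {
    stop("gene coordinates must satisfy 1 <= start <= end")
  }
  if (any(!nzchar(genes$chrom))) {
    stop("chromosome names must be non-empty")
  }
  if (length(intersect(pcg_biotypes, lnc_biotypes)) > 0) {
    stop("pcg_biotypes and lnc_biotypes must be disjoint")
  }
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes,
                 pcg_biotypes = pcg_biotypes,
                 lnc_biotypes = lnc_biotypes),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  n_pcg <- sum(x$genes$biotype %in% x$pcg_biotypes)
  n_lnc <- sum(x$genes$biotype %in% x$lnc_biotypes)
  cat(sprintf("annotation_set: %d genes (%d protein-coding, %d lncRNA) on %d chromosomes\n",
              nrow(x$genes), n_pcg, n_lnc, length(unique(x$genes$chrom))))
  invisible(x)
}

# subset helpers used throughout the classification code
pcg_genes <- function(annot) {
  annot$genes[annot$genes$biotype %in% annot$pcg_biotypes, , drop = FALSE]
}
lnc_genes <- function(annot) {
  annot$genes[annot$genes$biotype %in% annot$lnc_biotypes, , drop = FALSE]
}

# Diagnostic scan run when the GTF parser rejects a file: finds the first
# structurally broken line so the error can name it.
find_malformed_gtf_line <- function(path, max_lines = 5e6) {
  con <- file(path, open = "r")
  on.exit(close(con))
  lineno <- 0L
  repeat {
    chunk <- readLines(con, n = 10000L, warn = FALSE)
    if (length(chunk) == 0) break
    for (i in seq_along(chunk)) {
      lineno <- lineno + 1L
      if (lineno > max_lines) return(NA_integer_)
      ln <- chunk[i]
      if (!nzchar(ln) || startsWith(ln, "#")) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 9 ||
          is.na(suppressWarnings(as.integer(f[4]))) ||
          is.na(suppressWarnings(as.integer(f[5])))) {
        return(lineno)
      }
    }
  }
  NA_integer_
}

#' Read gene records from a GTF file
#'
#' Parses `gene` feature rows from a GENCODE- or Ensembl-dialect GTF and
#' keeps those whose biotype is in the protein-coding or lncRNA sets. Both
#' `gene_type` (GENCODE) and `gene_biotype` (Ensembl) attribute keys are
#' accepted. Coordinates stay 1-based inclusive as in the file. All other
#' feature rows (exons, transcripts, ...) are ignored.
#'
#' @param path Path to a GTF file (plain or gzipped).
#' @inheritParams annotation_set
#' @return An [annotation_set()].
#' @export
read_gtf <- function(path,
                     pcg_biotypes = "protein_coding",
                     lnc_biotypes = gencode_lnc_biotypes()) {
  if (!file.exists(path)) {
    stop("GTF file not found: ", path)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf", feature.type = "gene"),
    error = function(e) {
      bad <- find_malformed_gtf_line(path)
      if (!is.na(bad)) {
        stop("malformed GTF line ", bad, " in ", path, ": ",
             conditionMessage(e), call. = FALSE)
      }
      stop("failed to parse GTF ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (length(gr) == 0) {
    stop("no 'gene' feature rows found in GTF: ", path)
  }
  mc <- S4Vectors::mcols(gr)
  biotype <- if ("gene_type" %in% names(mc)) {
    mc$gene_type
  } else if ("gene_biotype" %in% names(mc)) {
    mc$gene_biotype
  } else {
    stop("GTF gene rows carry neither gene_type nor gene_biotype: ", path)
  }
  gene_name <- if ("gene_name" %in% names(mc)) mc$gene_name else mc$gene_id
  genes <- data.frame(
    gene_id = as.character(mc$gene_id),
    gene_name = ifelse(is.na(gene_name), as.character(mc$gene_id),
                       as.character(gene_name)),
    biotype = as.character(biotype),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
  keep <- genes$biotype %in% c(pcg_biotypes, lnc_biotypes)
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0) {
    stop("no gene rows with a protein-coding or lncRNA biotype in: ", path)
  }
  annotation_set(genes, pcg_biotypes, lnc_biotypes)
}

annot_granges <- function(genes, seqlevels = sort(unique(genes$chrom))) {
  GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = "*",
    gene_id = genes$gene_id
  )
}

#' Classify lncRNAs by distance to protein-coding genes
#'
#' Three positional categories on gene bodies (whole locus, introns
#' included), ignoring strand and comparing only genes on the same
#' chromosome:
#' * `overlapped` — shares at least one nucleotide with a protein-coding
#'   gene (PCG);
#' * `proximal` — no overlap, nearest PCG within `window_nt` (gap of
#'   exactly `window_nt` counts as proximal);
#' * `desert` — nearest PCG farther than `window_nt`, or no PCG on the
#'   chromosome at all.
#'
#' The gap is the number of intervening nucleotides between gene bodies
#' (`max(0, max(start) - min(end) - 1)`); immediately adjacent genes have
#' gap 0. For overlapped lncRNAs the gap is undefined and reported as
#' `NA`. Nearest-PCG ties are broken by smaller gap, then lexicographic
#' gene id, so output is deterministic.
#'
#' @param annot An [annotation_set()].
#' @param window_nt Proximity window in nucleotides (default 50000).
#' @return data.frame with one row per lncRNA: `gene_id`, `gene_name`,
#'   `chrom`, `start`, `end`, `category`, `nearest_pcg_id`, `gap_nt`.
#' @export
classify_lncrnas <- function(annot, window_nt = 50000) {
  if (!inherits(annot, "annotation_set")) {
    stop("annot must be an annotation_set")
  }
  if (!is.numeric(window_nt) || length(window_nt) != 1 || window_nt <= 0) {
    stop("window_nt must be a single positive number")
  }
  lnc <- lnc_genes(annot)
  pcg <- pcg_genes(annot)
  if (nrow(lnc) == 0) {
    return(data.frame(gene_id = character(), gene_name = character(),
                      chrom = character(), start = integer(), end = integer(),
                      category = character(), nearest_pcg_id = character(),
                      gap_nt = integer(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    gene_id = lnc$gene_id, gene_name = lnc$gene_name, chrom = lnc$chrom,
    start = lnc$start, end = lnc$end,
    category = NA_character_, nearest_pcg_id = NA_character_,
    gap_nt = NA_integer_, stringsAsFactors = FALSE
  )
  if (nrow(pcg) == 0) {
    warning("no protein-coding genes in annotation; all lncRNAs classified as desert")
    out$category <- "desert"
    return(out)
  }
  seqlev <- sort(unique(c(lnc$chrom, pcg$chrom)))
  lnc_gr <- annot_granges(lnc, seqlev)
  pcg_gr <- annot_granges(pcg, seqlev)
  lnc_no_pcg_chrom <- !(lnc$chrom %in% unique(pcg$chrom))
  if (any(lnc_no_pcg_chrom)) {
    warning(sum(lnc_no_pcg_chrom),
            " lncRNA(s) on chromosomes without any protein-coding gene; ",
            "classified as desert with undefined gap")
  }

  ov <- GenomicRanges::findOverlaps(lnc_gr, pcg_gr, ignore.strand = TRUE)
  if (length(ov) > 0) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    # lexicographically smallest overlapping PCG id per lncRNA
    hit_ids <- pcg$gene_id[sh]
    ord <- order(qh, hit_ids)
    first <- !duplicated(qh[ord])
    out$category[qh[ord][first]] <- "overlapped"
    out$nearest_pcg_id[qh[ord][first]] <- hit_ids[ord][first]
  }

  rest <- which(is.na(out$category) & !lnc_no_pcg_chrom)
  if (length(rest) > 0) {
    dn <- GenomicRanges::distanceToNearest(lnc_gr[rest], pcg_gr,
                                           select = "all",
                                           ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(dn)
    sh <- S4Vectors::subjectHits(dn)
    d <- S4Vectors::mcols(dn)$distance
    hit_ids <- pcg$gene_id[sh]
    # all hits are at the minimal distance; resolve ties by gene id
    ord <- order(qh, d, hit_ids)
    first <- !duplicated(qh[ord])
    idx <- rest[qh[ord][first]]
    gap <- d[ord][first]
    out$nearest_pcg_id[idx] <- hit_ids[ord][first]
    out$gap_nt[idx] <- as.integer(gap)
    out$category[idx] <- ifelse(gap <= window_nt, "proximal", "desert")
  }
  out$category[lnc_no_pcg_chrom] <- "desert"
  stopifnot(!anyNA(out$category))
  out
}

#' Category proportions of a classification
#'
#' @param classes data.frame as returned by [classify_lncrnas()].
#' @return Named numeric vector over `overlapped`, `proximal`, `desert`
#'   summing to 1 (categories absent from the input get 0).
#' @export
category_proportions <- function(classes) {
  if (is.null(classes) || nrow(classes) == 0) {
    stop("cannot compute proportions of an empty classification")
  }
  lev <- c("overlapped", "proximal", "desert")
  bad <- setdiff(unique(classes$category), lev)
  if (length(bad) > 0) {
    stop("unknown categories: ", paste(bad, collapse = ", "))
  }
  tab <- table(factor(classes$category, levels = lev))
  p <- as.numeric(tab) / nrow(classes)
  names(p) <- lev
  p
}
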