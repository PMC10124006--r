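#' Specification of a synthetic study
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object. The seed fully determines every output; all randomness flows
#' through it, with fixed offsets separating the annotation, count and
#' fractionation draws so each table is reproducible independently.
#'
#' @param seed Integer seed.
#' @param n_chrom Number of synthetic chromosomes.
#' @param n_pcg,n_lnc Numbers of protein-coding and lncRNA genes.
#' @param class_fractions Target overlapped/proximal/desert mix for the
#'   lncRNAs (named numeric summing to 1); realized exactly by
#'   largest-remainder apportionment.
#' @param n_stages Number of differentiation stages / cell types.
#' @param n_reps Replicates per stage and per condition.
#' @param frac_spec_genes Fraction of genes planted as stage-specific.
#' @param fold_spec Expression fold applied in a specific gene's stage.
#' @param nb_dispersion Negative-binomial dispersion of counts.
#' @param n_de Number of genes planted as differentially expressed
#'   between the two simulated conditions.
#' @param lfc_de Planted absolute log2 fold change for those genes.
#' @param frac_cytoplasmic,frac_nuclear Fractions of genes planted with a
#'   cytoplasmic (+`loc_log2_ratio`) or nuclear (-`loc_log2_ratio`)
#'   localization; the remainder is planted neutral (ratio 0).
#' @param loc_log2_ratio Planted cytoplasm:nucleus log2 ratio magnitude.
#' @param noise_sd Standard deviation (log2 scale) of the multiplicative
#'   noise on fraction FPKM.
#' @param gene_length_range Gene length range in nt (single-exon genes).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_chrom = 3L,
                           n_pcg = 300L,
                           n_lnc = 300L,
                           class_fractions = c(overlapped = 0.5,
                                               proximal = 0.3,
                                               desert = 0.2),
                           n_stages = 5L,
                           n_reps = 3L,
                           frac_spec_genes = 0.2,
                           fold_spec = 8,
                           nb_dispersion = 0.05,
                           n_de = 50L,
                           lfc_de = 2,
                           frac_cytoplasmic = 0.3,
                           frac_nuclear = 0.3,
                           loc_log2_ratio = 1,
                           noise_sd = 0.1,
                           gene_length_range = c(500L, 5000L)) {
  lev <- c("overlapped", "proximal", "desert")
  if (!all(lev %in% names(class_fractions))) {
    stop("class_fractions must be named overlapped/proximal/desert")
  }
  class_fractions <- class_fractions[lev]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must be non-negative and sum to 1")
  }
  if (n_pcg < 1 || n_lnc < 1) stop("n_pcg and n_lnc must be at least 1")
  if (n_stages < 2) stop("at least 2 stages are required")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (frac_cytoplasmic + frac_nuclear > 1) {
    stop("localization fractions exceed 1")
  }
  if (n_de > n_pcg + n_lnc) stop("n_de exceeds the number of genes")
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 n_pcg = as.integer(n_pcg), n_lnc = as.integer(n_lnc),
                 class_fractions = class_fractions,
                 n_stages = as.integer(n_stages),
                 n_reps = as.integer(n_reps),
                 frac_spec_genes = frac_spec_genes, fold_spec = fold_spec,
                 nb_dispersion = nb_dispersion, n_de = as.integer(n_de),
                 lfc_de = lfc_de, frac_cytoplasmic = frac_cytoplasmic,
                 frac_nuclear = frac_nuclear,
                 loc_log2_ratio = loc_log2_ratio, noise_sd = noise_sd,
                 gene_length_range = as.integer(gene_length_range)),
            class = "synthetic_spec")
}

# exact integer split of n by fractions (largest remainder)
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic annotation with planted positional classes
#'
#' Protein-coding genes are laid out on widely spaced slots (2 Mb apart),
#' then each lncRNA is placed relative to a host PCG so that its assigned
#' class holds by construction: overlapped lncRNAs start inside the host,
#' proximal lncRNAs follow it at a gap drawn from \[0, 50000\] nt, desert
#' lncRNAs at a gap drawn from (50000, 500000\] nt. The wide slot
#' spacing guarantees no other PCG comes within 50 kb. The realized
#' classes are verified against [classify_lncrnas()] before the GTF is
#' written; a mismatch aborts (it would indicate a generator bug).
#'
#' The same call also plants the expression programs recorded in the
#' ground-truth table: stage-specific genes, differentially expressed
#' genes with sign, and subcellular localization ratios.
#'
#' @param spec A [synthetic_spec()].
#' @param gtf_path Where to write the GENCODE-dialect GTF (single-exon
#'   genes). Defaults to a temporary file.
#' @return List with elements `annotation` (an [annotation_set()]),
#'   `truth` (data.frame: `gene_id`, `kind`, `length_nt`, `class`,
#'   `spec_stage`, `de_sign`, `loc_log2_ratio`), and `gtf` (the path).
#' @export
make_annotation <- function(spec, gtf_path = tempfile(fileext = ".gtf")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    spacing <- 2e6
    lenr <- spec$gene_length_range
    rlen <- function(n) sample(seq(lenr[1], lenr[2]), n, replace = TRUE)

    chrom_of_pcg <- rep(paste0("chr", seq_len(spec$n_chrom)),
                        length.out = spec$n_pcg)
    slot_in_chrom <- stats::ave(seq_len(spec$n_pcg), chrom_of_pcg,
                                FUN = seq_along)
    pcg_len <- rlen(spec$n_pcg)
    pcg_start <- as.integer(1e5 + (slot_in_chrom - 1) * spacing)
    pcg <- data.frame(
      gene_id = sprintf("SYNPG%04d", seq_len(spec$n_pcg)),
      gene_name = sprintf("PCG%d", seq_len(spec$n_pcg)),
      biotype = "protein_coding",
      chrom = chrom_of_pcg,
      start = pcg_start,
      end = pcg_start + pcg_len - 1L,
      strand = sample(c("+", "-"), spec$n_pcg, replace = TRUE),
      stringsAsFactors = FALSE
    )

    n_class <- apportion(spec$n_lnc, spec$class_fractions)
    lnc_class <- sample(rep(c("overlapped", "proximal", "desert"), n_class))
    host <- sample.int(spec$n_pcg, spec$n_lnc, replace = TRUE)
    lnc_len <- rlen(spec$n_lnc)
    lnc_start <- integer(spec$n_lnc)
    for (i in seq_len(spec$n_lnc)) {
      h <- host[i]
      lnc_start[i] <- switch(
        lnc_class[i],
        overlapped = pcg$start[h] +
          sample.int(pcg$end[h] - pcg$start[h] + 1L, 1L) - 1L,
        proximal = pcg$end[h] + sample(0:50000, 1L) + 1L,
        desert = pcg$end[h] + sample(50001:500000, 1L) + 1L
      )
    }
    lnc <- data.frame(
      gene_id = sprintf("SYNLN%04d", seq_len(spec$n_lnc)),
      gene_name = sprintf("LNC%d", seq_len(spec$n_lnc)),
      biotype = "lncRNA",
      chrom = pcg$chrom[host],
      start = lnc_start,
      end = lnc_start + lnc_len - 1L,
      strand = sample(c("+", "-"), spec$n_lnc, replace = TRUE),
      stringsAsFactors = FALSE
    )

    genes <- rbind(pcg, lnc)
    annot <- annotation_set(genes)

    realized <- classify_lncrnas(annot)
    want <- stats::setNames(lnc_class, lnc$gene_id)
    if (!all(realized$category == want[realized$gene_id])) {
      stop("internal error: planted classes not realized by placement")
    }

    n_gene <- nrow(genes)
    truth <- data.frame(
      gene_id = genes$gene_id,
      kind = ifelse(genes$biotype == "protein_coding", "pcg", "lnc"),
      length_nt = genes$end - genes$start + 1L,
      class = c(rep(NA_character_, spec$n_pcg), lnc_class),
      spec_stage = NA_integer_,
      de_sign = 0L,
      loc_log2_ratio = 0,
      stringsAsFactors = FALSE
    )
    n_spec <- round(spec$frac_spec_genes * n_gene)
    if (n_spec > 0) {
      idx <- sample.int(n_gene, n_spec)
      truth$spec_stage[idx] <- sample.int(spec$n_stages, n_spec,
                                          replace = TRUE)
    }
    if (spec$n_de > 0) {
      idx <- sample.int(n_gene, spec$n_de)
      truth$de_sign[idx] <- sample(c(-1L, 1L), spec$n_de, replace = TRUE)
    }
    n_cyt <- round(spec$frac_cytoplasmic * n_gene)
    n_nuc <- round(spec$frac_nuclear * n_gene)
    loc_idx <- sample.int(n_gene, n_cyt + n_nuc)
    truth$loc_log2_ratio[loc_idx[seq_len(n_cyt)]] <- spec$loc_log2_ratio
    truth$loc_log2_ratio[loc_idx[n_cyt + seq_len(n_nuc)]] <- -spec$loc_log2_ratio

    write_synthetic_gtf(genes, gtf_path)
    list(annotation = annot, truth = truth, gtf = gtf_path)
  })
}

write_synthetic_gtf <- function(genes, path) {
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  attr_str <- sprintf(
    'gene_id "%s"; gene_type "%s"; gene_name "%s";',
    genes$gene_id, genes$biotype, genes$gene_name)
  gene_lines <- sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        genes$chrom, genes$start, genes$end, genes$strand,
                        attr_str)
  exon_lines <- sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s",
                        genes$chrom, genes$start, genes$end, genes$strand,
                        attr_str)
  lines <- c("##description: synthetic single-exon annotation",
             as.vector(rbind(gene_lines, exon_lines)))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate negative-binomial count matrices
#'
#' Baseline gene abundances are drawn log-normally (log2 of the TPM-like
#' rate ~ Normal(4, 1.5)). Per stage, genes planted as specific to that
#' stage have their rate multiplied by `fold_spec`. Two additional
#' condition matrices (`cond_a`, `cond_b`) realize the planted
#' differential-expression program: genes with `de_sign != 0` are
#' multiplied by `2^(de_sign * lfc_de)` in condition B. Expected counts
#' allocate a library of 2e6 fragments proportionally to rate times gene
#' length; observed counts are negative binomial with the spec's
#' dispersion.
#'
#' @param spec A [synthetic_spec()].
#' @param truth Ground-truth table from [make_annotation()].
#' @return List with `stages` (list of counts [expression_matrix()],
#'   one per stage, `n_reps` columns each), `cond_a`, `cond_b` (counts
#'   matrices for the two-condition comparison), and `base_log2_rate`
#'   (the drawn baselines).
#' @export
make_counts <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- nrow(truth)
  len_kb <- truth$length_nt / 1000
  depth <- 2e6
  withr::with_seed(spec$seed + 1L, {
    base_log2 <- stats::rnorm(n, mean = 4, sd = 1.5)
    base_rate <- 2^base_log2
    draw <- function(rate, label) {
      w <- rate * len_kb
      mu <- depth * w / sum(w)
      m <- matrix(stats::rnbinom(n * spec$n_reps,
                                 mu = rep(mu, spec$n_reps),
                                 size = 1 / spec$nb_dispersion),
                  nrow = n,
                  dimnames = list(truth$gene_id,
                                  paste0(label, "_rep", seq_len(spec$n_reps))))
      expression_matrix(m, unit = "counts",
                        gene_lengths = stats::setNames(truth$length_nt,
                                                       truth$gene_id))
    }
    stages <- lapply(seq_len(spec$n_stages), function(s) {
      boost <- ifelse(!is.na(truth$spec_stage) & truth$spec_stage == s,
                      spec$fold_spec, 1)
      draw(base_rate * boost, paste0("S", s))
    })
    names(stages) <- paste0("S", seq_len(spec$n_stages))
    cond_a <- draw(base_rate, "condA")
    cond_b <- draw(base_rate * 2^(truth$de_sign * spec$lfc_de), "condB")
    list(stages = stages, cond_a = cond_a, cond_b = cond_b,
         base_log2_rate = base_log2)
  })
}

#' Simulate a fractionated-expression table
#'
#' For each gene a base FPKM is drawn log-normally; the nuclear elution
#' (NE) and nuclear insoluble (NM) fractions sit at the base level while
#' the cytoplasmic elution (CE) fraction is shifted by the planted
#' cytoplasm:nucleus log2 ratio, so that in the noise-free limit
#' `log2(CE/NE) = log2(CE/NM) = loc_log2_ratio` and the derived CN.RCI
#' equals exactly twice the planted ratio. Each fraction is then
#' perturbed by independent multiplicative noise `2^N(0, noise_sd)`.
#'
#' @param spec A [synthetic_spec()].
#' @param truth Ground-truth table from [make_annotation()] (only
#'   `gene_id` and `loc_log2_ratio` are used, so a hand-built table with
#'   arbitrary planted ratios also works).
#' @return data.frame with columns `gene_id`, `CE`, `NE`, `NM`.
#' @export
make_fractions <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- nrow(truth)
  withr::with_seed(spec$seed + 2L, {
    base <- 2^stats::rnorm(n, mean = 4, sd = 1)
    noise <- function() 2^stats::rnorm(n, 0, spec$noise_sd)
    data.frame(
      gene_id = truth$gene_id,
      CE = base * 2^truth$loc_log2_ratio * noise(),
      NE = base * noise(),
      NM = base * noise(),
      stringsAsFactors = FALSE
    )
  })
}

#' Write a complete synthetic study bundle to disk
#'
#' Materializes everything the pipeline consumes: the GTF, per-stage and
#' per-condition count TSVs, a gene-length TSV, the fraction TSV, a
#' sample-to-stage map, and the ground-truth table.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths plus the in-memory `truth` table.
#' @export
simulate_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- make_annotation(spec, gtf_path = file.path(dir, "annotation.gtf"))
  cnt <- make_counts(spec, ann$truth)
  frac <- make_fractions(spec, ann$truth)

  stage_mats <- lapply(cnt$stages, function(em) em$values)
  all_stage <- do.call(cbind, stage_mats)
  stage_counts <- file.path(dir, "stage_counts.tsv")
  write_expression_tsv(expression_matrix(all_stage, "counts",
                                         cnt$stages[[1]]$gene_lengths),
                       stage_counts)
  groups <- data.frame(
    sample_id = colnames(all_stage),
    group = sub("_rep\\d+$", "", colnames(all_stage)),
    stringsAsFactors = FALSE
  )
  paths <- list(
    gtf = ann$gtf,
    stage_counts = stage_counts,
    counts_a = file.path(dir, "counts_condA.tsv"),
    counts_b = file.path(dir, "counts_condB.tsv"),
    lengths = file.path(dir, "gene_lengths.tsv"),
    fractions = file.path(dir, "fractions.tsv"),
    groups = file.path(dir, "sample_groups.tsv"),
    truth_tsv = file.path(dir, "truth.tsv")
  )
  write_expression_tsv(cnt$cond_a, paths$counts_a)
  write_expression_tsv(cnt$cond_b, paths$counts_b)
  write_tsv_plain(data.frame(gene_id = ann$truth$gene_id,
                             length_nt = ann$truth$length_nt), paths$lengths)
  write_tsv_plain(frac, paths$fractions)
  write_tsv_plain(groups, paths$groups)
  write_tsv_plain(ann$truth, paths$truth_tsv)
  c(paths, list(truth = ann$truth))
}
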