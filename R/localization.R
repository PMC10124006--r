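#' Cytoplasm/nucleus relative concentration index
#'
#' Computes `CN.RCI = log2(CE/NE) + log2(CE/NM)` from FPKM in the three
#' fractionation components: cytoplasmic elution (CE), nuclear elution
#' (NE), and nuclear insoluble (NM). Positive values indicate cytoplasmic
#' enrichment, negative values nuclear retention; a gene present at equal
#' concentration in all three fractions scores 0.
#'
#' A pseudocount is added to every fraction before the ratios so that
#' zeros stay finite; genes whose maximal fraction FPKM falls below
#' `min_fpkm` are retained but flagged `passed_filter = FALSE`, and are
#' excluded from the category comparisons in
#' [compare_rci_by_category()].
#'
#' @param frac data.frame with columns `gene_id`, `CE`, `NE`, `NM`
#'   (FPKM, non-negative). Replicate fraction samples should be averaged
#'   beforehand, e.g. with [average_fractions()].
#' @param pseudocount Added to all three fractions (FPKM, default 0.01).
#' @param min_fpkm Expression filter on the maximal fraction (default 0.5).
#' @return data.frame with columns `gene_id`, `cn_rci`, `passed_filter`.
#' @examples
#' compute_rci(data.frame(gene_id = "g", CE = 8, NE = 2, NM = 4),
#'             pseudocount = 1e-9)  # log2(4) + log2(2) = 3
#' @export
compute_rci <- function(frac, pseudocount = 0.01, min_fpkm = 0.5) {
  required <- c("gene_id", "CE", "NE", "NM")
  missing <- setdiff(required, names(frac))
  if (length(missing) > 0) {
    stop("fraction table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be positive")
  }
  if (!is.numeric(min_fpkm) || min_fpkm < 0) {
    stop("min_fpkm must be non-negative")
  }
  vals <- as.matrix(frac[, c("CE", "NE", "NM")])
  if (anyNA(vals) || any(vals < 0)) {
    stop("fraction FPKM values must be non-negative and non-missing")
  }
  ce <- vals[, "CE"] + pseudocount
  ne <- vals[, "NE"] + pseudocount
  nm <- vals[, "NM"] + pseudocount
  data.frame(
    gene_id = frac$gene_id,
    cn_rci = log2(ce / ne) + log2(ce / nm),
    passed_filter = apply(vals, 1, max) >= min_fpkm,
    stringsAsFactors = FALSE
  )
}

#' Average replicate samples into one FPKM per fraction
#'
#' The localization index is defined per fractionation component, not per
#' replicate, so replicate columns of the same fraction are collapsed to
#' their mean before [compute_rci()].
#'
#' @param em An [expression_matrix()] in FPKM.
#' @param fraction_map Named character vector mapping each sample id to
#'   one of `"CE"`, `"NE"`, `"NM"`.
#' @return data.frame with columns `gene_id`, `CE`, `NE`, `NM`.
#' @export
average_fractions <- function(em, fraction_map) {
  samples <- colnames(em$values)
  unmapped <- setdiff(samples, names(fraction_map))
  if (length(unmapped) > 0) {
    stop("samples not mapped to a fraction: ", paste(unmapped, collapse = ", "))
  }
  bad <- setdiff(unique(fraction_map[samples]), c("CE", "NE", "NM"))
  if (length(bad) > 0) {
    stop("unknown fraction labels: ", paste(bad, collapse = ", "))
  }
  comp <- function(f) {
    cols <- samples[fraction_map[samples] == f]
    if (length(cols) == 0) stop("no samples mapped to fraction ", f)
    rowMeans(em$values[, cols, drop = FALSE])
  }
  data.frame(gene_id = rownames(em$values),
             CE = comp("CE"), NE = comp("NE"), NM = comp("NM"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare RCI distributions between lncRNA categories
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests of the CN.RCI
#' distribution of desert lncRNAs against overlapped lncRNAs, proximal
#' lncRNAs, and (optionally) protein-coding genes. Only genes passing the
#' expression filter enter the comparison. The rank test is reported with
#' group sizes and medians; being rank-based, its p-value is invariant to
#' monotone transforms of the index.
#'
#' @param rci data.frame from [compute_rci()] for lncRNAs.
#' @param classes data.frame from [classify_lncrnas()].
#' @param pcg_rci Optional data.frame from [compute_rci()] for
#'   protein-coding genes.
#' @return data.frame with one row per comparison: `comparison`,
#'   `n_desert`, `n_other`, `median_desert`, `median_other`, `statistic`,
#'   `p_value`.
#' @export
compare_rci_by_category <- function(rci, classes, pcg_rci = NULL) {
  merged <- merge(rci[rci$passed_filter, c("gene_id", "cn_rci")],
                  classes[, c("gene_id", "category")], by = "gene_id")
  groups <- split(merged$cn_rci, merged$category)
  desert <- groups[["desert"]]
  check_group <- function(x, label) {
    if (is.null(x) || length(x) < 2) {
      stop("group '", label, "' has fewer than 2 genes after filtering")
    }
    x
  }
  desert <- check_group(desert, "desert")
  others <- list(overlapped = check_group(groups[["overlapped"]], "overlapped"),
                 proximal = check_group(groups[["proximal"]], "proximal"))
  if (!is.null(pcg_rci)) {
    others$PCG <- check_group(pcg_rci$cn_rci[pcg_rci$passed_filter], "PCG")
  }
  rows <- lapply(names(others), function(nm) {
    other <- others[[nm]]
    wt <- stats::wilcox.test(desert, other, alternative = "two.sided",
                             exact = FALSE, correct = TRUE)
    data.frame(comparison = paste0("desert_vs_", nm),
               n_desert = length(desert), n_other = length(other),
               median_desert = stats::median(desert),
               median_other = stats::median(other),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
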