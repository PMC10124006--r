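#' Construct a differential-expression result table
#'
#' Normalizes an imported table (from any external engine, or from
#' [simple_de()]) into the canonical per-gene form: one row per gene with
#' a log2 fold change and a p-value, plus the labels of the two compared
#' conditions. Fold changes are oriented b vs a (positive = higher in
#' `condition_b`).
#'
#' @param df data.frame with columns `gene_id`, `log2fc`, `p_value`.
#' @param condition_a,condition_b Labels of the compared conditions.
#' @param method Free-text description of the engine that produced the
#'   statistics, kept in the table attributes so downstream reports are
#'   self-describing.
#' @return data.frame of class `de_table`.
#' @export
de_table <- function(df, condition_a = "A", condition_b = "B",
                     method = "external") {
  required <- c("gene_id", "log2fc", "p_value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("DE table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicated gene_id in DE table")
  }
  if (anyNA(df$p_value) || any(df$p_value < 0 | df$p_value > 1)) {
    stop("p_value must lie in [0, 1]")
  }
  out <- df[, required]
  attr(out, "conditions") <- c(a = condition_a, b = condition_b)
  attr(out, "method") <- method
  class(out) <- c("de_table", "data.frame")
  out
}

#' Threshold filter for differential-expression calls
#'
#' Applies the cutoff `p_value < p_max` and `|log2fc| > lfc_min` with
#' strict inequalities: a gene at exactly the p-value or fold-change
#' threshold is not called. Direction is `up` for positive log2
#' fold change, `down` otherwise. The filter is idempotent and monotone:
#' relaxing either threshold never removes a call.
#'
#' @param table A [de_table()] (or data.frame with the same columns).
#' @param p_max P-value cutoff (default 0.05, on the raw p-value).
#' @param lfc_min Absolute log2 fold-change cutoff (default 1.0).
#' @param adjust If `TRUE`, Benjamini-Hochberg-adjust p-values before
#'   thresholding; the default filters raw p-values.
#' @return data.frame with columns `gene_id`, `log2fc`, `p_value`,
#'   `direction`, `passed`.
#' @export
de_filter <- function(table, p_max = 0.05, lfc_min = 1.0, adjust = FALSE) {
  if (p_max <= 0 || lfc_min <= 0) {
    stop("thresholds must be positive")
  }
  if (anyNA(table$p_value) || any(table$p_value < 0 | table$p_value > 1)) {
    stop("p_value must lie in [0, 1]")
  }
  p <- if (adjust) stats::p.adjust(table$p_value, method = "BH") else table$p_value
  data.frame(
    gene_id = table$gene_id,
    log2fc = table$log2fc,
    p_value = table$p_value,
    direction = ifelse(table$log2fc > 0, "up", "down"),
    passed = p < p_max & abs(table$log2fc) > lfc_min,
    stringsAsFactors = FALSE
  )
}

#' Positional-category breakdown of differentially expressed lncRNAs
#'
#' Counts passing calls per positional category and the fraction of all
#' differentially expressed lncRNAs each category makes up; fractions sum
#' to 1.
#'
#' @param calls data.frame from [de_filter()] (only rows with
#'   `passed = TRUE` are counted).
#' @param classes data.frame from [classify_lncrnas()]. Every passing
#'   gene must be classified.
#' @return data.frame with columns `category`, `count`, `fraction`.
#' @export
de_category_breakdown <- function(calls, classes) {
  de_ids <- calls$gene_id[calls$passed]
  if (length(de_ids) == 0) {
    stop("no passing differential-expression calls to break down")
  }
  missing <- setdiff(de_ids, classes$gene_id)
  if (length(missing) > 0) {
    stop("DE genes without a positional classification: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  cat_of <- stats::setNames(classes$category, classes$gene_id)
  lev <- c("overlapped", "proximal", "desert")
  tab <- table(factor(cat_of[de_ids], levels = lev))
  data.frame(category = lev, count = as.integer(tab),
             fraction = as.numeric(tab) / length(de_ids),
             stringsAsFactors = FALSE)
}

#' Macro-average category fractions across datasets
#'
#' The mean of per-dataset fractions (each dataset weighted equally,
#' regardless of how many genes it calls), the convention for reporting
#' an average proportion over several cell lines.
#'
#' @param breakdowns List of data.frames from [de_category_breakdown()].
#' @return data.frame with columns `category`, `fraction`.
#' @export
macro_average_breakdown <- function(breakdowns) {
  if (length(breakdowns) == 0) {
    stop("no breakdowns to average")
  }
  lev <- c("overlapped", "proximal", "desert")
  fr <- vapply(breakdowns, function(b) {
    stats::setNames(b$fraction, b$category)[lev]
  }, numeric(3))
  data.frame(category = lev, fraction = rowMeans(fr),
             stringsAsFactors = FALSE)
}

#' Desk-scale two-group differential test
#'
#' A deliberately minimal stand-in for a full count-based engine: counts
#' are converted to TPM, log2(TPM + 1) transformed, and each gene is
#' tested with a two-sided Welch t-test between conditions; the log2
#' fold change is the mean difference (b minus a) on that scale. The
#' method name is recorded in the returned table's attributes so results
#' are never mistaken for a negative-binomial engine's. Genes with zero
#' variance in both groups get p = 1 when the means agree (e.g. all-zero
#' genes) and p = 0 when they differ.
#'
#' @param counts_a,counts_b [expression_matrix()] objects in counts with
#'   identical genes and lengths; at least 2 replicate columns each.
#' @param condition_a,condition_b Condition labels for the table.
#' @return A [de_table()] with `method = "welch_t_log2_tpm1"`.
#' @export
simple_de <- function(counts_a, counts_b,
                      condition_a = "A", condition_b = "B") {
  stop_unless_counts(counts_a)
  stop_unless_counts(counts_b)
  if (!identical(rownames(counts_a$values), rownames(counts_b$values))) {
    stop("both conditions must cover the same genes in the same order")
  }
  if (ncol(counts_a$values) < 2 || ncol(counts_b$values) < 2) {
    stop("at least 2 replicates per condition are required")
  }
  la <- log2(counts_to_tpm(counts_a)$values + 1)
  lb <- log2(counts_to_tpm(counts_b)$values + 1)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
  lfc <- mb - ma
  se2 <- va / na + vb / nb
  p <- numeric(length(lfc))
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)
  if (any(!degenerate)) {
    i <- !degenerate
    tstat <- lfc[i] / sqrt(se2[i])
    df <- se2[i]^2 / ((va[i] / na)^2 / (na - 1) + (vb[i] / nb)^2 / (nb - 1))
    p[i] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  de_table(data.frame(gene_id = rownames(la), log2fc = lfc, p_value = p,
                      stringsAsFactors = FALSE, row.names = NULL),
           condition_a, condition_b, method = "welch_t_log2_tpm1")
}

#' Compare two differential-expression tables
#'
#' Filters both tables at the same thresholds, intersects the calls, and
#' computes the Pearson correlation (with two-sided p-value) of log2 fold
#' changes over the union of called genes restricted to genes present in
#' both tables — the standard way of asking whether two perturbations
#' move the same genes the same way.
#'
#' @param t1,t2 [de_table()] objects.
#' @inheritParams de_filter
#' @return List with elements `overlap` (gene ids called in both),
#'   `n_de_1`, `n_de_2`, `n_overlap`, `n_union`, `pearson_r`,
#'   `pearson_p`.
#' @export
compare_de_tables <- function(t1, t2, p_max = 0.05, lfc_min = 1.0) {
  c1 <- de_filter(t1, p_max, lfc_min)
  c2 <- de_filter(t2, p_max, lfc_min)
  shared <- intersect(t1$gene_id, t2$gene_id)
  de1 <- c1$gene_id[c1$passed]
  de2 <- c2$gene_id[c2$passed]
  union_de <- intersect(union(de1, de2), shared)
  if (length(union_de) < 3) {
    stop("fewer than 3 shared differentially expressed genes; ",
         "correlation not computable")
  }
  l1 <- stats::setNames(t1$log2fc, t1$gene_id)[union_de]
  l2 <- stats::setNames(t2$log2fc, t2$gene_id)[union_de]
  ct <- stats::cor.test(l1, l2, method = "pearson", alternative = "two.sided")
  list(overlap = sort(intersect(de1, de2)),
       n_de_1 = length(de1), n_de_2 = length(de2),
       n_overlap = length(intersect(de1, de2)),
       n_union = length(union_de),
       pearson_r = unname(ct$estimate), pearson_p = ct$p.value)
}
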