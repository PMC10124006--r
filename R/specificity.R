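#' Collapse a TPM matrix to per-stage mean profiles
#'
#' Replicates belonging to the same stage or cell type are averaged, so
#' that specificity scoring works on one mean abundance per stage.
#'
#' @param em An [expression_matrix()] in TPM.
#' @param sample_groups Named character vector mapping each sample id to
#'   a stage/group label. Stage column order follows the first appearance
#'   of each label in the sample ordering.
#' @return Numeric matrix, genes x stages, of mean TPM.
#' @export
stage_means <- function(em, sample_groups) {
  samples <- colnames(em$values)
  unmapped <- setdiff(samples, names(sample_groups))
  if (length(unmapped) > 0) {
    stop("samples without a group label: ", paste(unmapped, collapse = ", "))
  }
  labels <- sample_groups[samples]
  stages <- unique(labels)
  out <- vapply(stages, function(s) {
    rowMeans(em$values[, samples[labels == s], drop = FALSE])
  }, numeric(nrow(em$values)))
  dimnames(out) <- list(rownames(em$values), stages)
  out
}

#' Stage-specificity score from Jensen-Shannon divergence
#'
#' A gene's stage profile is normalized to a probability vector `p` over
#' stages; for each stage `s` the candidate score is
#' `1 - sqrt(JSD(p, e_s))` with `e_s` the unit vector concentrated on
#' that stage and JSD the base-2 Jensen-Shannon divergence. The
#' specificity score is the maximum over stages and the peak stage the
#' argmax (ties resolved to the first stage in column order). The score
#' lies in \[0, 1\], equals 1 exactly when a single stage carries all
#' expression, and is invariant to global rescaling of the profile.
#'
#' @param profiles Numeric matrix genes x stages (>= 2 stages) of mean
#'   TPM, as from [stage_means()], or a single named numeric vector.
#' @return data.frame with columns `gene_id`, `spec_score`, `peak_stage`.
#'   All-zero profiles are dropped with a warning.
#' @examples
#' stage_specificity(rbind(g1 = c(ES = 0, DE = 12, PP = 0)))
#' @export
stage_specificity <- function(profiles) {
  profiles <- as_profile_matrix(profiles)
  n_stage <- ncol(profiles)
  zero <- rowSums(profiles) == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with all-zero profiles skipped")
    profiles <- profiles[!zero, , drop = FALSE]
  }
  if (nrow(profiles) == 0) {
    return(data.frame(gene_id = character(), spec_score = numeric(),
                      peak_stage = character(), stringsAsFactors = FALSE))
  }
  p <- profiles / rowSums(profiles)
  # JSD(p, e_s) column by column, vectorized over genes:
  #   m = p/2 except m_s = (p_s + 1)/2
  #   JSD = 0.5 * sum_i p_i log2(p_i / m_i) + 0.5 * log2(1 / m_s)
  scores <- matrix(NA_real_, nrow(p), n_stage)
  for (s in seq_len(n_stage)) {
    m_s <- (p[, s] + 1) / 2
    # KL(p || m): entries i != s contribute p_i log2(p_i / (p_i/2)) = p_i,
    # summing to 1 - p_s; entry s contributes p_s log2(p_s / m_s).
    off_peak <- 1 - p[, s]
    peak <- ifelse(p[, s] > 0, p[, s] * log2(p[, s] / m_s), 0)
    # KL(e_s || m) collapses to log2(1 / m_s)
    jsd_s <- 0.5 * (off_peak + peak) + 0.5 * log2(1 / m_s)
    scores[, s] <- 1 - sqrt(pmax(jsd_s, 0))
  }
  best <- max.col(scores, ties.method = "first")
  data.frame(
    gene_id = rownames(p),
    spec_score = scores[cbind(seq_len(nrow(p)), best)],
    peak_stage = colnames(p)[best],
    stringsAsFactors = FALSE
  )
}

#' Normalized Difference of stage expression
#'
#' `ND = (E1 - E2) / (E1 + E2)` where E1 and E2 are a gene's largest and
#' second-largest stage means. ND is 1 when only one stage is expressed,
#' 0 when the top two stages tie, and invariant to global rescaling.
#'
#' @inheritParams stage_specificity
#' @return data.frame with columns `gene_id`, `nd`. All-zero profiles are
#'   dropped with a warning.
#' @export
normalized_difference <- function(profiles) {
  profiles <- as_profile_matrix(profiles)
  if (ncol(profiles) < 2) {
    stop("at least 2 stages are required for the Normalized Difference")
  }
  zero <- rowSums(profiles) == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with all-zero profiles skipped")
    profiles <- profiles[!zero, , drop = FALSE]
  }
  top2 <- t(apply(profiles, 1, function(x) sort(x, decreasing = TRUE)[1:2]))
  data.frame(
    gene_id = rownames(profiles),
    nd = (top2[, 1] - top2[, 2]) / (top2[, 1] + top2[, 2]),
    stringsAsFactors = FALSE
  )
}

#' Specificity summary: JSD score, peak stage and Normalized Difference
#'
#' Convenience wrapper combining [stage_specificity()] and
#' [normalized_difference()]; genes whose peak stage mean falls below
#' `low_conf_tpm` are flagged low-confidence but still scored.
#'
#' @inheritParams stage_specificity
#' @param low_conf_tpm Peak-TPM floor below which a gene is flagged
#'   (default 1 TPM).
#' @return data.frame with columns `gene_id`, `spec_score`, `peak_stage`,
#'   `nd`, `low_confidence`.
#' @export
specificity_scores <- function(profiles, low_conf_tpm = 1) {
  profiles <- as_profile_matrix(profiles)
  ss <- stage_specificity(profiles)
  nd <- normalized_difference(profiles)
  out <- merge(ss, nd, by = "gene_id", sort = FALSE)
  peak <- apply(profiles[out$gene_id, , drop = FALSE], 1, max)
  out$low_confidence <- peak < low_conf_tpm
  out
}

#' Rank groups by median expression per gene
#'
#' For each gene, computes the median TPM within every sample group
#' (tissue, cell type, ...), sorts groups by decreasing median and
#' returns the top `top_k`. Median ties are broken lexicographically by
#' group name.
#'
#' @param em An [expression_matrix()] in TPM.
#' @param sample_groups Named character vector mapping sample id to group.
#' @param top_k Number of top groups to keep per gene (default 8).
#' @return data.frame in long form: `gene_id`, `rank`, `group`,
#'   `median_tpm`.
#' @export
group_expression_ranking <- function(em, sample_groups, top_k = 8) {
  if (!is.numeric(top_k) || length(top_k) != 1 || top_k < 1) {
    stop("top_k must be a positive integer")
  }
  samples <- colnames(em$values)
  unmapped <- setdiff(samples, names(sample_groups))
  if (length(unmapped) > 0) {
    stop("samples without a group label: ", paste(unmapped, collapse = ", "))
  }
  labels <- sample_groups[samples]
  groups <- sort(unique(labels))
  med <- vapply(groups, function(g) {
    apply(em$values[, samples[labels == g], drop = FALSE], 1, stats::median)
  }, numeric(nrow(em$values)))
  med <- matrix(med, nrow = nrow(em$values),
                dimnames = list(rownames(em$values), groups))
  k <- min(top_k, length(groups))
  rows <- lapply(seq_len(nrow(med)), function(i) {
    # groups are in lexicographic order, so a stable sort on -median
    # breaks ties by name
    ord <- order(-med[i, ], groups)[seq_len(k)]
    data.frame(gene_id = rownames(med)[i], rank = seq_len(k),
               group = groups[ord], median_tpm = unname(med[i, ord]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

as_profile_matrix <- function(profiles) {
  if (is.null(dim(profiles))) {
    profiles <- matrix(profiles, nrow = 1,
                       dimnames = list("gene", names(profiles)))
  }
  profiles <- as.matrix(profiles)
  if (anyNA(profiles) || any(profiles < 0)) {
    stop("stage profiles must be non-negative and non-missing")
  }
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("gene", seq_len(nrow(profiles)))
  }
  if (is.null(colnames(profiles))) {
    colnames(profiles) <- paste0("stage", seq_len(ncol(profiles)))
  }
  profiles
}
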