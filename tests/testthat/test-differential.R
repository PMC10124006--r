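test_that("the DE filter applies strict inequalities at both thresholds", {
  tab <- de_table(data.frame(
    gene_id = paste0("g", 1:6),
    log2fc = c(1.01, 1.01, -2.5, 0.99, 3.0, -1.0),
    p_value = c(0.049, 0.05, 0.01, 0.001, 0.2, 0.049)))
  calls <- de_filter(tab)
  got <- setNames(calls$passed, calls$gene_id)
  # g1 passes; g2 sits exactly at p = 0.05; g4 at |lfc| < 1; g6 at |lfc| = 1
  expect_equal(unname(got), c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(calls$passed), 2)
  dir <- setNames(calls$direction, calls$gene_id)
  expect_equal(dir[["g1"]], "up")
  expect_equal(dir[["g3"]], "down")
  expect_error(de_filter(tab, p_max = 0), "positive")
  expect_error(
    de_table(data.frame(gene_id = "g", log2fc = 0, p_value = 1.2)),
    "\\[0, 1\\]")
})

test_that("the DE filter is idempotent and monotone in both thresholds", {
  withr::with_seed(13, {
    tab <- de_table(data.frame(gene_id = sprintf("g%03d", 1:300),
                               log2fc = rnorm(300, sd = 2),
                               p_value = runif(300)))
    strict <- de_filter(tab, p_max = 0.01, lfc_min = 1.5)
    expect_identical(de_filter(strict, p_max = 0.01, lfc_min = 1.5)$passed,
                     strict$passed)
    for (p_max in c(0.05, 0.2)) {
      for (lfc_min in c(1.0, 0.5)) {
        relaxed <- de_filter(tab, p_max = p_max, lfc_min = lfc_min)
        expect_true(all(relaxed$passed[strict$passed]))
      }
    }
    # BH-adjusted mode is strictly more conservative than raw filtering
    adj <- de_filter(tab, adjust = TRUE)
    raw <- de_filter(tab)
    expect_true(all(raw$passed[adj$passed]))
  })
})

test_that("category breakdown fractions are exact and sum to one", {
  classes <- data.frame(
    gene_id = paste0("L", 1:10),
    category = c(rep("overlapped", 5), rep("proximal", 3), rep("desert", 2)))
  calls <- data.frame(gene_id = paste0("L", 1:10), passed = TRUE)
  bd <- de_category_breakdown(calls, classes)
  expect_equal(setNames(bd$fraction, bd$category),
               c(overlapped = 0.5, proximal = 0.3, desert = 0.2))
  expect_equal(sum(bd$fraction), 1)
  calls$gene_id[1] <- "unclassified"
  expect_error(de_category_breakdown(calls, classes), "unclassified")
})

test_that("macro-averaging weighs datasets equally", {
  mk <- function(f) data.frame(category = c("overlapped", "proximal", "desert"),
                               fraction = c(1 - f - 0.3, 0.3, f))
  avg <- macro_average_breakdown(list(mk(0.10), mk(0.20), mk(0.20)))
  expect_equal(avg$fraction[avg$category == "desert"], mean(c(0.1, 0.2, 0.2)),
               tolerance = 1e-12)  # 0.1667
  expect_equal(sum(avg$fraction), 1)
})

test_that("simple_de is null on identical inputs and degenerate on all-zero genes", {
  counts <- random_counts(17, n_gene = 30, n_sample = 3)
  zero_row <- matrix(0, 1, 3, dimnames = list("gzero", colnames(counts$values)))
  vals <- rbind(counts$values, zero_row)
  em <- expression_matrix(vals, "counts",
                          gene_lengths = c(counts$gene_lengths, gzero = 1000))
  tab <- simple_de(em, em)
  expect_true(all(tab$log2fc == 0))
  expect_equal(tab$p_value[tab$gene_id == "gzero"], 1)
  expect_equal(tab$log2fc[tab$gene_id == "gzero"], 0)
  expect_equal(attr(tab, "method"), "welch_t_log2_tpm1")
  expect_error(simple_de(expression_matrix(vals[, 1, drop = FALSE], "counts",
                                           gene_lengths = em$gene_lengths),
                         em), "2 replicates")
})

test_that("simple_de recovers a planted fold change", {
  spec <- synthetic_spec(seed = 23, n_pcg = 150, n_lnc = 50, n_reps = 5,
                         n_de = 40, lfc_de = 2, nb_dispersion = 0.05)
  ann <- make_annotation(spec)
  cnt <- make_counts(spec, ann$truth)
  tab <- simple_de(cnt$cond_a, cnt$cond_b)
  planted <- ann$truth$gene_id[ann$truth$de_sign != 0]
  sign_of <- setNames(ann$truth$de_sign, ann$truth$gene_id)
  est <- setNames(tab$log2fc, tab$gene_id)[planted]
  expect_true(all(abs(est * sign_of[planted] - 2) < 0.75))
  calls <- de_filter(tab)
  expect_gte(mean(calls$passed[calls$gene_id %in% planted]), 0.9)
})

test_that("comparing a table with itself and with its negation is exact", {
  withr::with_seed(31, {
    tab <- de_table(data.frame(gene_id = sprintf("g%03d", 1:100),
                               log2fc = rnorm(100, sd = 2),
                               p_value = runif(100, 0, 0.2)))
    same <- compare_de_tables(tab, tab)
    expect_equal(same$pearson_r, 1, tolerance = 1e-12)
    expect_equal(same$n_overlap, same$n_de_1)
    neg <- tab
    neg$log2fc <- -neg$log2fc
    flipped <- compare_de_tables(tab, de_table(as.data.frame(neg)))
    expect_equal(flipped$pearson_r, -1, tolerance = 1e-12)
    few <- de_table(data.frame(gene_id = c("g001", "g002"),
                               log2fc = c(2, 2), p_value = c(0.01, 0.01)))
    expect_error(compare_de_tables(few, few), "fewer than 3")
  })
})

test_that("a shared co-regulated module yields the planted correlation", {
  withr::with_seed(41, {
    n <- 500
    rho <- 0.8  # target correlation between the two fold-change vectors
    z <- rnorm(n, sd = 2)
    lfc1 <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n, sd = 2)
    lfc2 <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n, sd = 2)
    ids <- sprintf("g%03d", 1:n)
    t1 <- de_table(data.frame(gene_id = ids, log2fc = lfc1,
                              p_value = runif(n, 0, 0.04)))
    t2 <- de_table(data.frame(gene_id = ids, log2fc = lfc2,
                              p_value = runif(n, 0, 0.04)))
    res <- compare_de_tables(t1, t2)
    expect_gt(res$pearson_r, 0.7)
    expect_lt(res$pearson_r, 0.9)
    expect_lt(res$pearson_p, 1e-10)
  })
})
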