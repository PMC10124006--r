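#' Jensen-Shannon divergence between two probability vectors
#'
#' Base-2 Jensen-Shannon divergence, the symmetrized Kullback-Leibler
#' divergence to the midpoint distribution. Zero entries follow the
#' convention 0 * log(0) = 0. For base-2 logarithms the JSD lies in
#' \[0, 1\] and its square root is a metric.
#'
#' @param p,q Non-negative numeric vectors of equal length summing to 1
#'   (renormalized internally if they do not).
#' @return A single number in \[0, 1\].
#' @examples
#' jensen_shannon(c(1, 0), c(0, 1))   # 1: disjoint support
#' jensen_shannon(c(.5, .5), c(.5, .5)) # 0: identical
#' @export
jensen_shannon <- function(p, q) {
  if (length(p) != length(q)) {
    stop("p and q must have the same length")
  }
  if (any(p < 0) || any(q < 0)) {
    stop("probability vectors must be non-negative")
  }
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# write.table with the conventions used for every pipeline TSV:
# tab-separated, no quoting, no row names -> byte-stable across reruns
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
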