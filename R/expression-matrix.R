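#' Construct an expression matrix with a unit tag
#'
#' Lightweight container for a genes-by-samples abundance table. The unit
#' tag records whether the values are raw counts, TPM or FPKM so that
#' normalization functions can refuse inputs that are already normalized.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). No negative entries.
#' @param unit One of `"counts"`, `"TPM"`, `"FPKM"`.
#' @param gene_lengths Optional numeric vector of effective gene lengths in
#'   nucleotides, either named by gene id or in row order. Required (and
#'   strictly positive) before length-dependent normalization.
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `unit`, `gene_lengths`.
#' @examples
#' m <- matrix(c(10, 20, 5, 0), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' em <- expression_matrix(m, "counts", gene_lengths = c(g1 = 1000, g2 = 2000))
#' counts_to_tpm(em)$values
#' @export
expression_matrix <- function(values, unit = c("counts", "TPM", "FPKM"),
                              gene_lengths = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric")
  }
  if (anyNA(values)) {
    stop("expression values must not contain NA")
  }
  if (any(values < 0)) {
    stop("expression values must be non-negative")
  }
  if (is.null(rownames(values))) {
    stop("values must carry gene ids as rownames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated gene ids in expression matrix")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  }
  if (!is.null(gene_lengths)) {
    if (!is.null(names(gene_lengths))) {
      missing <- setdiff(rownames(values), names(gene_lengths))
      if (length(missing) > 0) {
        stop("gene lengths missing for: ",
             paste(utils::head(missing, 5), collapse = ", "))
      }
      gene_lengths <- gene_lengths[rownames(values)]
    } else if (length(gene_lengths) != nrow(values)) {
      stop("gene_lengths must be named or match the number of genes")
    } else {
      names(gene_lengths) <- rownames(values)
    }
    if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0)) {
      stop("gene lengths must be finite and positive")
    }
  }
  structure(list(values = values, unit = unit, gene_lengths = gene_lengths),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]%s\n",
              nrow(x$values), ncol(x$values), x$unit,
              if (is.null(x$gene_lengths)) "" else ", with gene lengths"))
  print(utils::head(x$values, 5))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids
#' (column name `gene_id`). An optional two-column lengths table
#' (`gene_id`, `length_nt`) supplies effective gene lengths.
#'
#' @param path Path to the matrix TSV.
#' @param unit Unit tag for the values (see [expression_matrix()]).
#' @param lengths_path Optional path to a gene-length TSV.
#' @return An `expr_matrix`.
#' @export
read_expression_tsv <- function(path, unit = "counts", lengths_path = NULL) {
  df <- read_tsv_plain(path)
  if (!"gene_id" %in% names(df)) {
    stop("expression TSV must have a gene_id column: ", path)
  }
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- read_tsv_plain(lengths_path)
    if (!all(c("gene_id", "length_nt") %in% names(lt))) {
      stop("length TSV must have columns gene_id and length_nt: ", lengths_path)
    }
    lengths <- stats::setNames(lt$length_nt, lt$gene_id)
  }
  expression_matrix(m, unit = unit, gene_lengths = lengths)
}

#' Write an expression matrix to TSV
#'
#' @param em An `expr_matrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}
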