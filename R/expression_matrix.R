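#' Construct an expression matrix
#'
#' A genes-by-samples real-valued matrix with unique gene and sample
#' identifiers, the basic data container used throughout the package.
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   existing row names, or `gene_1 ...`).
#' @param sample_ids Character vector of unique sample identifiers (defaults
#'   to existing column names, or `sample_1 ...`).
#'
#' @return A numeric matrix of class `"expression_matrix"` with row and
#'   column names set to the identifiers.
#' @export
#'
#' @examples
#' X <- expression_matrix(matrix(rnorm(12), 4, 3))
#' dim(X)
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("expression matrix needs at least 2 genes and 2 samples")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values; ",
         "impute or filter before analysis")
  if (is.null(gene_ids))
    gene_ids <- rownames(values) %||% paste0("gene_", seq_len(nrow(values)))
  if (is.null(sample_ids))
    sample_ids <- colnames(values) %||% paste0("sample_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match number of rows")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match number of columns")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_expression_matrix <- function(x) {
  if (inherits(x, "expression_matrix")) return(x)
  expression_matrix(as.matrix(x))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}
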