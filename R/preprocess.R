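#' Merge two platforms' matrices on their shared genes
#'
#' Keeps only genes measured on both platforms (rows sorted
#' lexicographically by gene ID for determinism) and concatenates the
#' columns, first matrix's samples first.
#'
#' @param a,b Numeric genes x samples matrices with disjoint sample IDs.
#' @return The merged matrix restricted to the common genes.
#' @export
intersect_genes <- function(a, b) {
  assert_expression_matrix(a, "a")
  assert_expression_matrix(b, "b")
  if (any(colnames(a) %in% colnames(b)))
    stop_invalid("sample identifiers overlap between the two matrices")
  common <- sort(intersect(rownames(a), rownames(b)))
  if (length(common) == 0)
    stop_invalid("the two matrices share no gene identifiers")
  cbind(a[common, , drop = FALSE], b[common, , drop = FALSE])
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto a common reference distribution: the
#' element-wise mean of the column-sorted matrix.  Each value is replaced by
#' the reference value at its within-column rank; ties receive the mean of
#' the reference values at the tied positions.  This makes all columns share
#' one value multiset, removing additive platform/batch differences at the
#' distribution level while preserving within-sample ranks.
#'
#' @param m Numeric genes x samples matrix with finite values.
#' @return The normalized matrix, same dimensions and dimnames.
#' @export
quantile_normalize <- function(m) {
  assert_expression_matrix(m)
  ref <- rowMeans(apply(m, 2, sort, method = "quick"))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    v <- numeric(length(x))
    v[order(x)] <- ref
    # tied input values share the mean reference value of their positions
    out[, j] <- stats::ave(v, match(x, x), FUN = mean)
  }
  out
}
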