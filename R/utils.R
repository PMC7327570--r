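# Internal helpers shared across stages.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so stages do not perturb each other.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from a root seed
#'
#' Each pipeline stage draws its randomness from a seed derived
#' deterministically from one root seed and the stage name, so any stage can
#' be re-run in isolation and reproduce its in-pipeline output.
#'
#' @param root_seed Integer root seed.
#' @param stage Character stage label.
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(root_seed) %% 2146483647 + h) %% 2147483647)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

assert_expression_matrix <- function(m, arg = "matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop_invalid("%s must be a numeric matrix (genes x samples)", arg)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_invalid("%s must carry gene-ID rownames and sample-ID colnames", arg)
  if (anyDuplicated(rownames(m)))
    stop_invalid("%s has duplicated gene identifiers", arg)
  if (anyDuplicated(colnames(m)))
    stop_invalid("%s has duplicated sample identifiers", arg)
  if (!all(is.finite(m)))
    stop_invalid("%s contains non-finite values", arg)
  invisible(m)
}

assert_labels <- function(labels, m) {
  if (is.null(names(labels))) {
    if (length(labels) != ncol(m))
      stop_invalid("labels length (%d) differs from sample count (%d)",
                   length(labels), ncol(m))
    names(labels) <- colnames(m)
  }
  if (!all(colnames(m) %in% names(labels)))
    stop_invalid("labels do not cover all samples")
  labels <- labels[colnames(m)]
  factor(as.character(labels))
}

#' Read / write the tab-separated expression-matrix dialect
#'
#' Matrices are stored as TSV with gene identifiers in the first column and a
#' header row of sample identifiers; labels as a two-column TSV
#' (`sample_id`, `class`).
#'
#' @param path File path.
#' @return `read_expression_matrix()` returns a numeric genes x samples
#'   matrix; `read_labels()` a named character vector keyed by sample ID.
#' @name matrix_io
#' @export
read_expression_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  assert_expression_matrix(m)
}

#' @rdname matrix_io
#' @param m Numeric genes x samples matrix.
#' @export
write_expression_matrix <- function(m, path) {
  assert_expression_matrix(m)
  d <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_labels <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(d[[2]]), d[[1]])
}

#' @rdname matrix_io
#' @param labels Named vector of class labels keyed by sample ID.
#' @export
write_labels <- function(labels, path) {
  d <- data.frame(sample_id = names(labels), class = as.character(labels))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
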