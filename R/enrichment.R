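#' Build a gene-set collection
#'
#' @param sets Named list of character vectors of member gene IDs
#'   (duplicates within a set are dropped).
#' @param universe Background gene IDs (e.g. all genes entering the filter
#'   stage).  Set members outside the universe are ignored when sizing the
#'   hypergeometric margins.
#' @param descriptions Optional named character vector of set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  if (length(universe) == 0) stop_invalid("the universe is empty")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop_invalid("every gene set needs a name")
  sets <- lapply(sets, unique)
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, universe = unique(universe),
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' GMT is tab-separated with one set per line: name, description, then the
#' member gene IDs.
#'
#' @param path Path to a `.gmt` file.
#' @param universe Background gene IDs; defaults to the union of all set
#'   members.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad))
    stop_invalid("malformed GMT line(s): %s",
                 paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  desc <- stats::setNames(vapply(parts, `[[`, character(1), 2), names(sets))
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe, desc)
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `overlap` annotated genes when
#' `query_size` genes are sampled without replacement from a universe of
#' `universe_size` genes of which `set_size` are annotated:
#' P(X >= k) for X ~ Hypergeometric(N, K, n).
#'
#' @param overlap Observed overlap k.
#' @param set_size Annotated genes K in the universe.
#' @param query_size Query genes n in the universe.
#' @param universe_size Universe size N.
#' @return The exact upper-tail p-value.
#' @export
hypergeometric_p <- function(overlap, set_size, query_size, universe_size) {
  if (set_size > universe_size || query_size > universe_size)
    stop_invalid("set_size and query_size cannot exceed universe_size")
  if (overlap > min(set_size, query_size) || overlap < 0)
    stop_invalid("overlap must lie in [0, min(set_size, query_size)]")
  phyper(overlap - 1, set_size, universe_size - set_size, query_size,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @return Adjusted values in the original input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop_invalid("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation of a gene list
#'
#' Tests each set of a collection for over-representation of the query genes
#' relative to the collection's universe (one-sided, upper tail), then
#' applies Benjamini-Hochberg FDR across the collection.  Collections meant
#' to be corrected separately (e.g. KEGG vs each GO namespace) should be
#' passed in separate calls.
#'
#' @param query Gene IDs of interest (e.g. the selected signature).  Genes
#'   outside the universe are dropped with a warning.
#' @param gsc A [gene_set_collection()].
#' @param fdr_threshold Sets with FDR below this are flagged significant.
#' @return A data frame with one row per set — `set_name`, `description`,
#'   `overlap_count`, `set_size_in_universe`, `query_size_in_universe`,
#'   `universe_size`, `p_value`, `fdr`, `significant` — sorted by FDR, then
#'   set name.
#' @export
enrich <- function(query, gsc, fdr_threshold = 0.05) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  query <- unique(query)
  outside <- setdiff(query, gsc$universe)
  if (length(outside) > 0) {
    warning(sprintf("%d query gene(s) outside the universe were dropped",
                    length(outside)))
    query <- intersect(query, gsc$universe)
  }
  N <- length(gsc$universe)
  n <- length(query)
  rows <- lapply(names(gsc$sets), function(nm) {
    members <- intersect(gsc$sets[[nm]], gsc$universe)
    k <- length(intersect(members, query))
    data.frame(set_name = nm,
               description = unname(gsc$descriptions[nm]),
               overlap_count = k,
               set_size_in_universe = length(members),
               query_size_in_universe = n,
               universe_size = N,
               p_value = hypergeometric_p(k, length(members), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < fdr_threshold
  out[order(out$fdr, out$set_name), , drop = FALSE]
}
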