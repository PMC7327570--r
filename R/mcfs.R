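#' Parameters for Monte-Carlo Feature Selection
#'
#' MCFS scores each gene by its relative importance (RI) accumulated over an
#' ensemble of s*t "projection" classification trees, each grown on a random
#' subset of m of the d candidate genes:
#'
#'   RI(g) = sum over trees tau of wAcc(tau)^u *
#'           sum over nodes of tau splitting on g of
#'             IG(n_g(tau)) * (no. in n_g(tau) / no. in tau)^v
#'
#' where wAcc is the tree's class-balanced held-out accuracy (mean per-class
#' recall), IG the entropy information gain of the node, and u, v exponents
#' weighting tree quality and node coverage.
#'
#' @param m Genes drawn per subset; default `max(ceiling(0.05 d), 5)`,
#'   resolved against the data when the run starts.
#' @param s Number of random subsets; default `ceiling(15 d / m)` so each
#'   gene is expected in at least 15 subsets.
#' @param t Trees grown per subset.
#' @param u,v Non-negative exponents on weighted accuracy and node coverage.
#' @param split_fraction Fraction of samples (stratified by class) used to
#'   train each tree; the remainder scores wAcc.
#' @param seed Integer RNG seed.
#' @return An `mcfs_params` list.
#' @export
mcfs_params <- function(m = NULL, s = NULL, t = 5L, u = 1, v = 1,
                        split_fraction = 0.66, seed = 1L) {
  if (!is.null(m) && m < 1) stop_invalid("m must be >= 1")
  if (!is.null(s) && s < 1) stop_invalid("s must be >= 1")
  if (t < 1) stop_invalid("t must be >= 1")
  if (u < 0 || v < 0) stop_invalid("u and v must be non-negative")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop_invalid("split_fraction must lie in (0, 1)")
  structure(list(m = m, s = s, t = as.integer(t), u = u, v = v,
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "mcfs_params")
}

resolve_mcfs_params <- function(p, d) {
  if (is.null(p$m)) p$m <- min(d, max(ceiling(0.05 * d), 5L))
  if (p$m > d) stop_invalid("m (%d) exceeds the number of genes (%d)", p$m, d)
  p$m <- as.integer(p$m)
  if (is.null(p$s)) p$s <- as.integer(ceiling(15 * d / p$m))
  p
}

draw_subsets <- function(gene_ids, m, s) {
  lapply(seq_len(s), function(i) sample(gene_ids, m))
}

#' Draw the s random feature subsets of an MCFS run
#'
#' @param gene_ids Candidate gene identifiers (the d features).
#' @param p An [mcfs_params()]; `m` and `s` are resolved against
#'   `length(gene_ids)` if unset.
#' @return A list of `s` character vectors of `m` distinct gene IDs;
#'   deterministic given `p$seed`.
#' @export
sample_feature_subsets <- function(gene_ids, p = mcfs_params()) {
  p <- resolve_mcfs_params(p, length(gene_ids))
  with_seed(p$seed, draw_subsets(gene_ids, p$m, p$s))
}

# Stratified train/held-out split; every class keeps >= 1 training sample
# and, where it has >= 2 samples, >= 1 held-out sample.
stratified_split <- function(labels, fraction) {
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_c <- length(idx)
    k <- max(1L, min(if (n_c > 1) n_c - 1L else 1L, round(fraction * n_c)))
    train <- c(train, if (n_c == 1) idx else sample(idx, k))
  }
  test <- setdiff(seq_along(labels), train)
  if (length(test) == 0)
    stop_invalid("stratified split left no held-out samples")
  list(train = sort(train), test = sort(test))
}

grow_one_tree <- function(xt, y, K, p, gene_ids, tree_id) {
  sp <- stratified_split(y, p$split_fraction)
  fit <- .fit_entropy_tree(xt[sp$train, , drop = FALSE],
                           as.integer(y[sp$train]) - 1L, K,
                           xt[sp$test, , drop = FALSE])
  truth <- as.integer(y[sp$test]) - 1L
  present <- sort(unique(truth))
  recall <- vapply(present, function(k)
    mean(fit$pred[truth == k] == k), numeric(1))
  list(tree_id = tree_id,
       w_acc = mean(recall),
       tree_n = length(sp$train),
       node_records = data.frame(
         gene_id = gene_ids[fit$feature],
         ig = fit$gain,
         n_node = fit$n_node,
         stringsAsFactors = FALSE))
}

#' Grow the t projection trees for one feature subset
#'
#' Each tree trains on a fresh stratified `split_fraction` draw of the
#' samples and is scored by wAcc, the mean per-class recall on the held-out
#' remainder.  Node records collect every internal node's splitting gene,
#' entropy information gain and sample count.
#'
#' @param m Expression matrix restricted to one feature subset.
#' @param labels Class labels (>= 2 classes present).
#' @param p An [mcfs_params()].
#' @param tree_id_offset Added to the 1..t tree indices (used by [mcfs()] to
#'   number trees 1..s*t).
#' @return A list of `t` tree evaluations (`tree_id`, `w_acc`, `tree_n`,
#'   `node_records`).
#' @export
build_projection_trees <- function(m, labels, p = mcfs_params(),
                                   tree_id_offset = 0L) {
  assert_expression_matrix(m)
  labels <- assert_labels(labels, m)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2)
    stop_invalid("labels must contain at least 2 classes")
  xt <- t(m)
  lapply(seq_len(p$t), function(i)
    grow_one_tree(xt, labels, nlevels(labels), p, rownames(m),
                  tree_id_offset + i))
}

#' Aggregate tree evaluations into relative-importance scores
#'
#' @param evals List of tree evaluations from [build_projection_trees()].
#' @param p An [mcfs_params()] supplying the exponents `u` and `v`.
#' @param gene_ids Optional universe of gene IDs; genes never used in any
#'   node get RI = 0.
#' @return A named numeric vector of RI scores.
#' @export
relative_importance <- function(evals, p = mcfs_params(), gene_ids = NULL) {
  acc <- new.env(parent = emptyenv())
  for (ev in evals) {
    nr <- ev$node_records
    if (nrow(nr) == 0) next
    w <- ev$w_acc^p$u
    term <- w * nr$ig * (nr$n_node / ev$tree_n)^p$v
    for (g in unique(nr$gene_id)) {
      add <- sum(term[nr$gene_id == g])
      acc[[g]] <- (if (is.null(acc[[g]])) 0 else acc[[g]]) + add
    }
  }
  ri <- unlist(as.list(acc))
  if (is.null(ri)) ri <- stats::setNames(numeric(0), character(0))
  if (!is.null(gene_ids)) {
    out <- stats::setNames(numeric(length(gene_ids)), gene_ids)
    out[names(ri)] <- ri
    ri <- out
  }
  ri
}

#' Order genes by decreasing relative importance
#'
#' Ties are broken lexicographically by gene ID so the ranking is
#' deterministic.
#'
#' @param ri Named numeric vector of RI scores.
#' @return A `ranked_features` data frame with columns `rank`, `gene_id`,
#'   `ri`, ordered by decreasing RI.
#' @export
rank_features <- function(ri) {
  if (length(ri) == 0) stop_invalid("no RI scores to rank")
  ord <- order(-ri, names(ri))
  out <- data.frame(rank = seq_along(ri),
                    gene_id = names(ri)[ord],
                    ri = unname(ri[ord]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_features", "data.frame"),
            N = length(ri))
}

#' Run a full MCFS ranking
#'
#' Draws `s` random `m`-gene subsets, grows `t` projection trees on each,
#' accumulates relative importance over all s*t trees, and ranks.
#'
#' @param m Expression matrix of the d candidate genes.
#' @param labels Class labels.
#' @param params An [mcfs_params()].
#' @return A `ranked_features` data frame (see [rank_features()]) with the
#'   resolved parameters in `attr(, "params")` and the mean tree wAcc in
#'   `attr(, "mean_w_acc")`.
#' @export
mcfs <- function(m, labels, params = mcfs_params()) {
  assert_expression_matrix(m)
  labels <- assert_labels(labels, m)
  p <- resolve_mcfs_params(params, nrow(m))
  evals <- with_seed(p$seed, {
    subsets <- draw_subsets(rownames(m), p$m, p$s)
    out <- vector("list", p$s)
    for (i in seq_len(p$s)) {
      out[[i]] <- build_projection_trees_raw(
        m[subsets[[i]], , drop = FALSE], labels, p,
        tree_id_offset = (i - 1L) * p$t)
    }
    do.call(c, out)
  })
  ri <- relative_importance(evals, p, gene_ids = rownames(m))
  ranked <- rank_features(ri)
  attr(ranked, "params") <- p
  attr(ranked, "mean_w_acc") <- mean(vapply(evals, `[[`, numeric(1), "w_acc"))
  ranked
}

# Internal variant that consumes the ambient RNG stream (no reseeding), so
# mcfs() controls determinism with a single seed.
build_projection_trees_raw <- function(m, labels, p, tree_id_offset = 0L) {
  labels <- droplevels(labels)
  xt <- t(m)
  lapply(seq_len(p$t), function(i)
    grow_one_tree(xt, labels, nlevels(labels), p, rownames(m),
                  tree_id_offset + i))
}

#' Estimate how many top-ranked genes beat a permutation null
#'
#' Re-runs the full MCFS ranking on label-permuted data `n_perm` times,
#' takes a quantile of the resulting maximal RI values as the null
#' threshold, and returns the largest position k such that every gene ranked
#' at or above k exceeds the threshold.  A fixed cutoff can be forced with
#' `fixed_k` (useful to replicate a published list length).
#'
#' @param ranked A `ranked_features` ranking of the observed data.
#' @param m,labels The matrix and labels the ranking was built from.
#' @param p The [mcfs_params()] used for the ranking.
#' @param n_perm Number of label permutations (>= 1).
#' @param null_quantile Quantile of the permutation maxima used as the
#'   threshold.
#' @param fixed_k Optional override: return this k regardless of the data.
#' @return An integer cutoff position (possibly 0) with the null threshold
#'   in `attr(, "threshold")`.
#' @export
top_ranking_cutoff <- function(ranked, m, labels, p = mcfs_params(),
                               n_perm = 20L, null_quantile = 0.95,
                               fixed_k = NULL) {
  if (!is.null(fixed_k)) return(as.integer(fixed_k))
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  assert_expression_matrix(m)
  labels <- assert_labels(labels, m)
  maxima <- vapply(seq_len(n_perm), function(b) {
    perm <- with_seed(derive_seed(p$seed, paste0("label-perm-", b)),
                      sample(labels))
    names(perm) <- names(labels)
    pb <- p
    pb$seed <- derive_seed(p$seed, paste0("mcfs-perm-", b))
    max(mcfs(m, perm, pb)$ri)
  }, numeric(1))
  thr <- as.numeric(quantile(maxima, null_quantile))
  above <- ranked$ri > thr
  k <- if (!above[1]) 0L else {
    first_below <- match(FALSE, above)
    if (is.na(first_below)) nrow(ranked) else first_below - 1L
  }
  structure(as.integer(k), threshold = thr, perm_maxima = maxima)
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("MCFS ranking of %d genes (top of list):\n", attr(x, "N")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
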