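#' Parameters for the all-relevant (Boruta) filter
#'
#' @param n_estimators Trees per random forest.
#' @param max_iter Maximum Boruta iterations.
#' @param alpha Two-sided level of the per-gene binomial hit test.
#' @param correct Apply a Bonferroni-style correction across the genes still
#'   undecided at each test (canonical behavior); set `FALSE` to disable.
#' @param seed Integer RNG seed.
#' @return A `boruta_params` list.
#' @export
boruta_params <- function(n_estimators = 100L, max_iter = 100L, alpha = 0.05,
                          correct = TRUE, seed = 1L) {
  if (max_iter < 1) stop_invalid("max_iter must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  if (n_estimators < 1) stop_invalid("n_estimators must be >= 1")
  structure(list(n_estimators = as.integer(n_estimators),
                 max_iter = as.integer(max_iter), alpha = alpha,
                 correct = isTRUE(correct), seed = as.integer(seed)),
            class = "boruta_params")
}

#' Append shadow features to an expression matrix
#'
#' Adds, for every gene, a "shadow" copy whose values are a random
#' permutation of that gene's values across samples.  Shadows carry the same
#' class-independent marginal distribution as their source gene and serve as
#' the importance null.
#'
#' @param m Numeric genes x samples matrix.
#' @param seed Integer RNG seed for the permutations.
#' @return A matrix with `2 * nrow(m)` rows; shadow rows are prefixed
#'   `shadow_`.
#' @export
make_shadow_features <- function(m, seed = 1L) {
  assert_expression_matrix(m)
  with_seed(seed, {
    sh <- t(apply(m, 1, sample))
    colnames(sh) <- colnames(m)
    rownames(sh) <- paste0("shadow_", rownames(m))
    rbind(m, sh)
  })
}

# One permutation pass used inside the iteration loop (consumes the current
# RNG stream rather than reseeding).
permute_rows <- function(m) {
  sh <- t(apply(m, 1, sample))
  colnames(sh) <- colnames(m)
  rownames(sh) <- paste0("shadow_", rownames(m))
  sh
}

#' Run the Boruta all-relevant filter
#'
#' Iteratively (i) permutes every input gene into a fresh shadow copy,
#' (ii) fits a random forest (impurity importance) on the still-undecided
#' real genes plus all shadows, (iii) scores a "hit" for each real gene
#' whose importance strictly exceeds the iteration's maximum shadow
#' importance, and (iv) confirms or rejects genes by two-sided binomial
#' tests on their cumulative hit counts at level `alpha`
#' (Bonferroni-corrected across undecided genes unless `correct = FALSE`).
#' Rejected genes leave the forest, but the shadow ensemble always keeps a
#' permuted copy of every input gene, so the null bar a gene must beat does
#' not weaken as the field thins.  Genes still undecided after `max_iter`
#' iterations remain `tentative` and are excluded from the confirmed set.
#'
#' @param m Numeric genes x samples matrix.
#' @param labels Class labels, one per sample (named by sample ID or in
#'   column order).
#' @param params A [boruta_params()].
#' @return A `boruta_result` with per-gene `status`
#'   (confirmed/rejected/tentative), `importance_history` (genes x
#'   iterations, NA once a gene left the forest), `shadow_max_history`,
#'   `hits`, `n_iter` and `n_confirmed`.
#' @export
boruta_run <- function(m, labels, params = boruta_params()) {
  assert_expression_matrix(m)
  labels <- assert_labels(labels, m)
  if (nlevels(labels) < 2)
    stop_invalid("labels must contain at least 2 classes")
  if (any(table(labels) < 2))
    stop_invalid("every class needs at least 2 samples")

  genes <- rownames(m)
  G <- length(genes)
  status <- stats::setNames(rep("tentative", G), genes)
  hits <- stats::setNames(integer(G), genes)
  trials <- stats::setNames(integer(G), genes)
  imp_hist <- matrix(NA_real_, G, params$max_iter,
                     dimnames = list(genes, NULL))
  shadow_max <- numeric(0)
  xt <- t(m)  # samples x features for the forest

  with_seed(params$seed, {
    for (it in seq_len(params$max_iter)) {
      active <- genes[status == "tentative"]
      if (length(active) == 0) break
      shadows <- permute_rows(m)  # every input gene, decided or not
      x <- cbind(xt[, active, drop = FALSE], t(shadows))
      fit <- ranger::ranger(
        x = x, y = labels, num.trees = params$n_estimators,
        importance = "impurity", num.threads = 1,
        seed = sample.int(.Machine$integer.max, 1))
      imp <- fit$variable.importance
      real_imp <- imp[active]
      sh_max <- max(imp[startsWith(names(imp), "shadow_")])
      shadow_max <- c(shadow_max, sh_max)
      imp_hist[active, it] <- real_imp
      hits[active] <- hits[active] + (real_imp > sh_max)
      trials[active] <- trials[active] + 1L

      denom <- if (params$correct) length(active) else 1L
      p_hi <- pbinom(hits[active] - 1L, trials[active], 0.5,
                     lower.tail = FALSE)
      p_lo <- pbinom(hits[active], trials[active], 0.5)
      status[active[pmin(2 * p_hi, 1) < params$alpha / denom]] <- "confirmed"
      status[active[pmin(2 * p_lo, 1) < params$alpha / denom]] <- "rejected"
    }
  })

  n_iter <- length(shadow_max)
  structure(list(status = factor(status,
                                 levels = c("confirmed", "rejected", "tentative")),
                 importance_history = imp_hist[, seq_len(n_iter), drop = FALSE],
                 shadow_max_history = shadow_max,
                 hits = hits, trials = trials, n_iter = n_iter,
                 n_confirmed = sum(status == "confirmed"),
                 params = params),
            class = "boruta_result")
}

#' Genes confirmed by a Boruta run
#'
#' @param r A `boruta_result`.
#' @return Confirmed gene IDs, in the input matrix's row order.
#' @export
confirmed_features <- function(r) {
  stopifnot(inherits(r, "boruta_result"))
  names(r$status)[r$status == "confirmed"]
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$status)
  cat(sprintf(
    "Boruta filter: %d genes -> %d confirmed, %d rejected, %d tentative (%d iterations)\n",
    length(x$status), tab[["confirmed"]], tab[["rejected"]],
    tab[["tentative"]], x$n_iter))
  invisible(x)
}
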