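# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and textbook formulas only.

# One-way ANOVA F statistic for one gene.
oracle_f_stat <- function(values, labels) {
  labels <- as.factor(labels)
  n <- length(values)
  k <- nlevels(labels)
  grand <- mean(values)
  ss_between <- 0
  ss_within <- 0
  for (cl in levels(labels)) {
    v <- values[labels == cl]
    ss_between <- ss_between + length(v) * (mean(v) - grand)^2
    ss_within <- ss_within + sum((v - mean(v))^2)
  }
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# Term-by-term evaluation of the relative-importance sum over trees/nodes.
oracle_ri <- function(evals, u, v) {
  out <- list()
  for (ev in evals) {
    nr <- ev$node_records
    for (r in seq_len(nrow(nr))) {
      g <- nr$gene_id[r]
      term <- (ev$w_acc^u) * nr$ig[r] * (nr$n_node[r] / ev$tree_n)^v
      out[[g]] <- (if (is.null(out[[g]])) 0 else out[[g]]) + term
    }
  }
  unlist(out)
}

# Exact hypergeometric upper tail by combinatorial summation.
oracle_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running_min <- 1
  for (i in m:1) {
    val <- min(1, p[ord[i]] * m / i)
    running_min <- min(running_min, val)
    q[ord[i]] <- running_min
  }
  q
}

# Quantile normalization for tie-free columns: each column's sorted values
# replaced by the row means of the column-sorted matrix.
oracle_qn_tie_free <- function(m) {
  srt <- apply(m, 2, sort)
  ref <- rowMeans(srt)
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- ref
  out
}

# Small labeled matrix fixture: `n_noise` Gaussian genes plus optional
# planted genes elevated in a cycling class.
make_fixture <- function(n_noise = 30, n_planted = 0, per_class = 10,
                         classes = c("A", "B", "C", "D"), effect = 3,
                         seed = 42) {
  withr::with_seed(seed, {
    n <- per_class * length(classes)
    labels <- factor(rep(classes, each = per_class))
    g <- n_noise + n_planted
    m <- matrix(rnorm(g * n), g, n,
                dimnames = list(sprintf("g%03d", seq_len(g)),
                                sprintf("s%03d", seq_len(n))))
    names(labels) <- colnames(m)
    planted <- character(0)
    if (n_planted > 0) {
      planted <- rownames(m)[seq_len(n_planted)]
      for (i in seq_len(n_planted)) {
        cl <- classes[(i - 1) %% length(classes) + 1]
        m[i, labels == cl] <- m[i, labels == cl] + effect
      }
    }
    list(matrix = m, labels = labels, planted = planted)
  })
}
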