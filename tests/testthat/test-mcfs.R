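test_that("feature-subset sampling has the right shape, determinism, and coverage", {
  genes <- paste0("g", 1:5)
  p <- mcfs_params(m = 2, s = 3, seed = 4)
  subs <- sample_feature_subsets(genes, p)
  expect_length(subs, 3)
  for (s in subs) {
    expect_length(s, 2)
    expect_false(anyDuplicated(s) > 0)
  }
  expect_identical(subs, sample_feature_subsets(genes, p))

  # m == d forces every subset to be the full gene set
  full <- sample_feature_subsets(genes, mcfs_params(m = 5, s = 4, seed = 1))
  for (s in full) expect_setequal(s, genes)

  expect_error(sample_feature_subsets(genes, mcfs_params(m = 9, s = 2)),
               "exceeds")

  # with m = 1, d = 2 each gene appears in about half the subsets
  freq <- table(unlist(sample_feature_subsets(
    c("a", "b"), mcfs_params(m = 1, s = 400, seed = 2))))
  expect_lt(abs(freq[["a"]] - 200), 4 * sqrt(400 * 0.25))
})

test_that("projection trees separate a clean gene perfectly and record the root over all samples", {
  labels <- factor(rep(c("A", "B"), each = 10))
  m <- rbind(g1 = c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01)))
  colnames(m) <- sprintf("s%02d", 1:20)
  names(labels) <- colnames(m)
  withr::with_seed(1, {
    evals <- build_projection_trees(m, labels, mcfs_params(t = 4))
  })
  for (ev in evals) {
    expect_equal(ev$w_acc, 1.0)
    expect_equal(ev$node_records$n_node[1], ev$tree_n)  # root recorded first
    expect_true(all(ev$node_records$n_node <= ev$tree_n))
    expect_true(all(ev$node_records$ig >= 0))
  }
})

test_that("trees on label-shuffled data score near chance", {
  fx <- make_fixture(n_noise = 12, per_class = 15, seed = 17)
  w <- unlist(lapply(1:20, function(i) {
    lab <- withr::with_seed(100 + i, sample(fx$labels))
    names(lab) <- names(fx$labels)
    withr::with_seed(i, {
      evals <- build_projection_trees(fx$matrix, lab, mcfs_params(t = 2))
    })
    vapply(evals, `[[`, numeric(1), "w_acc")
  }))
  expect_lt(abs(mean(w) - 0.25), 0.08)
})

test_that("relative importance matches hand-summed evaluation of its defining formula", {
  evals <- list(
    list(tree_id = 1, w_acc = 0.8, tree_n = 10,
         node_records = data.frame(
           gene_id = c("g1", "g2", "g1"), ig = c(0.9, 0.4, 0.2),
           n_node = c(10, 4, 3))),
    list(tree_id = 2, w_acc = 0.5, tree_n = 8,
         node_records = data.frame(
           gene_id = c("g2", "g3"), ig = c(0.7, 0.1), n_node = c(8, 2))))
  for (uv in list(c(1, 1), c(2, 0.5), c(0, 0))) {
    p <- mcfs_params(u = uv[1], v = uv[2])
    got <- relative_importance(evals, p)
    want <- oracle_ri(evals, uv[1], uv[2])
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
  # forced arithmetic: one tree, wAcc 1, one node covering all samples
  single <- list(list(tree_id = 1, w_acc = 1, tree_n = 6,
                      node_records = data.frame(gene_id = "g", ig = 0.5,
                                                n_node = 6)))
  expect_equal(unname(relative_importance(single, mcfs_params())), 0.5)
  # a gene never split on gets RI zero
  ri <- relative_importance(evals, mcfs_params(), gene_ids = c("g1", "g2", "g3", "g9"))
  expect_equal(unname(ri["g9"]), 0)
})

test_that("with u = v = 0 relative importance reduces to the plain IG sum", {
  fx <- make_fixture(n_noise = 8, n_planted = 2, per_class = 8, seed = 51)
  withr::with_seed(2, {
    evals <- build_projection_trees(fx$matrix, fx$labels, mcfs_params(t = 5))
  })
  p0 <- mcfs_params(u = 0, v = 0)
  got <- relative_importance(evals, p0)
  plain <- tapply(
    unlist(lapply(evals, function(e) e$node_records$ig)),
    unlist(lapply(evals, function(e) e$node_records$gene_id)), sum)
  expect_equal(got[names(plain)], c(plain), tolerance = 1e-12)
})

test_that("relative importance is additive over disjoint tree sets", {
  fx <- make_fixture(n_noise = 10, n_planted = 2, per_class = 8, seed = 52)
  withr::with_seed(3, {
    evals <- build_projection_trees(fx$matrix, fx$labels, mcfs_params(t = 6))
  })
  p <- mcfs_params(u = 1, v = 1)
  ids <- rownames(fx$matrix)
  whole <- relative_importance(evals, p, gene_ids = ids)
  parts <- relative_importance(evals[1:3], p, gene_ids = ids) +
    relative_importance(evals[4:6], p, gene_ids = ids)
  expect_equal(whole, parts, tolerance = 1e-12)
})

test_that("ranking is by descending RI with lexicographic tie-break", {
  expect_equal(rank_features(c(a = 0.1, b = 0.9))$gene_id, c("b", "a"))
  tied <- rank_features(c(z = 0.5, a = 0.5, m = 0.5))
  expect_equal(tied$gene_id, c("a", "m", "z"))
  r <- rank_features(c(x = 0, y = 2, w = 1))
  expect_true(all(diff(r$ri) <= 0))
  expect_equal(attr(r, "N"), 3)
})

test_that("a full MCFS run is seed-deterministic and puts planted genes on top", {
  fx <- make_fixture(n_noise = 60, n_planted = 6, per_class = 12,
                     effect = 4, seed = 61)
  p <- mcfs_params(s = 60, t = 3, seed = 9)
  r1 <- mcfs(fx$matrix, fx$labels, p)
  r2 <- mcfs(fx$matrix, fx$labels, p)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  ranks <- match(fx$planted, r1$gene_id)
  expect_lte(median(ranks), ceiling(nrow(r1) / 10))
})

test_that("the permutation cutoff covers strongly planted genes and honors the fixed-k override", {
  fx <- make_fixture(n_noise = 190, n_planted = 10, per_class = 20,
                     effect = 4, seed = 71)
  p <- mcfs_params(seed = 10)
  ranked <- mcfs(fx$matrix, fx$labels, p)
  k <- top_ranking_cutoff(ranked, fx$matrix, fx$labels, p, n_perm = 5)
  expect_gte(k, 10)
  expect_true(all(fx$planted %in% ranked$gene_id[1:k]))
  expect_equal(top_ranking_cutoff(ranked, fx$matrix, fx$labels, p,
                                  fixed_k = 663), 663L)
  expect_error(top_ranking_cutoff(ranked, fx$matrix, fx$labels, p,
                                  n_perm = 0), "n_perm")
})
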