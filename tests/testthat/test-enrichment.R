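test_that("hypergeometric tail handles boundary cases and forced arithmetic", {
  expect_equal(hypergeometric_p(0, 5, 10, 20), 1.0)
  expect_equal(hypergeometric_p(5, 5, 5, 5), 1.0)
  expect_equal(hypergeometric_p(4, 5, 10, 20), 28028 / 184756)
  expect_error(hypergeometric_p(6, 5, 10, 20), "overlap")
  expect_error(hypergeometric_p(1, 25, 10, 20), "exceed")
})

test_that("hypergeometric tail agrees with combinatorial enumeration on sampled cases", {
  withr::with_seed(8, {
    for (i in 1:200) {
      N <- sample(2:30, 1)
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(hypergeometric_p(k, K, n, N),
                   oracle_hyper_tail(k, K, n, N), tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment matches the step-up definition and its invariances", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(9, {
    p <- runif(50)^2
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(50)
    expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]), tolerance = 1e-12)
    # idempotent on an already-adjusted monotone sequence
    q <- sort(bh_fdr(p))
    expect_equal(bh_fdr(q), oracle_bh(q), tolerance = 1e-12)
  })
})

test_that("GMT files round-trip with names, descriptions, and members", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tfirst pathway\tg1\tg2\tg3",
               "setB\t\tg2\tg4",
               "setC\tdup members\tg5\tg5\tg6"), path)
  gsc <- read_gmt(path)
  expect_equal(names(gsc$sets), c("setA", "setB", "setC"))
  expect_equal(gsc$sets$setA, c("g1", "g2", "g3"))
  expect_equal(gsc$sets$setC, c("g5", "g6"))  # duplicates dropped
  expect_equal(unname(gsc$descriptions["setA"]), "first pathway")
  expect_setequal(gsc$universe, paste0("g", 1:6))

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("lonely_name", bad)
  expect_error(read_gmt(bad), "malformed")
})

test_that("over-representation ranks a fully recovered set at the minimum attainable p", {
  universe <- sprintf("u%02d", 1:20)
  gsc <- gene_set_collection(
    list(hit = universe[1:5], miss = universe[11:15], half = universe[3:8]),
    universe)
  out <- enrich(universe[1:5], gsc, fdr_threshold = 0.05)
  expect_equal(out$set_name[1], "hit")
  expect_equal(out$p_value[out$set_name == "hit"],
               oracle_hyper_tail(5, 5, 5, 20), tolerance = 1e-12)
  # minimum possible p for these margins is attained
  expect_equal(out$p_value[out$set_name == "hit"],
               min(vapply(0:5, function(k) oracle_hyper_tail(k, 5, 5, 20),
                          numeric(1))))
  expect_true(out$significant[out$set_name == "hit"])
  expect_equal(out$overlap_count[out$set_name == "miss"], 0)
  expect_equal(out$p_value[out$set_name == "miss"], 1.0)
})

test_that("a query disjoint from every set finds nothing", {
  universe <- sprintf("u%02d", 1:30)
  gsc <- gene_set_collection(list(s1 = universe[1:5], s2 = universe[6:10]),
                             universe)
  out <- enrich(universe[21:25], gsc)
  expect_true(all(out$p_value == 1))
  expect_false(any(out$significant))
})

test_that("query genes outside the universe are dropped with a warning", {
  gsc <- gene_set_collection(list(s = c("a", "b")), c("a", "b", "c", "d"))
  expect_warning(out <- enrich(c("a", "zzz"), gsc), "outside the universe")
  expect_equal(out$query_size_in_universe[1], 1)
})

test_that("random queries give super-uniform p-values under the null", {
  universe <- sprintf("u%03d", 1:60)
  gsc <- gene_set_collection(list(s = universe[1:12]), universe)
  ps <- withr::with_seed(11, vapply(1:1000, function(i)
    enrich(sample(universe, 10), gsc)$p_value[1], numeric(1)))
  # discrete test: P(p <= a) <= a, checked with Monte-Carlo slack
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 1000))
  expect_gt(mean(ps), 0.4)
})
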