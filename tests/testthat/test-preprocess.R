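mk <- function(values, genes, samples) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples))
}

test_that("gene intersection keeps exactly the shared genes, sorted, columns concatenated", {
  a <- mk(1:6, c("g2", "g1", "g3"), c("s1", "s2"))
  b <- mk(7:12, c("g1", "g2", "g3"), c("s3", "s4"))
  out <- intersect_genes(a, b)
  expect_equal(rownames(out), c("g1", "g2", "g3"))
  expect_equal(colnames(out), c("s1", "s2", "s3", "s4"))
  expect_equal(out["g1", "s2"], a["g1", "s2"])

  b2 <- mk(1:6, c("g2", "g3", "g4"), c("s3", "s4"))
  expect_equal(rownames(intersect_genes(a, b2)), c("g2", "g3"))

  withr::with_seed(1, {
    ga <- sprintf("g%03d", sample(200, 80))
    gb <- sprintf("g%03d", sample(200, 80))
    ra <- mk(rnorm(80 * 3), ga, paste0("a", 1:3))
    rb <- mk(rnorm(80 * 3), gb, paste0("b", 1:3))
    expect_equal(nrow(intersect_genes(ra, rb)), length(intersect(ga, gb)))
  })
})

test_that("disjoint gene sets and overlapping sample IDs are rejected", {
  a <- mk(1:4, c("g1", "g2"), c("s1", "s2"))
  b <- mk(1:4, c("g3", "g4"), c("s3", "s4"))
  expect_error(intersect_genes(a, b), "no gene identifiers")
  b_dup <- mk(1:4, c("g1", "g2"), c("s2", "s3"))
  expect_error(intersect_genes(a, b_dup), "sample identifiers overlap")
})

test_that("the 3x2 worked example maps both columns onto the reference distribution", {
  m <- mk(c(1, 2, 3, 4, 5, 6), paste0("g", 1:3), c("s1", "s2"))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "s2"]), c(2.5, 3.5, 4.5))
})

test_that("columns that are already identical multisets are a fixed point", {
  withr::with_seed(2, {
    v <- rnorm(10)
    m <- mk(c(v, sample(v), sample(v)), sprintf("g%02d", 1:10),
            c("s1", "s2", "s3"))
    expect_equal(quantile_normalize(m), m, tolerance = 1e-12)
  })
})

test_that("normalization equalizes column distributions, preserves ranks, and is idempotent", {
  withr::with_seed(3, {
    m <- mk(rnorm(200, sd = 4), sprintf("g%02d", 1:40), paste0("s", 1:5))
    out <- quantile_normalize(m)
    srt <- apply(out, 2, sort)
    for (j in 2:5) expect_equal(srt[, j], srt[, 1], tolerance = 1e-12,
                                ignore_attr = TRUE)
    for (j in 1:5) expect_equal(order(out[, j]), order(m[, j]))
    expect_equal(quantile_normalize(out), out, tolerance = 1e-12)
    expect_equal(out, oracle_qn_tie_free(m), tolerance = 1e-12)
  })
})

test_that("tied values receive the mean of the reference values at their positions", {
  m <- mk(c(1, 1, 5, 2, 4, 9), paste0("g", 1:3), c("s1", "s2"))
  # reference = rowMeans(sorted columns) = (1.5, 2.5, 7)
  # column s1 has a tie at value 1 occupying positions 1 and 2
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "s1"]), c(2, 2, 7))
  expect_equal(unname(out[, "s2"]), c(1.5, 2.5, 7))
})

test_that("normalization matches limma's on tie-free data", {
  skip_if_not_installed("limma")
  withr::with_seed(4, {
    m <- mk(rnorm(300), sprintf("g%03d", 1:60), paste0("s", 1:5))
    expect_equal(unname(quantile_normalize(m)),
                 unname(limma::normalizeQuantiles(m)), tolerance = 1e-10)
  })
})

test_that("an additive platform shift is removed at the distribution level", {
  withr::with_seed(5, {
    m <- mk(rnorm(400), sprintf("g%03d", 1:50), paste0("s", 1:8))
    assign <- rep(c(0, 1), 4)
    shifted <- apply_batch_effect(m, assign, 3)
    qn <- quantile_normalize(shifted)
    srt <- apply(qn, 2, sort)
    for (j in 2:8) expect_equal(srt[, j], srt[, 1], tolerance = 1e-12,
                                ignore_attr = TRUE)
    # equal to the unshifted normalization up to one global constant
    delta <- qn - quantile_normalize(m)
    expect_lt(max(delta) - min(delta), 1e-10)
  })
})

test_that("non-finite values are rejected", {
  m <- mk(c(1, NA, 3, 4), c("g1", "g2"), c("s1", "s2"))
  expect_error(quantile_normalize(m), "non-finite")
})
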