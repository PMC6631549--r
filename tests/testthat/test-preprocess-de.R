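# Normalization, presence filtering, differential expression, clustering.

test_that("normalization log2-transforms and median-centers per array", {
  x <- make_expr(matrix(c(1, 10, 100), 3, 1))
  out <- normalize_expression(x)
  expect_equal(as.vector(out$values), c(-3.3219, 0, 3.3219), tolerance = 1e-4)
  expect_true(out$log2)

  # constant array centers to zero
  const <- normalize_expression(make_expr(matrix(7, 4, 1)))
  expect_equal(as.vector(const$values), rep(0, 4))

  # a global scale factor between arrays vanishes
  m <- matrix(2^rnorm(20, 8), 10, 2)
  m[, 2] <- m[, 1] * 3.7
  sc <- normalize_expression(make_expr(m))
  expect_equal(sc$values[, 1], sc$values[, 2])
})

test_that("normalization is idempotent-safe and rejects bad intensities", {
  x <- make_expr(matrix(2^rnorm(24, 8), 6, 4))
  once <- normalize_expression(x)
  twice <- normalize_expression(once)
  expect_equal(once$values, twice$values)

  bad <- matrix(c(1, 2, -3, 4), 2, 2,
                dimnames = list(c("gA", "gB"), c("sX", "sY")))
  expect_error(normalize_expression(expr_matrix(bad)), "gA.*sY")
})

test_that("presence filter keeps genes detected in >=80% of either group", {
  det <- rbind(c(rep(TRUE, 4), rep(FALSE, 4)),   # 4/4 good, 0/4 bad -> keep
               c(rep(c(TRUE, TRUE, TRUE, FALSE), 2)),  # 3/4 both -> drop
               rep(TRUE, 8))                     # everywhere -> keep
  x <- make_expr(matrix(1, 3, 8), detected = det, log2 = TRUE)
  ph <- make_phen(c(rep(95, 4), rep(20, 4)))
  out <- presence_filter(x, ph)
  expect_identical(gene_ids(out), c("g01", "g03"))

  # unlabeled samples are ignored by the criterion but kept in the matrix
  ph2 <- make_phen(c(rep(95, 4), rep(20, 4), 50, 60),
                   sample_ids = sprintf("s%02d", 1:10))
  x2 <- make_expr(matrix(1, 3, 10),
                  detected = cbind(det, c(FALSE, FALSE, FALSE),
                                   c(FALSE, FALSE, FALSE)), log2 = TRUE)
  out2 <- presence_filter(x2, ph2)
  expect_identical(gene_ids(out2), c("g01", "g03"))
  expect_identical(ncol(out2$values), 10L)

  # idempotent, and output genes are a subset of input genes
  expect_identical(gene_ids(presence_filter(out, ph)), gene_ids(out))
  expect_true(all(gene_ids(out) %in% gene_ids(x)))

  # a missing group is an error
  expect_error(presence_filter(x, make_phen(rep(95, 8))), "bad")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.005, 0.009, 0.05, 0.5)),
               c(0.018, 0.018, 0.05 * 4 / 3, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::with_seed(1, {
    for (k in 1:50) {
      p <- runif(sample(1:40, 1))
      expect_identical(bh_adjust(p), bh_oracle(p))
    }
  })
})

test_that("differential expression handles identical and shifted genes", {
  withr::with_seed(10, {
    m <- matrix(rnorm(20 * 32), 20, 32)
    m[1, ] <- 0                       # identical in both groups
    m[2, 17:32] <- m[2, 17:32] + 5    # 5 within-group SDs shift
  })
  x <- make_expr(m, log2 = TRUE)
  ph <- make_phen(c(rep(95, 16), rep(20, 16)))
  de <- differential_expression(x, ph)
  expect_identical(de$t[1], 0)
  expect_identical(de$p_value[1], 1)
  expect_false(de$significant[1])
  expect_true(de$significant[2])
  expect_gt(de$fold_change[2], 1)
  expect_true(all(de$q_value >= de$p_value))
  expect_true(all(abs(de$fold_change) >= 1))
})

test_that("a strongly shifted gene is significant across seeds", {
  hits <- 0
  for (s in 1:20) {
    withr::with_seed(s, {
      m <- matrix(rnorm(50 * 32), 50, 32)
      m[1, 17:32] <- m[1, 17:32] + 5
    })
    de <- differential_expression(make_expr(m, log2 = TRUE),
                                  make_phen(c(rep(95, 16), rep(20, 16))))
    hits <- hits + de$significant[1]
  }
  expect_gte(hits, 19)
})

test_that("per-gene t statistics agree with stats::t.test", {
  withr::with_seed(4, m <- matrix(rnorm(10 * 12, sd = rep(1:10, 12)), 10, 12))
  x <- make_expr(m, log2 = TRUE)
  ph <- make_phen(c(rep(95, 6), rep(20, 6)))
  for (var_equal in c(FALSE, TRUE)) {
    de <- differential_expression(x, ph, var_equal = var_equal)
    for (g in 1:10) {
      ref <- t.test(m[g, 7:12], m[g, 1:6], var.equal = var_equal)
      expect_equal(de$t[g], unname(ref$statistic), tolerance = 1e-12)
      expect_equal(de$p_value[g], ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("fold changes follow the signed bad-vs-good convention", {
  m <- rbind(c(0, 0, 1, 1),    # bad - good = +1 -> +2
             c(1, 1, 0, 0),    # -1 -> -2
             c(2, 2, 2, 2))    # 0 -> +1
  x <- make_expr(m, log2 = TRUE)
  ph <- make_phen(c(95, 96, 20, 21))
  expect_equal(unname(fold_change(x, ph)), c(2, -2, 1))
})

test_that("clustering orders genes by correlation structure", {
  withr::with_seed(2, base <- rnorm(10))
  m <- rbind(g1 = base + rnorm(10, 0, 0.05),
             g2 = base + rnorm(10, 0, 0.05),
             g3 = -base + rnorm(10, 0, 0.3))
  colnames(m) <- sprintf("s%02d", 1:10)
  co <- cluster_order(expr_matrix(m, log2 = TRUE))
  # g1 and g2 merge first: topology ((g1,g2),g3)
  expect_setequal(abs(co$gene_tree$merge[1, ]), c(1, 2))
  # identical profiles merge at height ~0
  dup <- cluster_order(make_expr(rbind(m, g4 = m["g1", ]), log2 = TRUE))
  expect_lt(dup$gene_tree$height[1], 1e-3)
  # permuting input gene order leaves merge heights unchanged
  perm <- cluster_order(make_expr(m[c(3, 1, 2), ], log2 = TRUE))
  expect_equal(sort(perm$gene_tree$height), sort(co$gene_tree$height))
})
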