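# Correlation filtering against survival and redundancy pruning.

test_that("correlation filter retains correlated genes and drops noise", {
  withr::with_seed(6, y <- runif(32, 10, 95))
  m <- rbind(hit = y,                            # identical to survival
             weak = vector_with_cor(y, 0.1, seed = 2),  # r = 0.1 exactly
             flat = rep(3, 32))                  # constant
  x <- make_expr(m, log2 = TRUE)
  cf <- correlation_filter(x, y)
  expect_true(cf$retained[1])
  expect_lt(cf$p_value[1], 1e-10)
  # n = 32, r = 0.1: two-sided p ~ 0.586 > 0.1 -> discarded
  expect_equal(cf$r_survival[2], 0.1, tolerance = 1e-10)
  expect_equal(cf$p_value[2], 0.586, tolerance = 2e-3)
  expect_false(cf$retained[2])
  # constant gene: r defined 0, p = 1, discarded
  expect_identical(cf$r_survival[3], 0)
  expect_identical(cf$p_value[3], 1)
  expect_false(cf$retained[3])
})

test_that("correlation test p-values match stats::cor.test", {
  withr::with_seed(11, {
    m <- matrix(rnorm(8 * 30), 8, 30)
    y <- rnorm(30)
  })
  cf <- correlation_filter(make_expr(m), y)
  for (g in 1:8) {
    ref <- cor.test(m[g, ], y)
    expect_equal(cf$r_survival[g], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(cf$p_value[g], ref$p.value, tolerance = 1e-12)
  }
})

test_that("redundancy pruning keeps the best gene of each component", {
  withr::with_seed(3, {
    y <- runif(40, 0, 100)
    g1 <- vector_with_cor(y, 0.8, seed = 31)
    g2 <- g1 + rnorm(40, 0, 0.05)     # near-duplicate of g1
    g5 <- rnorm(40)                   # isolated
  })
  m <- rbind(g1 = g1, g2 = g2, g5 = g5)
  rp <- redundancy_prune(make_expr(m, log2 = TRUE), y)
  expect_true(rp$kept[rp$gene_id == "g1"])
  expect_false(rp$kept[rp$gene_id == "g2"])
  expect_true(rp$kept[rp$gene_id == "g5"])
  expect_identical(rp$component[1], rp$component[2])
})

test_that("transitive chains collapse to one representative", {
  # exact construction from an orthonormal basis: cor(g1,g2) = cor(g2,g3)
  # = 0.96 but cor(g1,g3) = 0.96^2 = 0.9216 < 0.95 -> a genuine chain
  withr::with_seed(8, {
    # centered orthonormal basis: QR of a column-centered random matrix
    q <- qr.Q(qr(scale(matrix(rnorm(60 * 3), 60, 3), scale = FALSE)))
    y <- runif(60, 0, 100)
  })
  a <- 0.96
  b <- sqrt(1 - a^2)
  m <- rbind(g1 = a * q[, 1] + b * q[, 2],
             g2 = q[, 1],
             g3 = a * q[, 1] + b * q[, 3])
  cc <- cor(t(m))
  expect_equal(unname(cc["g1", "g2"]), 0.96, tolerance = 1e-6)
  expect_lt(cc["g1", "g3"], 0.95)
  rp <- redundancy_prune(make_expr(m, log2 = TRUE), y)
  expect_identical(length(unique(rp$component)), 1L)
  expect_identical(sum(rp$kept), 1L)
  # the kept gene has the largest |r| with survival
  expect_identical(rp$gene_id[rp$kept],
                   rp$gene_id[which.max(abs(rp$r_survival))])
})

test_that("pruning is the identity when no pair exceeds the threshold", {
  withr::with_seed(12, m <- matrix(rnorm(6 * 30), 6, 30))
  y <- withr::with_seed(13, runif(30, 0, 100))
  rp <- redundancy_prune(make_expr(m, log2 = TRUE), y)
  expect_true(all(rp$kept))
})

test_that("no retained pair exceeds the threshold after pruning", {
  d <- generate_dataset(synth_config(n_samples = 36, n_genes = 120,
                                     n_duplicate_blocks = 8,
                                     frac_absent_genes = 0, seed = 14))
  x <- normalize_expression(d$expression)
  rp <- redundancy_prune(x, d$phenotypes$survival)
  kept <- x$values[rp$gene_id[rp$kept], ]
  cc <- cor(t(kept))
  expect_true(all(cc[upper.tri(cc)] <= 0.95))
})

test_that("planted duplicate blocks collapse to their best member", {
  d <- generate_dataset(synth_config(n_samples = 36, n_genes = 100,
                                     n_duplicate_blocks = 4,
                                     frac_absent_genes = 0, seed = 15))
  x <- normalize_expression(d$expression)
  y <- d$phenotypes$survival
  rp <- redundancy_prune(x, y)
  for (block in d$truth$duplicate_blocks) {
    rows <- rp[rp$gene_id %in% block, ]
    expect_identical(sum(rows$kept), 1L)
    expect_identical(rows$gene_id[rows$kept],
                     rows$gene_id[which.max(abs(rows$r_survival))])
  }
  # pruning is deterministic
  rp2 <- redundancy_prune(x, y)
  expect_identical(rp, rp2)
})

test_that("the gene pool records provenance and respects both filters", {
  d <- generate_dataset(synth_config(n_samples = 36, n_genes = 150, seed = 16))
  x <- normalize_expression(d$expression)
  pool <- build_gene_pool(x, d$phenotypes$survival)
  prov <- attr(pool, "provenance")
  expect_identical(prov$n_input, 150L)
  expect_identical(prov$n_after_prune, nrow(pool))
  expect_true(all(pool$p_value <= 0.1))
  # planted genes correlate with survival and with each other below the
  # pruning threshold, so the whole module survives into the pool
  expect_true(all(d$truth$signal_gene_ids %in% pool$gene_id))
})
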