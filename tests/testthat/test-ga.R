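# Genetic-algorithm operators and population search.

small_cfg <- function(n_generations = 5) {
  ga_config(population_size = 20, n_generations = n_generations,
            n_populations = 1, final_eval_runs = 2)
}

test_that("configuration invariants are enforced", {
  expect_error(ga_config(min_genes = 5, max_genes = 3), "max_genes")
  expect_error(ga_config(mutation_fraction = 1.2), "mutation_fraction")
  expect_error(ga_config(population_size = 10, n_elite = 10), "n_elite")
})

test_that("initial populations respect size bounds and uniqueness", {
  cfg <- ga_config()
  pop <- init_population(5410, cfg, seed = 4)
  expect_length(pop, 500)
  sizes <- lengths(pop)
  expect_true(all(sizes >= 1 & sizes <= 20))
  expect_true(all(vapply(pop, function(i) !anyDuplicated(i), logical(1))))
  expect_identical(pop, init_population(5410, cfg, seed = 4))

  singles <- init_population(100, ga_config(min_genes = 1, max_genes = 1),
                             seed = 1)
  expect_true(all(lengths(singles) == 1))

  expect_error(init_population(10, cfg), "smaller")
})

test_that("initial subset sizes are uniform on {min..max}", {
  cfg <- ga_config(population_size = 10000)
  sizes <- lengths(init_population(2000, cfg, seed = 9))
  expect_gt(chisq.test(table(factor(sizes, levels = 1:20)))$p.value, 0.01)
})

test_that("rank-proportional selection matches its probabilities", {
  pop <- list(1L, 2L, 3L)
  fitness <- c(0.1, 0.5, 0.9)   # ranks 1, 2, 3 -> probs 1/6, 2/6, 3/6
  draws <- unlist(lapply(1:4000, function(s)
    unlist(select_parents(pop, fitness, seed = s))))
  freq <- tabulate(draws, 3) / length(draws)
  p <- c(1, 2, 3) / 6
  se <- sqrt(p * (1 - p) / length(draws))
  expect_true(all(abs(freq - p) < 3.5 * se))
  # all-equal fitness: ordinal ranks still sum correctly and selection works
  expect_length(select_parents(pop, c(0.5, 0.5, 0.5), seed = 1), 3)
})

test_that("mutation respects feasibility at the size bounds", {
  cfg <- ga_config(min_genes = 1, max_genes = 20)
  for (s in 1:100) {
    out <- mutate_individual(5L, pool_size = 50, cfg, seed = s)
    expect_gte(length(out), 1)
    expect_true(!anyDuplicated(out))
  }
  for (s in 1:100) {
    out <- mutate_individual(1:20, pool_size = 50, cfg, seed = s)
    expect_lte(length(out), 20)
  }
})

test_that("mutation picks add/remove/replace uniformly when all feasible", {
  cfg <- ga_config()
  ind <- 1:10
  ops <- vapply(1:3000, function(s) {
    out <- mutate_individual(ind, pool_size = 100, cfg, seed = s)
    if (length(out) > 10) "add" else if (length(out) < 10) "remove"
    else "replace"
  }, character(1))
  expect_gt(chisq.test(table(ops))$p.value, 0.01)
})

test_that("crossover exchanges subsets and preserves the gene universe", {
  cfg <- ga_config(min_genes = 1, max_genes = 20)
  for (s in 1:50) {
    a <- sort(sample(100, 8))
    b <- sort(sample(setdiff(1:100, a), 6))
    ch <- crossover(a, b, pool_size = 100, cfg, seed = s)
    expect_true(all(unlist(ch) %in% c(a, b)))
    expect_true(all(lengths(ch) >= 1))
  }
  # identical parents reproduce themselves
  same <- crossover(1:5, 1:5, pool_size = 100, cfg, seed = 3)
  expect_identical(same[[1]], 1:5)
  expect_identical(same[[2]], 1:5)
})

test_that("zero generations returns the scored initial population", {
  d <- null_dataset(16, 40, seed = 31)
  X <- t(log2(d$expression$values))
  cfg <- small_cfg(n_generations = 0)
  res <- run_ga(X, d$phenotypes$survival, colnames(X), cfg, seed = 5)
  init <- init_population(40, cfg, derive_seed(5, 0))
  expect_identical(res$individuals,
                   lapply(init, function(i) colnames(X)[i]))
  expect_length(res$fitness, 20)
})

test_that("runs are reproducible and track a monotone best-ever fitness", {
  d <- null_dataset(16, 40, seed = 32)
  X <- t(log2(d$expression$values))
  y <- d$phenotypes$survival
  cfg <- small_cfg()
  a <- run_ga(X, y, colnames(X), cfg, seed = 11)
  b <- run_ga(X, y, colnames(X), cfg, seed = 11)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$fitness, b$fitness)
  expect_true(all(diff(a$history$best_ever) >= 0))
  sizes <- lengths(a$individuals)
  expect_true(all(sizes >= cfg$min_genes & sizes <= cfg$max_genes))
})

test_that("multi-population runs pool solutions with provenance", {
  d <- null_dataset(16, 40, seed = 33)
  X <- t(log2(d$expression$values))
  cfg <- ga_config(population_size = 10, n_generations = 2,
                   n_populations = 2, final_eval_runs = 2, seed = 3)
  sols <- run_multi(X, d$phenotypes$survival, colnames(X), cfg)
  expect_length(sols$individuals, 20)
  expect_identical(sols$population, rep(1:2, each = 10))
  sols2 <- run_multi(X, d$phenotypes$survival, colnames(X), cfg)
  expect_identical(sols$fitness, sols2$fitness)
})

test_that("the GA finds a strong planted signal in a tiny pool", {
  d <- generate_dataset(synth_config(
    n_samples = 32, n_genes = 12, n_signal_genes = 2,
    effect_weights = c(7, 5), noise_sd = 1, frac_absent_genes = 0,
    n_duplicate_blocks = 0, seed = 34))
  X <- t(log2(d$expression$values))
  cfg <- ga_config(population_size = 30, max_genes = 3, n_generations = 15,
                   n_populations = 1, final_eval_runs = 5, seed = 2)
  res <- run_ga(X, d$phenotypes$survival, colnames(X), cfg, seed = 2)
  best <- res$individuals[[which.max(res$fitness)]]
  expect_gte(length(intersect(best, d$truth$signal_gene_ids)), 1)
  expect_gt(max(res$fitness), 0.8)
})
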