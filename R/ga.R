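# Genetic-algorithm wrapper search over gene subsets.  Individuals are
# subsets of 1-20 pool genes; fitness is the 2-FCV R^2 of a PLS regression of
# survival on the subset.  Each generation: evaluate -> rank-proportional
# selection -> crossover of a fraction of individuals -> mutation of a
# fraction of individuals; after the last generation every individual is
# re-scored by repeated (default 10-run) 2-FCV.  Multiple independent
# populations are concatenated into the final solution set.

#' Configuration for the genetic-algorithm subset search
#'
#' Defaults follow the full-scale search design: populations of 500 subsets
#' of 1 to 20 genes, 90% mutation and 50% crossover per generation, 200
#' generations, 70 independent populations (35,000 final solutions), and a
#' final evaluation of 10 runs of two-fold cross-validation.
#' Desk-scale analyses shrink `population_size`, `n_generations` and
#' `n_populations`.
#'
#' @param population_size Individuals per population.
#' @param min_genes,max_genes Subset size bounds.
#' @param n_generations Number of evaluate/select/crossover/mutate cycles.
#' @param mutation_fraction Fraction of individuals mutated per generation.
#' @param crossover_fraction Fraction of individuals entering crossover per
#'   generation (paired randomly; an odd count leaves one unpaired).
#' @param n_populations Independent populations whose final individuals are
#'   pooled.
#' @param final_eval_runs Runs of 2-FCV in the final evaluation.
#' @param elitism Carry the generation's best individual(s) unchanged into
#'   the next population (default `TRUE`; `FALSE` reproduces the bare
#'   evolutionary scheme).
#' @param n_elite Number of top individuals carried over when `elitism` is
#'   on.
#' @param n_components PLS component cap passed to the scorer.
#' @param scale Autoscale predictors in the PLS fits.
#' @param seed Master seed; per-population and per-generation seeds are
#'   derived from it with [derive_seed()].
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 500,
                      min_genes = 1,
                      max_genes = 20,
                      n_generations = 200,
                      mutation_fraction = 0.90,
                      crossover_fraction = 0.50,
                      n_populations = 70,
                      final_eval_runs = 10,
                      elitism = TRUE,
                      n_elite = 5,
                      n_components = 2,
                      scale = TRUE,
                      seed = 1) {
  population_size <- .check_count(population_size, "population_size", min = 2)
  min_genes <- .check_count(min_genes, "min_genes", min = 1)
  max_genes <- .check_count(max_genes, "max_genes", min = min_genes)
  n_generations <- .check_count(n_generations, "n_generations", min = 0)
  .check_fraction(mutation_fraction, "mutation_fraction")
  .check_fraction(crossover_fraction, "crossover_fraction")
  n_populations <- .check_count(n_populations, "n_populations", min = 1)
  final_eval_runs <- .check_count(final_eval_runs, "final_eval_runs", min = 1)
  n_elite <- .check_count(n_elite, "n_elite", min = 1)
  if (n_elite >= population_size) .fail("n_elite must be < population_size")
  n_components <- .check_count(n_components, "n_components", min = 1)
  structure(list(population_size = population_size, min_genes = min_genes,
                 max_genes = max_genes, n_generations = n_generations,
                 mutation_fraction = mutation_fraction,
                 crossover_fraction = crossover_fraction,
                 n_populations = n_populations,
                 final_eval_runs = final_eval_runs,
                 elitism = isTRUE(elitism), n_elite = n_elite,
                 n_components = n_components,
                 scale = isTRUE(scale), seed = as.integer(seed)),
            class = "ga_config")
}

# individuals are integer index vectors into the pool (sorted for stable
# memoization keys); public results translate them back to gene ids

.valid_individual <- function(ind, config, pool_size) {
  length(ind) >= config$min_genes && length(ind) <= config$max_genes &&
    !anyDuplicated(ind) && all(ind >= 1 & ind <= pool_size)
}

#' Initialize a GA population of random gene subsets
#'
#' Each individual's size is drawn uniformly from
#' `[min_genes, max_genes]` and its genes are sampled without replacement
#' from the pool.
#'
#' @param pool_size Number of genes in the pool.
#' @param config A [ga_config()].
#' @param seed Integer seed.
#' @return A list of `population_size` integer index vectors.
#' @export
init_population <- function(pool_size, config, seed = config$seed) {
  stopifnot(inherits(config, "ga_config"))
  pool_size <- .check_count(pool_size, "pool_size", min = 1)
  if (pool_size < config$max_genes) {
    .fail("pool (%d genes) smaller than max_genes (%d)",
          pool_size, config$max_genes)
  }
  withr::with_seed(seed, {
    sizes <- sample(config$min_genes:config$max_genes,
                    config$population_size, replace = TRUE)
    lapply(sizes, function(s) sort(sample.int(pool_size, s)))
  })
}

# draw one pool gene not already in `ind` (pool >> subset, so rejection
# sampling is cheap; falls back to setdiff for tiny pools)
.draw_new_gene <- function(ind, pool_size) {
  if (pool_size - length(ind) <= 0) return(NA_integer_)
  if (pool_size > 4 * length(ind)) {
    repeat {
      g <- sample.int(pool_size, 1)
      if (!(g %in% ind)) return(g)
    }
  }
  cand <- setdiff(seq_len(pool_size), ind)
  cand[sample.int(length(cand), 1)]
}

#' Evaluate a population by two-fold cross-validated R-squared
#'
#' Fitness of each individual is the 2-FCV R^2 of the PLS regression of
#' survival on the individual's genes. One shared random split (drawn from
#' `seed`) is used for the whole population so fitness values are comparable
#' within a generation; duplicate individuals therefore receive identical
#' fitness.
#'
#' @param population List of integer index vectors (see [init_population()]).
#' @param X Samples x pool-genes numeric matrix.
#' @param y Survival vector.
#' @param config A [ga_config()].
#' @param seed Generation seed for the shared split.
#' @return Numeric fitness vector.
#' @export
evaluate_population <- function(population, X, y, config, seed) {
  stopifnot(inherits(config, "ga_config"))
  n <- length(y)
  perm <- withr::with_seed(seed, sample.int(n))
  memo <- new.env(hash = TRUE, parent = emptyenv())
  vapply(population, function(ind) {
    key <- paste(ind, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    r2 <- .cv_r2_split(X[, ind, drop = FALSE], y, config$n_components, perm,
                       scale = config$scale)
    memo[[key]] <- r2
    r2
  }, numeric(1))
}

#' Rank-proportional parent selection
#'
#' Individuals are ranked ascending by fitness (rank 1 = worst; ties share
#' ordinal ranks by stable input order) and sampled with replacement with
#' probability proportional to rank, back to the population size.
#'
#' @param population List of individuals.
#' @param fitness Numeric fitness vector.
#' @param seed Integer seed.
#' @return A list of selected parents (same length as `population`).
#' @export
select_parents <- function(population, fitness, seed) {
  stopifnot(length(population) == length(fitness))
  r <- rank(fitness, ties.method = "first")
  withr::with_seed(seed, {
    idx <- sample.int(length(population), length(population),
                      replace = TRUE, prob = r / sum(r))
    population[idx]
  })
}

# one mutation: uniformly among the feasible operations add / remove /
# replace.  Caller seeds the RNG.
.mutate_one <- function(ind, pool_size, config) {
  ops <- c(if (length(ind) < config$max_genes && length(ind) < pool_size)
             "add",
           if (length(ind) > config$min_genes) "remove",
           if (pool_size > length(ind)) "replace")
  if (length(ops) == 0) return(ind)
  op <- ops[sample.int(length(ops), 1)]
  if (op == "add") {
    sort(c(ind, .draw_new_gene(ind, pool_size)))
  } else if (op == "remove") {
    sort(ind[-sample.int(length(ind), 1)])
  } else {
    out <- ind[-sample.int(length(ind), 1)]
    sort(c(out, .draw_new_gene(out, pool_size)))
  }
}

#' Mutate a gene subset
#'
#' Applies one operation chosen uniformly among the feasible ones: add a
#' random pool gene, remove a random gene, or replace one gene by a random
#' pool gene. Additions are never drawn at the maximum size and removals
#' never at the minimum, so the result always satisfies the size bounds.
#'
#' @param individual Integer index vector.
#' @param pool_size Number of genes in the pool.
#' @param config A [ga_config()].
#' @param seed Integer seed.
#' @return The mutated individual.
#' @export
mutate_individual <- function(individual, pool_size, config, seed) {
  withr::with_seed(seed, .mutate_one(individual, pool_size, config))
}

# one crossover: each parent's gene set is split uniformly at random into
# two parts; the second parts are exchanged.  Genes shared by both parents
# stay in both children (exchanging them is a no-op, so identical parents
# reproduce themselves exactly); children are deduplicated by construction
# and repaired to the size bounds.  Caller seeds the RNG.
.crossover_one <- function(a, b, pool_size, config) {
  common <- intersect(a, b)
  in_a1 <- stats::runif(length(a)) < 0.5
  in_b1 <- stats::runif(length(b)) < 0.5
  child_a <- unique(c(common, a[in_a1], b[!in_b1]))
  child_b <- unique(c(common, b[in_b1], a[!in_a1]))
  repair <- function(ch) {
    if (length(ch) > config$max_genes) {
      ch <- ch[sample.int(length(ch), config$max_genes)]
    }
    while (length(ch) < config$min_genes) {
      ch <- c(ch, .draw_new_gene(ch, pool_size))
    }
    sort(ch)
  }
  list(repair(child_a), repair(child_b))
}

#' Cross over two gene subsets
#'
#' Randomly partitions each parent's gene set into two parts and exchanges
#' one part between the parents. Genes present in both parents remain in
#' both children (so identical parents reproduce themselves). Children are
#' deduplicated; a child exceeding `max_genes` is trimmed at random, one
#' below `min_genes` gets random pool genes added.
#'
#' @param parent_a,parent_b Integer index vectors.
#' @inheritParams mutate_individual
#' @return A list of the two children.
#' @export
crossover <- function(parent_a, parent_b, pool_size, config, seed) {
  withr::with_seed(seed,
                   .crossover_one(parent_a, parent_b, pool_size, config))
}

#' Run one GA population
#'
#' Evolves `population_size` gene subsets for `n_generations` cycles of
#' evaluate / rank-proportional select / crossover / mutate, then scores
#' every individual of the final population by repeated 2-FCV
#' (`final_eval_runs` splits). With `elitism` the best individual of each
#' generation is carried over unchanged, so the recorded best-ever fitness is
#' non-decreasing. With `n_generations = 0` the initial population is scored
#' directly.
#'
#' @param X Samples x pool-genes numeric matrix (columns ordered as
#'   `pool_ids`).
#' @param y Survival vector.
#' @param pool_ids Character vector of pool gene identifiers.
#' @param config A [ga_config()].
#' @param seed Population seed (defaults to `config$seed`).
#' @return A list of class `ga_result`: `individuals` (list of gene-id
#'   vectors), `fitness` (mean repeated-CV R^2), `per_run_r2` (matrix), and a
#'   `history` data.frame with per-generation best/mean/best-ever fitness.
#' @export
run_ga <- function(X, y, pool_ids, config, seed = config$seed) {
  stopifnot(inherits(config, "ga_config"))
  X <- as.matrix(X)
  if (ncol(X) != length(pool_ids)) {
    .fail("ncol(X) (%d) must equal length(pool_ids) (%d)",
          ncol(X), length(pool_ids))
  }
  pool_size <- length(pool_ids)
  pop <- init_population(pool_size, config, derive_seed(seed, 0))
  history <- data.frame(generation = integer(0), best = numeric(0),
                        mean = numeric(0), best_ever = numeric(0))
  best_ever <- -Inf

  for (g in seq_len(config$n_generations)) {
    fit <- evaluate_population(pop, X, y, config, derive_seed(seed, g, 1))
    elite <- pop[order(fit, decreasing = TRUE)[seq_len(config$n_elite)]]
    best_ever <- max(best_ever, max(fit))
    history <- rbind(history, data.frame(generation = g, best = max(fit),
                                         mean = mean(fit),
                                         best_ever = best_ever))
    pop <- select_parents(pop, fit, derive_seed(seed, g, 2))

    # crossover phase: a random crossover_fraction of individuals, paired
    withr::with_seed(derive_seed(seed, g, 3), {
      n_cross <- floor(config$crossover_fraction * length(pop) / 2) * 2
      if (n_cross >= 2) {
        who <- sample.int(length(pop), n_cross)
        for (k in seq_len(n_cross / 2)) {
          i <- who[2 * k - 1]; j <- who[2 * k]
          ch <- .crossover_one(pop[[i]], pop[[j]], pool_size, config)
          pop[[i]] <- ch[[1]]; pop[[j]] <- ch[[2]]
        }
      }
    })

    # mutation phase: a random mutation_fraction of individuals
    withr::with_seed(derive_seed(seed, g, 4), {
      n_mut <- round(config$mutation_fraction * length(pop))
      if (n_mut >= 1) {
        who <- sample.int(length(pop), n_mut)
        for (i in who) pop[[i]] <- .mutate_one(pop[[i]], pool_size, config)
      }
    })

    if (config$elitism) pop[seq_len(config$n_elite)] <- elite
  }

  # final extensive evaluation: repeated 2-FCV, shared seeds across
  # individuals so scores are comparable (and identical subsets tie exactly)
  final_seed <- derive_seed(seed, config$n_generations + 1, 9)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  per_run <- matrix(NA_real_, length(pop), config$final_eval_runs)
  for (i in seq_along(pop)) {
    key <- paste(pop[[i]], collapse = ",")
    hit <- memo[[key]]
    if (is.null(hit)) {
      hit <- repeated_cv(X[, pop[[i]], drop = FALSE], y,
                         n_components = config$n_components,
                         n_runs = config$final_eval_runs,
                         base_seed = final_seed,
                         scale = config$scale)$per_run_r2
      memo[[key]] <- hit
    }
    per_run[i, ] <- hit
  }
  fitness <- rowMeans(per_run)
  structure(list(individuals = lapply(pop, function(i) pool_ids[i]),
                 fitness = fitness, per_run_r2 = per_run,
                 history = history, seed = as.integer(seed),
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("ga_result: %d final individuals, best mean %d-run 2-FCV R2 = %.4f\n",
              length(x$individuals), x$config$final_eval_runs,
              max(x$fitness)))
  invisible(x)
}

#' Run multiple independent GA populations
#'
#' Executes `n_populations` independent [run_ga()] searches with
#' per-population seeds derived from the master seed and concatenates their
#' final individuals into one solution set with population provenance
#' (e.g. 70 populations x 500 individuals = 35,000 final solutions at full
#' scale).
#'
#' @inheritParams run_ga
#' @return A list of class `ga_solutions`: `individuals` (list of gene-id
#'   vectors), `fitness`, `population` (index per solution), `seeds`,
#'   `config`, `source = "actual"`.
#' @export
run_multi <- function(X, y, pool_ids, config) {
  stopifnot(inherits(config, "ga_config"))
  seeds <- vapply(seq_len(config$n_populations),
                  function(p) derive_seed(config$seed, 100, p), integer(1))
  runs <- lapply(seq_len(config$n_populations), function(p) {
    run_ga(X, y, pool_ids, config, seed = seeds[p])
  })
  structure(list(
    individuals = do.call(c, lapply(runs, `[[`, "individuals")),
    fitness = do.call(c, lapply(runs, `[[`, "fitness")),
    population = rep(seq_len(config$n_populations),
                     each = config$population_size),
    seeds = seeds, config = config, source = "actual"),
    class = "ga_solutions")
}

#' @export
print.ga_solutions <- function(x, ...) {
  cat(sprintf("ga_solutions (%s): %d solutions from %d population(s); best R2 = %.4f\n",
              x$source, length(x$individuals),
              length(unique(x$population)), max(x$fitness)))
  invisible(x)
}
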