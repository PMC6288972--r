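# cheap deterministic evaluator for lattice-mechanics tests
stub_evaluator <- function(fitness = 1, n_good = 1L) {
  force(fitness); force(n_good)
  function(g) list(fitness = fitness, report = list(n_good = n_good))
}

test_that("Margolus diffusion permutes occupants and preserves emptiness", {
  set.seed(30)
  g <- matrix(0L, 12, 12); g[sample(144, 40)] <- 1:40
  for (i in 1:20) {
    g2 <- margolus_diffuse(g)
    expect_setequal(g2[g2 > 0], 1:40)
    expect_equal(sum(g2 == 0), 144 - 40)
    g <- g2
  }
  empty <- matrix(0L, 10, 10)
  expect_identical(margolus_diffuse(empty), empty)
})

test_that("a lone diffusing individual mixes uniformly over its parity class", {
  # each rotation moves an occupant to an adjacent cell, so a full update
  # (two half-steps) conserves the checkerboard parity of its site: a lone
  # walker observed at update boundaries lives on one 50-site colour class
  # and should visit it uniformly (positions thinned to reduce the
  # autocorrelation of single-step moves)
  set.seed(31)
  g <- matrix(0L, 10, 10); g[5, 5] <- 1L
  counts <- numeric(100)
  for (i in 1:20000) {
    g <- margolus_diffuse(g)
    if (i %% 10 == 0) {
      w <- which(g == 1L)
      counts[w] <- counts[w] + 1
    }
  }
  idx <- which(counts > 0)
  parity <- ((idx - 1) %% 10 + (idx - 1) %/% 10) %% 2
  expect_equal(length(idx), 50)
  expect_true(all(parity == parity[1]))
  expect_gt(chisq.test(counts[idx])$p.value, 0.001)
})

test_that("death is binomial and without births the population only shrinks", {
  set.seed(32)
  cfg <- evo_config(grid_w = 30, grid_h = 30, n_initial = 900,
                    death_rate = 0.5, n_steps = 1)
  pop <- init_population(init_random_genome(seed = 1), cfg,
                         stub_evaluator(fitness = 0))
  expect_equal(length(pop$inds), 900)
  pop1 <- evolution_step(pop, cfg, stub_evaluator(fitness = 0))
  survivors <- length(pop1$inds)
  expect_gt(survivors, 450 - 3 * 15) # binomial 3 sigma
  expect_lt(survivors, 450 + 3 * 15)
  expect_equal(sum(pop1$grid > 0), survivors)
})

test_that("parents are drawn in proportion to fitness", {
  founder <- init_random_genome(seed = 2)
  set.seed(33)
  # the 7x7 window covers the whole 4x4 torus, so every empty site
  # competes between exactly the two founders, at fitnesses 1 and 3
  cfg <- evo_config(grid_w = 4, grid_h = 4, n_initial = 2,
                    death_rate = 0, n_steps = 1, neighbourhood = 7)
  ev <- function(g) list(fitness = 1, report = list(n_good = 1L))
  zero <- mutation_rates(0, 0, 0, 0, 0, 0, 0)
  n1 <- 0; n3 <- 0
  for (rep in 1:120) {
    pop <- init_population(founder, cfg, ev)
    pop$inds[[2]]$fit$fitness <- 3
    pop1 <- evolution_step(pop, cfg, ev, zero)
    ln <- vapply(pop1$inds, function(i) i$lineage, 0L)
    n1 <- n1 + sum(ln == 1) - 1 # subtract the founders themselves
    n3 <- n3 + sum(ln == 2) - 1
  }
  frac <- n3 / (n1 + n3)
  se <- sqrt(0.75 * 0.25 / (n1 + n3))
  expect_gt(frac, 0.75 - 3 * se)
  expect_lt(frac, 0.75 + 3 * se)
})

test_that("the population can fill but never exceed the lattice", {
  set.seed(34)
  cfg <- evo_config(grid_w = 30, grid_h = 30, n_initial = 50,
                    death_rate = 0.2, n_steps = 1)
  pop <- init_population(init_random_genome(seed = 3), cfg, stub_evaluator())
  sizes <- integer(40)
  for (s in 1:40) {
    pop <- evolution_step(pop, cfg, stub_evaluator(),
                          mutation_rates(0, 0, 0, 0, 0, 0, 0))
    sizes[s] <- length(pop$inds)
    expect_equal(sum(pop$grid > 0), sizes[s])
  }
  expect_lte(max(sizes), 900)
  expect_equal(sizes[40], 900) # death 0.2 with full refill saturates the torus
})

test_that("zero-step runs return the founder population unchanged", {
  cfg <- evo_config(grid_w = 10, grid_h = 10, n_initial = 50, n_steps = 0)
  r <- run_evolution(cfg, seed = 40, evaluator = stub_evaluator())
  expect_equal(length(r$population$inds), 50)
  keys <- vapply(r$population$inds,
                 function(i) paste(format_genome(i$genome), collapse = ";"),
                 "")
  expect_equal(length(unique(keys)), 1)
  expect_equal(nrow(r$stats), 0)
})

test_that("runs are exactly reproducible from (config, seed)", {
  cfg <- evo_config(grid_w = 6, grid_h = 6, n_initial = 8, n_steps = 5)
  r1 <- run_evolution(cfg, morphogen = morphogen_config(d = 0.2), seed = 41)
  r2 <- run_evolution(cfg, morphogen = morphogen_config(d = 0.2), seed = 41)
  expect_identical(r1$stats, r2$stats)
  expect_identical(format_genome(r1$best$genome), format_genome(r2$best$genome))
})

test_that("with zero total fitness no site is ever filled", {
  set.seed(42)
  cfg <- evo_config(grid_w = 10, grid_h = 10, n_initial = 60,
                    death_rate = 0.3, n_steps = 1)
  pop <- init_population(init_random_genome(seed = 5), cfg,
                         stub_evaluator(fitness = 0))
  sizes <- integer(10)
  for (s in 1:10) {
    pop <- evolution_step(pop, cfg, stub_evaluator(fitness = 0))
    sizes[s] <- length(pop$inds)
  }
  expect_true(all(diff(c(60, sizes)) <= 0))
})

test_that("switching the gradient onto itself is a no-op", {
  g <- make_fixture_genome("gated_clock_and_switch")
  cfg <- evo_config(grid_w = 6, grid_h = 6, n_initial = 5, n_steps = 0)
  sw <- switch_gradient_experiment(g, old_d = 0.2, new_d = 0.2, cfg = cfg,
                                   seed = 50)
  expect_equal(sw$segment_ratio, 1)
  expect_equal(sw$recovery_step, 0)
})

test_that("the segmentation pattern genuinely depends on the gradient", {
  g <- make_fixture_genome("gated_clock_and_switch")
  pre <- score_genome(g, morphogen = morphogen_config(d = 0.2))
  post <- score_genome(g, morphogen = morphogen_config(d = 0.025))
  expect_gte(pre$report$n_good, 2)
  expect_gte(post$report$n_good, 2)
  # a slower-decaying gradient shifts every boundary: the pattern is not
  # simply carried over when the wavefront speed changes
  expect_false(identical(pre$report$boundaries, post$report$boundaries))
})
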