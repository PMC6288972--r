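fp <- fitness_params()

test_that("pattern averaging returns per-cell time mean and population variance", {
  m <- rbind(rep(7, 100), rep(c(0, 20), 50))
  avg <- average_segmentation_expression(m, 100)
  expect_equal(avg$mean, c(7, 10))
  expect_equal(avg$var, c(0, 100))
  expect_error(average_segmentation_expression(m[, 1:50, drop = FALSE], 100),
               "control period")
})

test_that("segment calling reproduces the canonical patterns", {
  hi <- 2 * fp$theta_hi
  # all-low head + uniformly expressing body: the two-segment stage
  two <- c(rep(0, 9), rep(hi, 125))
  rep2 <- call_segments(two, fp)
  expect_equal(rep2$n_good, 2)
  expect_equal(rep2$n_narrow, 0)
  expect_equal(rep2$boundaries, 10)

  # a fully low tissue is a single wide segment
  expect_equal(call_segments(rep(0, 134), fp)$n_good, 1)

  # a 6-cell high plateau between wide low plateaus is narrow
  narrow <- c(rep(0, 60), rep(hi, 6), rep(0, 68))
  repn <- call_segments(narrow, fp)
  expect_equal(repn$n_good, 2)
  expect_equal(repn$n_narrow, 1)

  # a transition wider than five cells is not a boundary
  mid <- (fp$theta_hi + fp$theta_lo) / 2
  blur <- c(rep(0, 30), rep(mid, 6), rep(hi, 93), rep(hi, 5))
  repb <- call_segments(blur, fp)
  expect_equal(repb$n_good, 0) # neither plateau has two valid sides
  blur5 <- c(rep(0, 30), rep(mid, 5), rep(hi, 94), rep(hi, 5))
  expect_equal(call_segments(blur5, fp)$n_good, 2)
})

test_that("segment calling agrees with an independent reference on random patterns", {
  set.seed(14)
  small <- fitness_params(min_segment_width = 3, max_boundary_width = 2,
                          n_growth_zone = 2)
  for (i in 1:300) {
    n <- sample(5:30, 1)
    mean_expr <- sample(c(0, (small$theta_hi + small$theta_lo) / 2,
                          2 * small$theta_hi), n, replace = TRUE)
    got <- call_segments(mean_expr, small)
    ref <- reference_call_segments(mean_expr, small)
    expect_equal(got$n_good, ref$n_good, info = paste(mean_expr, collapse = ","))
    expect_equal(got$n_narrow, ref$n_narrow, info = paste(mean_expr, collapse = ","))
  }
})

test_that("segment calling is invariant under joint rescaling", {
  set.seed(15)
  mean_expr <- runif(60, 0, 400)
  a <- call_segments(mean_expr, fp)
  scaled <- fitness_params(theta_hi = fp$theta_hi * 3.7,
                           theta_lo = fp$theta_lo * 3.7)
  b <- call_segments(mean_expr * 3.7, scaled)
  expect_equal(a$n_good, b$n_good)
  expect_equal(a$n_narrow, b$n_narrow)
  expect_equal(a$boundaries, b$boundaries)
})

test_that("unstable cells are counted strictly above the variance threshold", {
  expect_equal(count_unstable_cells(c(0, 0, 0), fp), 0)
  expect_equal(count_unstable_cells(c(4.9, 5.0, 5.1), fp), 1)
  expect_equal(count_unstable_cells(100, fp), 1) # the alternating 0/20 cell
})

test_that("the fitness score matches hand-computed values exactly", {
  g20 <- genome(c(lapply(0:15, gene),
                  lapply(1:4, function(t)
                    gene(t, lapply(1:10, function(i) c(1L, 1L))))))
  expect_equal(n_genes(g20), 20)
  expect_equal(n_tfbs(g20), 40)
  rep10 <- list(n_good = 10, n_narrow = 0)
  res <- evaluate_fitness(g20, rep10, n_unstable = 0, fp)
  expect_equal(res$F, 10 - 20 * 0.0005 - 40 * 0.00005, tolerance = 1e-12)
  expect_equal(res$F, 9.988, tolerance = 1e-12)
  expect_equal(res$fitness, exp(9.988) - 1, tolerance = 1e-12)

  # F <= 0 gives zero fitness; a missing gene type forces zero
  expect_equal(evaluate_fitness(g20, list(n_good = 0, n_narrow = 1), 0, fp)$fitness, 0)
  g_missing <- genome(lapply(1:15, gene))
  res0 <- evaluate_fitness(g_missing, rep10, 0, fp)
  expect_false(res0$viable)
  expect_equal(res0$fitness, 0)
})

test_that("fitness is monotone in its components", {
  g <- init_random_genome(seed = 16)
  f <- function(good, narrow, unstable)
    evaluate_fitness(g, list(n_good = good, n_narrow = narrow), unstable, fp)$fitness
  expect_gt(f(5, 0, 0), f(4, 0, 0))
  expect_gt(f(5, 0, 0), f(5, 1, 0))
  expect_gt(f(5, 0, 0), f(5, 0, 3))
})

test_that("the segment maximum on the standard geometry is 18, verified by a witness", {
  res <- max_good_segments(134, 9, fp)
  expect_equal(res$n_max, 18)
  expect_true(res$verified)
  expect_equal(length(res$pattern), 134)
  expect_equal(call_segments(res$pattern, fp)$n_good, 18)
})

test_that("the run-length maximiser matches exhaustive search on small tissues", {
  small <- fitness_params(min_segment_width = 3, max_boundary_width = 2,
                          n_growth_zone = 2)
  hi <- 2 * small$theta_hi
  for (n_cells in c(8, 10, 12)) {
    n_head <- 2
    L <- n_cells - small$n_growth_zone
    free <- L - n_head
    best <- 0
    for (code in 0:(2^free - 1)) {
      bits <- as.integer(intToBits(code))[seq_len(free)]
      pat <- c(rep(0, n_head), bits * hi, rep(0, small$n_growth_zone))
      best <- max(best, call_segments(pat, small)$n_good)
    }
    expect_equal(max_good_segments(n_cells, n_head, small)$n_max, best,
                 info = paste("n_cells =", n_cells))
  }
})
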