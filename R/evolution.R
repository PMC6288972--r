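#' Margolus diffusion of the population lattice
#'
#' One diffusion update: two Margolus half-steps, one on each 2x2 block
#' partition (even, then odd offset), with toroidal wrap. Every block is
#' independently rotated 90 degrees clockwise or counter-clockwise with
#' probability 1/2. Occupancy is conserved: diffusion only permutes sites.
#'
#' @param grid integer matrix (0 = empty site); both dimensions must be
#'   even so the block partitions tile the torus.
#' @return The diffused grid.
#' @export
margolus_diffuse <- function(grid) {
  stopifnot(nrow(grid) %% 2 == 0, ncol(grid) %% 2 == 0)
  margolus_half(margolus_half(grid, 0L), 1L)
}

margolus_half <- function(grid, offset) {
  n <- nrow(grid); m <- ncol(grid)
  ro <- ((seq_len(n) - 1 + offset) %% n) + 1
  co <- ((seq_len(m) - 1 + offset) %% m) + 1
  g <- grid[ro, co]
  # column-major linear indices of each block's corners
  a <- as.vector(outer(seq(1, n, 2), (seq(1, m, 2) - 1) * n, `+`)) # top-left
  b <- a + n      # top-right
  bl <- a + 1     # bottom-left
  d <- a + n + 1  # bottom-right
  cw <- stats::runif(length(a)) < 0.5
  out <- g
  out[c(a[cw], b[cw], d[cw], bl[cw])] <- g[c(bl[cw], a[cw], b[cw], d[cw])]
  out[c(a[!cw], b[!cw], d[!cw], bl[!cw])] <- g[c(b[!cw], d[!cw], bl[!cw], a[!cw])]
  unshifted <- out
  unshifted[ro, co] <- out
  unshifted
}

#' Initialise a population lattice
#'
#' Places `n_initial` identical copies of a founder genome at random sites
#' of the lattice. The founder is evaluated once (all copies share the
#' result).
#'
#' @param founder a `cw_genome`.
#' @param cfg an [evo_config()].
#' @param evaluator function mapping a genome to a `cw_fitness_result`
#'   (see [build_evaluator()]).
#' @return A `cw_population`: list with `grid` (integer matrix indexing
#'   into `inds`; 0 = empty), `inds` (list of individuals, each with
#'   `genome`, `fit`, `lineage`) and `step`.
#' @export
init_population <- function(founder, cfg = evo_config(), evaluator) {
  grid <- matrix(0L, cfg$grid_h, cfg$grid_w)
  sites <- sample.int(length(grid), cfg$n_initial)
  fit <- evaluator(founder)
  inds <- lapply(seq_len(cfg$n_initial), function(i)
    list(genome = founder, fit = fit, lineage = i))
  grid[sites] <- seq_len(cfg$n_initial)
  structure(list(grid = grid, inds = inds, step = 0L),
            class = "cw_population")
}

#' @export
print.cw_population <- function(x, ...) {
  cat(sprintf("<cw_population> %d individuals on a %dx%d lattice (step %d)\n",
              length(x$inds), nrow(x$grid), ncol(x$grid), x$step))
  invisible(x)
}

#' One evolutionary step
#'
#' In order: (1) every individual dies with probability `death_rate`;
#' (2) Margolus diffusion; (3) every empty site, visited in random order, is
#' competed for by the individuals in its local neighbourhood (taken from
#' the post-diffusion, pre-reproduction snapshot, so a newborn cannot
#' parent within the same step): a parent is drawn with probability
#' `f_i / sum_j f_j`, its offspring genome is mutated, developed and scored,
#' and placed in the site. Sites whose neighbourhood holds no positive
#' fitness stay empty.
#'
#' @param pop a `cw_population`.
#' @param cfg an [evo_config()].
#' @param evaluator genome -> `cw_fitness_result` function.
#' @param rates a [mutation_rates()] object.
#' @param reuse_parent_fit when the mutation operators leave an offspring
#'   genome untouched, reuse the parent's fitness instead of re-evaluating.
#'   Only exact when evaluation is deterministic (noise off);
#'   [run_evolution()] enables it in that case.
#' @return The updated `cw_population`.
#' @export
evolution_step <- function(pop, cfg = evo_config(), evaluator,
                           rates = mutation_rates(),
                           reuse_parent_fit = FALSE) {
  grid <- pop$grid
  inds <- pop$inds
  H <- nrow(grid); W <- ncol(grid)

  occ <- which(grid > 0L)
  if (length(occ) > 0 && cfg$death_rate > 0) {
    dies <- stats::runif(length(occ)) < cfg$death_rate
    grid[occ[dies]] <- 0L
  }

  grid <- margolus_diffuse(grid)

  snapshot <- grid
  fvec <- vapply(inds, function(i) i$fit$fitness, 0.0)
  empty <- which(snapshot == 0L)
  if (length(empty) > 1) empty <- empty[sample.int(length(empty))]
  k <- (cfg$neighbourhood - 1L) %/% 2L
  newborn_sites <- integer(0)
  newborns <- list()
  for (e in empty) {
    r <- ((e - 1L) %% H) + 1L
    cc <- ((e - 1L) %/% H) + 1L
    # unique() guards small lattices where the toroidal window wraps onto
    # itself: an individual competes once however often the torus repeats
    ids <- snapshot[unique(((r - 1L + (-k:k)) %% H) + 1L),
                    unique(((cc - 1L + (-k:k)) %% W) + 1L)]
    ids <- ids[ids > 0L]
    if (length(ids) == 0) next
    fs <- fvec[ids]
    tot <- sum(fs)
    if (tot <= 0) next
    pid <- if (length(ids) == 1L) ids else sample(ids, 1L, prob = fs)
    parent <- inds[[pid]]
    child <- mutate_genome(parent$genome, rates)
    fit <- if (reuse_parent_fit && identical(child, parent$genome))
      parent$fit else evaluator(child)
    newborns[[length(newborns) + 1L]] <-
      list(genome = child, fit = fit, lineage = parent$lineage)
    newborn_sites <- c(newborn_sites, e)
  }

  # compact: re-index survivors, then append the newborns
  alive <- which(grid > 0L)
  new_inds <- inds[grid[alive]]
  remap <- grid
  remap[alive] <- seq_along(alive)
  if (length(newborn_sites) > 0) {
    remap[newborn_sites] <- length(alive) + seq_along(newborn_sites)
    new_inds <- c(new_inds, newborns)
  }
  pop$grid <- remap
  pop$inds <- new_inds
  pop$step <- pop$step + 1L
  pop
}

#' Build the default genome evaluator
#'
#' Returns a closure that develops and scores a genome under the given
#' conditions ([score_genome()]). With noise off, development is
#' deterministic, so results are memoized by serialized genome; with noise
#' on, every call is a fresh realization (an individual's fitness is
#' evaluated once, at birth).
#'
#' @inheritParams score_genome
#' @param cache memoize deterministic evaluations (default: iff noise off).
#' @return A function `genome -> cw_fitness_result`.
#' @export
build_evaluator <- function(schedule = dev_schedule(),
                            morphogen = morphogen_config(),
                            params = kinetic_params(),
                            noise = noise_model(),
                            fitness = fitness_params(),
                            headless = FALSE,
                            cache = noise$l == 0) {
  memo <- new.env(parent = emptyenv())
  n_head <- if (headless) 0L else schedule$n_head
  function(g) {
    fg <- flatten_genome(g)
    if (cache) {
      key <- paste(c(fg$gene_types, 99L, fg$site_gene, fg$site_type,
                     fg$site_weight), collapse = " ")
      hit <- get0(key, envir = memo, inherits = FALSE)
      if (!is.null(hit)) return(hit)
    }
    # lean inline scoring pipeline (per-cell pattern table not retained;
    # use score_genome() directly when it is wanted)
    raw <- develop_cpp(fg$gene_types, fg$site_gene, fg$site_type,
                       fg$site_weight,
                       schedule$n_steps_total, schedule$n_steps_growth,
                       schedule$division_interval, n_head,
                       schedule$n_growth_zone,
                       params$E, params$delta, params$H, params$n, params$dt,
                       morphogen$d, morphogen$M_max, noise$l,
                       schedule$control_period, FALSE)
    m <- raw$seg_record
    mu <- rowMeans(m)
    va <- rowMeans(m * m) - mu * mu
    rep_ <- call_segments(mu, fitness)
    res <- evaluate_fitness(g, rep_, sum(va > fitness$var_threshold), fitness)
    if (cache) assign(key, res, envir = memo)
    res
  }
}

#' Run an evolutionary simulation
#'
#' Initialises the lattice with identical copies of a founder genome and
#' iterates [evolution_step()]. Per-step statistics (population size,
#' max/mean fitness, best segment count) are logged, together with the
#' waiting times until individuals with >= 2 and >= 10 well-formed segments
#' first appear. Fully reproducible from (configuration, seed).
#'
#' @param cfg an [evo_config()].
#' @param schedule,morphogen,params,noise,fitness developmental and scoring
#'   configuration (see [score_genome()]).
#' @param rates a [mutation_rates()] object.
#' @param seed optional integer seed covering the whole run.
#' @param init_genome founder genome; default a fresh
#'   [init_random_genome()] with `cfg$mean_tfbs` sites per gene.
#' @param headless develop embryos without head cells.
#' @param evaluator override the genome evaluator (default
#'   [build_evaluator()] with the run's configuration); mainly useful for
#'   testing lattice dynamics in isolation.
#' @param stop_when_good stop early once the best individual reaches this
#'   many well-formed segments (`NULL` = run all `cfg$n_steps`). Waiting
#'   times recorded up to the stopping step are unaffected.
#' @return A `cw_evolution`: list with `stats` (one row per step), `best`
#'   (highest-fitness final individual or `NULL`), `population`,
#'   `first_two`/`first_ten` (earliest step whose best individual had >= 2
#'   / >= 10 good segments; `NA` if never), `extinct` flag and the
#'   configuration.
#' @export
run_evolution <- function(cfg = evo_config(),
                          schedule = dev_schedule(),
                          morphogen = morphogen_config(),
                          params = kinetic_params(),
                          noise = noise_model(),
                          fitness = fitness_params(),
                          rates = mutation_rates(),
                          seed = NULL, init_genome = NULL,
                          headless = FALSE, evaluator = NULL,
                          stop_when_good = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reuse <- is.null(evaluator) && noise$l == 0 # deterministic evaluation
  if (is.null(evaluator))
    evaluator <- build_evaluator(schedule, morphogen, params, noise, fitness,
                                 headless = headless)
  founder <- if (is.null(init_genome))
    init_random_genome(mean_tfbs = cfg$mean_tfbs) else init_genome
  pop <- init_population(founder, cfg, evaluator)

  n <- cfg$n_steps
  s_pop <- rep(NA_integer_, n)
  s_maxf <- rep(NA_real_, n)
  s_meanf <- rep(NA_real_, n)
  s_good <- rep(NA_integer_, n)
  best_good0 <- max(vapply(pop$inds, function(i) i$fit$report$n_good, 0L), 0L)
  first_two <- if (best_good0 >= 2) 0L else NA_integer_
  first_ten <- if (best_good0 >= 10) 0L else NA_integer_
  extinct <- FALSE
  last <- 0L

  for (s in seq_len(n)) {
    pop <- evolution_step(pop, cfg, evaluator, rates,
                          reuse_parent_fit = reuse)
    last <- s
    np <- length(pop$inds)
    if (np == 0) {
      s_pop[s] <- 0L; s_maxf[s] <- 0; s_meanf[s] <- 0; s_good[s] <- 0L
      extinct <- TRUE
      break
    }
    f <- vapply(pop$inds, function(i) i$fit$fitness, 0.0)
    mg <- max(vapply(pop$inds, function(i) i$fit$report$n_good, 0L))
    s_pop[s] <- np; s_maxf[s] <- max(f); s_meanf[s] <- mean(f)
    s_good[s] <- mg
    if (is.na(first_two) && mg >= 2) first_two <- s
    if (is.na(first_ten) && mg >= 10) first_ten <- s
    if (!is.null(stop_when_good) && mg >= stop_when_good) break
  }
  keep <- seq_len(last)
  stats <- data.frame(step = keep, pop_size = s_pop[keep],
                      max_fitness = s_maxf[keep],
                      mean_fitness = s_meanf[keep],
                      max_good = s_good[keep])

  best <- NULL
  if (length(pop$inds) > 0) {
    f <- vapply(pop$inds, function(i) i$fit$fitness, 0.0)
    best <- pop$inds[[which.max(f)]]
  }
  structure(list(stats = stats, best = best, population = pop,
                 first_two = first_two, first_ten = first_ten,
                 extinct = extinct, cfg = cfg, seed = seed,
                 founder = founder),
            class = "cw_evolution")
}

#' @export
print.cw_evolution <- function(x, ...) {
  n <- nrow(x$stats)
  cat(sprintf("<cw_evolution> %d steps, final population %d%s\n", n,
              length(x$population$inds),
              if (x$extinct) " (extinct)" else ""))
  if (n > 0)
    cat(sprintf("  best segments %d; first >=2 at step %s, first >=10 at step %s\n",
                max(x$stats$max_good, na.rm = TRUE),
                format(x$first_two), format(x$first_ten)))
  invisible(x)
}

#' Gradient-switch experiment
#'
#' Takes an individual evolved under one morphogen decay rate, scores it
#' under the opposite one, re-seeds a lattice with it and continues
#' evolution under the new gradient until the pre-switch segment count is
#' recovered (or `cfg$n_steps` elapse). Reports the immediate post-switch
#' segment count and ratio, and the recovery time.
#'
#' @param g the evolved `cw_genome`.
#' @param old_d,new_d morphogen decay rates before/after the switch.
#' @param cfg,schedule,params,noise,fitness,rates,seed as [run_evolution()].
#' @param analyze also prune the genome before the switch and the best
#'   post-switch genome (each under its own gradient) and compute their
#'   frequency differences, reporting how core size and oscillator slope
#'   change across the switch.
#' @return List with `pre_good`, `post_good`, `segment_ratio`
#'   (post/pre), `recovery_step` (first step whose best individual matches
#'   `pre_good`; `NA` if not reached) and the continued `run`; with
#'   `analyze = TRUE` also `core_before`/`core_after` (gene and TFBS
#'   counts) and `freq_diff_before`/`freq_diff_after`.
#' @export
switch_gradient_experiment <- function(g, old_d, new_d,
                                       cfg = evo_config(),
                                       schedule = dev_schedule(),
                                       params = kinetic_params(),
                                       noise = noise_model(),
                                       fitness = fitness_params(),
                                       rates = mutation_rates(),
                                       seed = NULL, analyze = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  pre <- score_genome(g, schedule, morphogen_config(d = old_d), params,
                      noise, fitness)
  post <- score_genome(g, schedule, morphogen_config(d = new_d), params,
                       noise, fitness)
  pre_good <- pre$report$n_good
  post_good <- post$report$n_good
  run <- run_evolution(cfg, schedule, morphogen_config(d = new_d), params,
                       noise, fitness, rates, init_genome = g,
                       stop_when_good = pre_good)
  rec <- run$stats$step[!is.na(run$stats$max_good) &
                          run$stats$max_good >= pre_good]
  if (post_good >= pre_good) rec <- c(0L, rec)
  out <- list(pre_good = pre_good, post_good = post_good,
              segment_ratio = if (pre_good > 0) post_good / pre_good
                              else NA_real_,
              recovery_step = if (length(rec)) min(rec) else NA_integer_,
              run = run)
  if (analyze) {
    fdiff <- function(gn) {
      prof <- frequency_profile(gn, params = params)
      win <- window_profile(gn, params = params,
                            gene = if (prof$non_oscillatory) NULL
                                   else prof$selected_gene)
      classify_oscillator(prof, win)$freq_diff
    }
    core_b <- prune_genome(g, schedule, morphogen_config(d = old_d),
                           params, fitness)$genome
    out$core_before <- c(n_genes = n_genes(core_b), n_tfbs = n_tfbs(core_b))
    out$freq_diff_before <- fdiff(g)
    if (!is.null(run$best)) {
      core_a <- prune_genome(run$best$genome, schedule,
                             morphogen_config(d = new_d), params, fitness)$genome
      out$core_after <- c(n_genes = n_genes(core_a), n_tfbs = n_tfbs(core_a))
      out$freq_diff_after <- fdiff(run$best$genome)
    }
  }
  out
}
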