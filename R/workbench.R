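#' Experiment configuration
#'
#' A declarative description of one experiment (or a batch), serializable
#' to YAML and echoed alongside every output directory so any run can be
#' reproduced from (config, seed).
#'
#' @param kind `"evolve"` (full evolutionary run + analysis of the best
#'   individual), `"headless"` (the same without head cells), `"switch"`
#'   (gradient-switch continuation of an evolved genome), `"analyze"`
#'   (analysis pipeline only, on a genome file or fixture) or `"batch"`
#'   (a seed list of evolve runs plus an aggregate summary).
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @param gradient `"steep"` (d = 0.2), `"shallow"` (d = 0.025) or a
#'   numeric decay rate.
#' @param noise noise level `l`.
#' @param genome_file serialized genome for `analyze`/`switch`.
#' @param fixture fixture kind for `analyze` when no genome file is given.
#' @param new_gradient post-switch gradient for `switch`.
#' @param seeds integer seeds for `batch`.
#' @param evolution,schedule,kinetics,fitness,mutation,analysis named lists
#'   of overrides passed to [evo_config()], [dev_schedule()],
#'   [kinetic_params()], [fitness_params()], [mutation_rates()] and the
#'   analysis functions (`n_levels`, `n_steps`, `window`, `stride`,
#'   `osc_floor`, `damping_fraction`, `slope_threshold`, `prune_criterion`).
#' @return A `cw_experiment_config` list.
#' @export
experiment_config <- function(kind = c("evolve", "headless", "switch",
                                       "analyze", "batch"),
                              seed = 1L, out_dir = "clockwave-out",
                              gradient = "steep", noise = 0,
                              genome_file = NULL, fixture = NULL,
                              new_gradient = NULL, seeds = NULL,
                              evolution = list(), schedule = list(),
                              kinetics = list(), fitness = list(),
                              mutation = list(), analysis = list()) {
  kind <- match.arg(kind)
  if (kind == "batch" && is.null(seeds))
    stop("batch experiments need a `seeds` vector")
  if (kind == "switch" && is.null(new_gradient))
    stop("switch experiments need `new_gradient`")
  if (kind %in% c("analyze", "switch") &&
      is.null(genome_file) && is.null(fixture))
    stop(kind, " experiments need `genome_file` or `fixture`")
  structure(list(kind = kind, seed = as.integer(seed), out_dir = out_dir,
                 gradient = gradient, noise = noise,
                 genome_file = genome_file, fixture = fixture,
                 new_gradient = new_gradient, seeds = seeds,
                 evolution = evolution, schedule = schedule,
                 kinetics = kinetics, fitness = fitness,
                 mutation = mutation, analysis = analysis),
            class = "cw_experiment_config")
}

gradient_d <- function(gradient) {
  if (is.numeric(gradient)) return(gradient)
  switch(gradient, steep = 0.2, shallow = 0.025,
         stop("unknown gradient: ", gradient))
}

#' Read/write experiment configurations
#'
#' @param cfg a `cw_experiment_config`.
#' @param path YAML file path.
#' @return `read_experiment_config()` the configuration; the writer, the
#'   config invisibly.
#' @export
write_experiment_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(cfg)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw[!vapply(raw, is.null, TRUE)])
}

an_opt <- function(cfg, name, default) {
  v <- cfg$analysis[[name]]
  if (is.null(v)) default else v
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

analyze_genome <- function(g, cfg, out, sched, kin, fit, morph) {
  pruned <- prune_genome(g, sched, morph, kin, fit,
                         criterion = an_opt(cfg, "prune_criterion", "pattern"))
  comp <- complexity_report(pruned)
  prof <- frequency_profile(g, n_levels = an_opt(cfg, "n_levels", 50),
                            n_steps = an_opt(cfg, "n_steps", 1800),
                            params = kin, M_max = morph$M_max,
                            osc_floor = an_opt(cfg, "osc_floor", 1.0))
  win <- window_profile(g, params = kin, level = morph$M_max,
                        n_steps = an_opt(cfg, "n_steps", 1800),
                        window = an_opt(cfg, "window", 256),
                        stride = an_opt(cfg, "stride", 128),
                        gene = if (prof$non_oscillatory) NULL
                               else prof$selected_gene)
  cls <- classify_oscillator(prof, win,
                             damping_fraction = an_opt(cfg, "damping_fraction", 0.1),
                             slope_threshold = an_opt(cfg, "slope_threshold", 0.02))
  write_genome(pruned$genome, file.path(out, "core_genome.txt"))
  write_tsv(data.frame(n_genes = comp$n_genes, n_tfbs = comp$n_tfbs,
                       n_pos_fbl = comp$n_pos_fbl, n_neg_fbl = comp$n_neg_fbl,
                       n_ffl = comp$n_ffl),
            file.path(out, "complexity.tsv"))
  write_tsv(data.frame(size = as.integer(names(comp$loop_size_histogram)),
                       count = as.integer(comp$loop_size_histogram)),
            file.path(out, "loop_sizes.tsv"))
  spec <- data.frame(freq = rep(prof$freqs, times = length(prof$levels)),
                     level = rep(prof$levels, each = length(prof$freqs)),
                     amplitude = as.vector(prof$spectra))
  write_tsv(spec, file.path(out, "frequency_profile.tsv"))
  write_tsv(data.frame(category = cls$category, freq_max = cls$freq_max,
                       freq_min = cls$freq_min, freq_diff = cls$freq_diff,
                       freeze_point = as.numeric(cls$freeze_point),
                       window_amp_ratio = cls$window_amp_ratio,
                       selected_gene = prof$selected_gene),
            file.path(out, "classification.tsv"))
  list(pruned = pruned, complexity = comp, profile = prof, windows = win,
       classification = cls)
}

#' Run an experiment from a configuration
#'
#' Dispatches to the matching pipeline, writes every table, genome and the
#' echoed configuration under `cfg$out_dir`, and returns the in-memory
#' results invisibly. Batch runs write one subdirectory per seed plus an
#' aggregate summary (successful runs and the damped / constant / sloped /
#' unclassified fractions among them).
#'
#' @param cfg a [experiment_config()].
#' @return Invisibly, a list of results (shape depends on `cfg$kind`).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "cw_experiment_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_experiment_config(cfg, file.path(out, "config.yaml"))

  sched <- do.call(dev_schedule, cfg$schedule)
  kin <- do.call(kinetic_params, cfg$kinetics)
  fit <- do.call(fitness_params, cfg$fitness)
  rates <- do.call(mutation_rates, cfg$mutation)
  morph <- morphogen_config(d = gradient_d(cfg$gradient))
  noise <- noise_model(cfg$noise)

  load_genome <- function() {
    if (!is.null(cfg$genome_file)) read_genome(cfg$genome_file)
    else make_fixture_genome(cfg$fixture)
  }

  res <- switch(cfg$kind,
    analyze = {
      set.seed(cfg$seed)
      analyze_genome(load_genome(), cfg, out, sched, kin, fit, morph)
    },
    evolve = ,
    headless = {
      evo <- do.call(evo_config, cfg$evolution)
      run <- run_evolution(evo, sched, morph, kin, noise, fit, rates,
                           seed = cfg$seed,
                           headless = cfg$kind == "headless")
      write_tsv(run$stats, file.path(out, "stats.tsv"))
      write_tsv(data.frame(first_two = run$first_two,
                           first_ten = run$first_ten,
                           extinct = run$extinct,
                           best_good = if (is.null(run$best)) NA_integer_
                                       else run$best$fit$report$n_good),
                file.path(out, "waiting_times.tsv"))
      ana <- NULL
      if (!is.null(run$best)) {
        write_genome(run$best$genome, file.path(out, "best_genome.txt"))
        ana <- analyze_genome(run$best$genome, cfg, out, sched, kin, fit,
                              morph)
      }
      list(run = run, analysis = ana)
    },
    switch = {
      g <- load_genome()
      evo <- do.call(evo_config, cfg$evolution)
      sw <- switch_gradient_experiment(g, old_d = gradient_d(cfg$gradient),
                                       new_d = gradient_d(cfg$new_gradient),
                                       cfg = evo, schedule = sched,
                                       params = kin, noise = noise,
                                       fitness = fit, rates = rates,
                                       seed = cfg$seed,
                                       analyze = isTRUE(an_opt(cfg, "switch_analyze", FALSE)))
      summ <- data.frame(pre_good = sw$pre_good, post_good = sw$post_good,
                         segment_ratio = sw$segment_ratio,
                         recovery_step = sw$recovery_step)
      if (!is.null(sw$core_before)) {
        summ$core_genes_before <- sw$core_before[["n_genes"]]
        summ$core_tfbs_before <- sw$core_before[["n_tfbs"]]
        summ$freq_diff_before <- sw$freq_diff_before
        if (!is.null(sw$core_after)) {
          summ$core_genes_after <- sw$core_after[["n_genes"]]
          summ$core_tfbs_after <- sw$core_after[["n_tfbs"]]
          summ$freq_diff_after <- sw$freq_diff_after
        }
      }
      write_tsv(summ, file.path(out, "switch_summary.tsv"))
      sw
    },
    batch = {
      rows <- list()
      runs <- list()
      for (s in cfg$seeds) {
        sub <- experiment_config("evolve", seed = s,
                                 out_dir = file.path(out, sprintf("seed-%d", s)),
                                 gradient = cfg$gradient, noise = cfg$noise,
                                 evolution = cfg$evolution,
                                 schedule = cfg$schedule,
                                 kinetics = cfg$kinetics,
                                 fitness = cfg$fitness,
                                 mutation = cfg$mutation,
                                 analysis = cfg$analysis)
        r <- run_experiment(sub)
        runs[[as.character(s)]] <- r
        best_good <- if (is.null(r$run$best)) 0L else r$run$best$fit$report$n_good
        rows[[as.character(s)]] <- data.frame(
          seed = s, best_good = best_good,
          successful = best_good >= fit$success_threshold,
          category = if (is.null(r$analysis)) NA_character_
                     else r$analysis$classification$category,
          first_two = r$run$first_two, first_ten = r$run$first_ten)
      }
      tab <- do.call(rbind, rows)
      succ <- tab[tab$successful, , drop = FALSE]
      frac <- function(cat) if (nrow(succ) == 0) NA_real_
                            else mean(succ$category == cat)
      summary <- data.frame(n_runs = nrow(tab), n_successful = nrow(succ),
                            damped = frac("damped"),
                            constant = frac("constant"),
                            sloped = frac("sloped"),
                            unclassified = frac("unclassified"))
      write_tsv(tab, file.path(out, "batch_runs.tsv"))
      write_tsv(summary, file.path(out, "batch_summary.tsv"))
      list(runs = runs, table = tab, summary = summary)
    })
  invisible(res)
}

#' Export a space-time record
#'
#' Writes the cells x steps segmentation-gene record as a tab-separated
#' numeric table and, optionally, a heat-map image (developmental time on
#' the x axis, cells on the y axis with the posterior growth zone at the
#' top; cells not yet born are blank).
#'
#' @param record a `cw_development` with a full record, or a cells x steps
#'   matrix (`NA` before a cell is born).
#' @param table_path output TSV path.
#' @param png_path optional PNG path.
#' @return The record matrix, invisibly.
#' @export
render_spacetime <- function(record, table_path, png_path = NULL) {
  m <- if (inherits(record, "cw_development")) {
    if (is.null(record$spacetime))
      stop("development was run without record = \"full\"")
    record$spacetime
  } else record
  stopifnot(is.matrix(m), nrow(m) > 0)
  utils::write.table(m, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 900, height = 450)
    on.exit(grDevices::dev.off())
    graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                    col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                    xlab = "developmental step", ylab = "cell (posterior up)",
                    useRaster = TRUE)
  }
  invisible(m)
}
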