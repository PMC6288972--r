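#' Initialise an embryo
#'
#' The starting tissue is a row of `n_head + n_growth_zone` cells: an
#' anterior "head" with no morphogen (and, since there is no basal
#' transcription, never any gene expression) and a posterior growth zone in
#' which the morphogen is clamped at `M_max`. All other concentrations are 0.
#'
#' @param schedule a [dev_schedule()].
#' @param morphogen a [morphogen_config()].
#' @param headless if `TRUE` the head cells are omitted and the tissue
#'   starts as the bare growth zone.
#' @return A `cw_tissue`: list with `conc` (cells x 16 concentration matrix,
#'   anterior first), `birth_step` (step at which each cell left the growth
#'   zone; 0 for head cells, `NA` inside the zone), `n_head`, `n_zone`.
#' @export
init_embryo <- function(schedule = dev_schedule(),
                        morphogen = morphogen_config(),
                        headless = FALSE) {
  n_head <- if (headless) 0L else schedule$n_head
  n <- n_head + schedule$n_growth_zone
  conc <- matrix(0, nrow = n, ncol = 16)
  conc[seq(n - schedule$n_growth_zone + 1, n), 1] <- morphogen$M_max
  structure(list(conc = conc,
                 birth_step = c(rep(0L, n_head),
                                rep(NA_integer_, schedule$n_growth_zone)),
                 n_head = n_head,
                 n_zone = schedule$n_growth_zone),
            class = "cw_tissue")
}

#' Divide the posterior-most cell
#'
#' The posterior-most growth-zone cell divides; the daughter inherits an
#' exact copy of the mother's concentration vector and the tissue grows by
#' one cell. The anterior-most growth-zone cell thereby exits the zone (the
#' zone is always the posterior `n_zone` cells) and its morphogen starts to
#' decay. The other four zone cells never divide themselves.
#'
#' @param tissue a `cw_tissue`.
#' @param step the current developmental step, recorded as the exiting
#'   cell's birth step.
#' @return The grown `cw_tissue`.
#' @export
division_step <- function(tissue, step = NA_integer_) {
  n <- nrow(tissue$conc)
  tissue$conc <- rbind(tissue$conc, tissue$conc[n, , drop = FALSE])
  tissue$birth_step <- c(tissue$birth_step, NA_integer_)
  tissue$birth_step[n + 1 - tissue$n_zone] <- as.integer(step)
  tissue
}

#' Morphogen clamping and decay
#'
#' Growth-zone cells are reset to `M_max`; every cell outside the zone takes
#' one Euler step of `dM/dt = -d M`, i.e. is multiplied by `1 - d*dt`. Head
#' cells hold at 0. The continuous half-life is `ln(2)/d` time units.
#'
#' @param tissue a `cw_tissue`.
#' @param morphogen a [morphogen_config()].
#' @param params a [kinetic_params()] (supplies `dt`).
#' @return The updated `cw_tissue`.
#' @export
update_morphogen <- function(tissue, morphogen = morphogen_config(),
                             params = kinetic_params()) {
  n <- nrow(tissue$conc)
  zone <- seq(n - tissue$n_zone + 1, n)
  tissue$conc[-zone, 1] <- tissue$conc[-zone, 1] *
    max(0, 1 - morphogen$d * params$dt)
  tissue$conc[zone, 1] <- morphogen$M_max
  tissue
}

#' Develop an embryo from a genome
#'
#' Runs the full developmental program: every step updates the morphogen
#' (clamp + decay), then advances every cell's gene expression by one Euler
#' step; the posterior cell divides every `division_interval` steps during
#' the growth phase (120 divisions with the defaults, growing 14 cells out
#' to 134), after which dynamics continue so the youngest cells also reach
#' low morphogen and can settle. The segmentation gene (type 5) is recorded
#' for the final `control_period` steps, and for every step when
#' `record = "full"`.
#'
#' @param g a `cw_genome`.
#' @param schedule a [dev_schedule()].
#' @param morphogen a [morphogen_config()].
#' @param params a [kinetic_params()].
#' @param noise a [noise_model()]; with noise on, seed the RNG for
#'   reproducibility.
#' @param headless drop the head cells from the initial tissue.
#' @param record `"control"` (segmentation gene over the control period) or
#'   `"full"` (additionally the whole space-time record).
#' @param seed optional integer seed.
#' @return A `cw_development`: list with `tissue` (final `cw_tissue`),
#'   `seg_record` (cells x control_period matrix of segmentation-gene
#'   levels), `spacetime` (cells x steps matrix or `NULL`; `NA` before a
#'   cell exists), and the configuration used.
#' @export
develop <- function(g, schedule = dev_schedule(),
                    morphogen = morphogen_config(),
                    params = kinetic_params(), noise = noise_model(),
                    headless = FALSE, record = c("control", "full"),
                    seed = NULL) {
  record <- match.arg(record)
  if (!is.null(seed)) set.seed(seed)
  fg <- flatten_genome(g)
  n_head <- if (headless) 0L else schedule$n_head
  res <- develop_cpp(fg$gene_types, fg$site_gene, fg$site_type, fg$site_weight,
                     schedule$n_steps_total, schedule$n_steps_growth,
                     schedule$division_interval, n_head,
                     schedule$n_growth_zone,
                     params$E, params$delta, params$H, params$n, params$dt,
                     morphogen$d, morphogen$M_max, noise$l,
                     schedule$control_period, record == "full")
  tissue <- structure(list(conc = res$conc,
                           birth_step = res$birth_step[seq_len(res$n_cells)],
                           n_head = n_head,
                           n_zone = schedule$n_growth_zone),
                      class = "cw_tissue")
  structure(list(tissue = tissue,
                 seg_record = res$seg_record,
                 spacetime = res$full_record,
                 schedule = schedule, morphogen = morphogen,
                 params = params, noise = noise, headless = headless),
            class = "cw_development")
}

#' @export
print.cw_development <- function(x, ...) {
  cat(sprintf("<cw_development> %d cells after %d steps (%s record)\n",
              nrow(x$tissue$conc), x$schedule$n_steps_total,
              if (is.null(x$spacetime)) "control-period" else "full"))
  invisible(x)
}
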