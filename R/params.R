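#' Kinetic parameters of gene expression
#'
#' Parameters of the Hill-function expression dynamics integrated by forward
#' Euler: each non-morphogen protein follows
#' \deqn{dG_i/dt = \max_j\big(A_j^n/(A_j^n+H^n)\big)\; \prod_k\big(H^n/(I_k^n+H^n)\big)\; E \;-\; \delta G_i,}
#' with the strongest activator setting the activation (an OR gate) and
#' repressors multiplying (an AND gate).
#'
#' @param E maximal transcription rate (concentration per time unit).
#' @param delta protein decay rate (1/time).
#' @param H Hill constant: concentration of half-maximal activation/repression.
#' @param n Hill coefficient. Not part of the published parameter table;
#'   2 is the package default (the smallest value giving strongly nonlinear
#'   input integration).
#' @param dt forward-Euler step size (time units per integration step).
#' @return An object of class `cw_kinetics`.
#' @export
kinetic_params <- function(E = 100, delta = 0.3, H = 60, n = 2, dt = 0.2) {
  stopifnot(E > 0, delta > 0, H > 0, n >= 1, dt > 0)
  structure(list(E = E, delta = delta, H = H, n = n, dt = dt),
            class = "cw_kinetics")
}

#' Multiplicative gene-expression noise model
#'
#' When `l > 0`, the realised transcription rate of every gene copy at every
#' Euler step is `max(0, R + eps)` with `eps ~ Normal(0, (l*R)^2)`, so the
#' coefficient of variation is constant across expression levels. `l = 0`
#' reproduces the deterministic dynamics exactly (and consumes no random
#' draws).
#'
#' @param l noise level; 0 (off), 0.07 (low), 0.14 (medium) or 0.21 (high)
#'   are the levels used in the simulation study, but any value >= 0 is valid.
#' @return An object of class `cw_noise`.
#' @export
noise_model <- function(l = 0) {
  stopifnot(is.numeric(l), length(l) == 1, l >= 0)
  structure(list(l = l), class = "cw_noise")
}

#' Morphogen gradient configuration
#'
#' The morphogen (protein type 0) is clamped at `M_max` inside the posterior
#' growth zone and decays at rate `d` (per time unit) in every cell that has
#' left the zone, so a spatial gradient forms from the age ordering of cells.
#' The half-maximal position/time is `lambda = ln(2)/d`.
#'
#' @param d decay rate; 0.2 gives the steep gradient, 0.025 the shallow one.
#' @param M_max clamped growth-zone concentration.
#' @return An object of class `cw_morphogen`.
#' @export
morphogen_config <- function(d = 0.2, M_max = 100) {
  stopifnot(d > 0, M_max > 0)
  structure(list(d = d, M_max = M_max), class = "cw_morphogen")
}

#' Developmental schedule
#'
#' An embryo starts as `n_head + n_growth_zone` cells and the posterior-most
#' cell divides every `division_interval` integration steps during the first
#' `n_steps_growth` steps, after which dynamics continue without growth until
#' `n_steps_total`. With the defaults this is 120 divisions and a final
#' tissue of 134 cells, followed by a 600-step stabilisation phase.
#'
#' @param n_steps_total total developmental steps.
#' @param n_steps_growth steps during which divisions occur.
#' @param division_interval steps between divisions.
#' @param n_head anterior morphogen-free (and hence expression-free) cells.
#' @param n_growth_zone posterior cells with clamped morphogen.
#' @param control_period trailing steps over which the segmentation pattern
#'   is averaged for fitness scoring.
#' @return An object of class `cw_schedule`.
#' @export
dev_schedule <- function(n_steps_total = 1200, n_steps_growth = 600,
                         division_interval = 5, n_head = 9,
                         n_growth_zone = 5, control_period = 100) {
  stopifnot(n_steps_total >= n_steps_growth, division_interval >= 1,
            n_head >= 0, n_growth_zone >= 1,
            control_period >= 1, control_period <= n_steps_total)
  structure(list(n_steps_total = n_steps_total,
                 n_steps_growth = n_steps_growth,
                 division_interval = division_interval,
                 n_head = n_head, n_growth_zone = n_growth_zone,
                 control_period = control_period),
            class = "cw_schedule")
}

#' Fitness-function parameters
#'
#' Segment calling and the fitness score
#' `F = n_good - n_narrow - G*genes - T*tfbs - U*unstable`, with realised
#' fitness `exp(max(0, F)) - 1`. Segments must be at least
#' `min_segment_width` cells wide; boundaries must be a high/low transition
#' completed within `max_boundary_width` cells. Cells whose segmentation-gene
#' variance over the control period exceeds `var_threshold` count as
#' unstable. `theta_hi`/`theta_lo` are the plateau thresholds used to label
#' cells high/low; defaults are half and a quarter of the maximal steady
#' state E/delta (hysteresis avoids chattering around a single cut).
#'
#' @param G per-gene penalty.
#' @param T per-TFBS penalty.
#' @param U per-unstable-cell penalty.
#' @param var_threshold variance above which a cell counts as unstable.
#' @param control_period averaging window (steps) at the end of development.
#' @param min_segment_width minimum width (cells) of a well-formed segment.
#' @param max_boundary_width maximum width (cells) of a segment boundary.
#' @param success_threshold segments from which a run counts as successful.
#' @param theta_hi,theta_lo high/low plateau thresholds on mean expression.
#' @param n_growth_zone posterior cells excluded from segment scoring.
#' @return An object of class `cw_fitness_params`.
#' @export
fitness_params <- function(G = 0.0005, T = 0.00005, U = 0.1,
                           var_threshold = 5.0, control_period = 100,
                           min_segment_width = 7, max_boundary_width = 5,
                           success_threshold = 10,
                           theta_hi = 0.5 * 100 / 0.3,
                           theta_lo = 0.25 * 100 / 0.3,
                           n_growth_zone = 5) {
  stopifnot(G >= 0, T >= 0, U >= 0, var_threshold >= 0,
            min_segment_width >= 1, max_boundary_width >= 0,
            theta_hi > theta_lo, theta_lo >= 0, n_growth_zone >= 0)
  structure(list(G = G, T = T, U = U, var_threshold = var_threshold,
                 control_period = control_period,
                 min_segment_width = min_segment_width,
                 max_boundary_width = max_boundary_width,
                 success_threshold = success_threshold,
                 theta_hi = theta_hi, theta_lo = theta_lo,
                 n_growth_zone = n_growth_zone),
            class = "cw_fitness_params")
}

#' Per-element mutation rates
#'
#' Probabilities applied per reproduction event: per gene for duplication,
#' deletion and de-novo TFBS innovation; per binding site for weight flip,
#' type randomisation, duplication and deletion. Gene types themselves never
#' mutate, so gene duplication cannot be followed by divergence.
#'
#' @param gene_dup,gene_del per-gene duplication/deletion probability.
#' @param tfbs_weight_change,tfbs_type_change,tfbs_dup,tfbs_del per-site rates.
#' @param tfbs_innovation per-gene probability of gaining one random new site.
#' @return An object of class `cw_mutation_rates`.
#' @export
mutation_rates <- function(gene_dup = 0.006, gene_del = 0.009,
                           tfbs_weight_change = 0.001,
                           tfbs_type_change = 0.001,
                           tfbs_dup = 0.0015, tfbs_del = 0.004,
                           tfbs_innovation = 0.001) {
  r <- list(gene_dup = gene_dup, gene_del = gene_del,
            tfbs_weight_change = tfbs_weight_change,
            tfbs_type_change = tfbs_type_change,
            tfbs_dup = tfbs_dup, tfbs_del = tfbs_del,
            tfbs_innovation = tfbs_innovation)
  stopifnot(all(vapply(r, function(x) is.numeric(x) && x >= 0 && x <= 1, TRUE)))
  structure(r, class = "cw_mutation_rates")
}

#' Evolutionary run configuration
#'
#' A population of individuals lives on a toroidal `grid_w` x `grid_h`
#' lattice (at most one individual per site). Each evolutionary step:
#' death with probability `death_rate`, Margolus diffusion (two half-steps),
#' then every empty site is competed for by the individuals in its
#' `neighbourhood` x `neighbourhood` surroundings with probability
#' proportional to fitness.
#'
#' @param grid_w,grid_h lattice dimensions.
#' @param n_initial founder copies of the initial genome.
#' @param death_rate per-individual death probability per step.
#' @param n_steps evolutionary steps.
#' @param neighbourhood side length of the local competition window (odd).
#' @param mean_tfbs mean number of binding sites per gene in the founder.
#' @return An object of class `cw_evo_config`.
#' @export
evo_config <- function(grid_w = 30, grid_h = 30, n_initial = 50,
                       death_rate = 0.5, n_steps = 10000,
                       neighbourhood = 7, mean_tfbs = 2) {
  stopifnot(grid_w >= 2, grid_h >= 2, n_initial >= 1,
            n_initial <= grid_w * grid_h,
            death_rate >= 0, death_rate <= 1, n_steps >= 0,
            neighbourhood %% 2 == 1, mean_tfbs >= 0)
  structure(list(grid_w = grid_w, grid_h = grid_h, n_initial = n_initial,
                 death_rate = death_rate, n_steps = n_steps,
                 neighbourhood = neighbourhood, mean_tfbs = mean_tfbs),
            class = "cw_evo_config")
}
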