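#' Time-averaged segmentation-gene pattern
#'
#' Per-cell mean and (population) variance of segmentation-gene expression
#' over the final `control_period` developmental steps. Averaging over a
#' window, rather than taking the last step, refuses credit to oscillatory
#' "patterns" that never settle.
#'
#' @param record a `cw_development` or a cells x steps numeric matrix of
#'   segmentation-gene levels.
#' @param control_period number of trailing steps to average over.
#' @return data.frame with columns `cell`, `mean`, `var`.
#' @export
average_segmentation_expression <- function(record, control_period = 100) {
  m <- if (inherits(record, "cw_development")) record$seg_record else record
  stopifnot(is.matrix(m))
  if (ncol(m) < control_period)
    stop("record spans ", ncol(m), " steps; control period needs ",
         control_period)
  m <- m[, seq(ncol(m) - control_period + 1, ncol(m)), drop = FALSE]
  mu <- rowMeans(m)
  data.frame(cell = seq_len(nrow(m)), mean = mu,
             var = rowMeans(m^2) - mu^2)
}

#' Call segments from a mean expression pattern
#'
#' Cells are labelled `high` (mean >= `theta_hi`), `low` (<= `theta_lo`) or
#' `transition`; the posterior `n_growth_zone` cells are excluded from
#' scoring (segments are counted outside the growth zone, though the zone
#' boundary may terminate the last segment). A segment is a maximal plateau:
#' consecutive same-state plateau runs merge across intervening transition
#' cells (only plateau-level cells count toward its width). A segment is
#' scored when each of its sides is either a tissue edge or a valid
#' boundary: a transition to the opposite plateau state completed within
#' `max_boundary_width` cells. Scored segments at least `min_segment_width`
#' cells wide are well-formed (`n_good`); narrower ones count as narrow
#' (`n_narrow`). The expressionless head is itself a low plateau, which is
#' why a uniformly expressing body already scores two segments and why at
#' most 18 segments fit in the standard 134-cell geometry.
#'
#' @param mean_expr per-cell mean segmentation-gene expression for the whole
#'   tissue, anterior first (e.g. the `mean` column of
#'   [average_segmentation_expression()]).
#' @param params a [fitness_params()] object.
#' @return A `cw_segment_report`: list with `n_good`, `n_narrow`,
#'   `boundaries` (cell index of the first cell of the segment posterior to
#'   each valid boundary), `per_cell_state` (`high`/`low`/`transition`, and
#'   `zone` for excluded cells) and `segments` (one row per plateau).
#' @export
call_segments <- function(mean_expr, params = fitness_params()) {
  n <- length(mean_expr)
  nz <- min(params$n_growth_zone, n)
  body <- mean_expr[seq_len(n - nz)]
  lab <- rep("transition", length(body))
  lab[body >= params$theta_hi] <- "high"
  lab[body <= params$theta_lo] <- "low"

  st <- character(0); wd <- integer(0); s0 <- integer(0); s1 <- integer(0)
  gap_before <- integer(0) # transition cells between a segment and its predecessor
  if (length(lab) > 0) {
    r <- rle(lab)
    pos <- 1L
    pending <- 0L
    j <- 0L
    for (k in seq_along(r$values)) {
      len <- r$lengths[k]
      if (r$values[k] == "transition") {
        pending <- pending + len
      } else if (j > 0L && st[j] == r$values[k]) {
        # same state across a dip: one segment
        wd[j] <- wd[j] + len
        s1[j] <- pos + len - 1L
        pending <- 0L
      } else {
        j <- j + 1L
        st[j] <- r$values[k]; wd[j] <- len
        s0[j] <- pos; s1[j] <- pos + len - 1L
        gap_before[j] <- pending
        pending <- 0L
      }
      pos <- pos + len
    }
  }
  segs <- data.frame(state = st, width = wd, start = s0, end = s1)

  k <- nrow(segs)
  left_ok <- right_ok <- logical(k)
  if (k > 0) {
    between_ok <- gap_before[-1] <= params$max_boundary_width # k-1 internal boundaries
    left_ok <- c(TRUE, between_ok)   # anterior tissue edge always terminates
    right_ok <- c(between_ok, TRUE)  # growth-zone / posterior edge likewise
  }
  scored <- left_ok & right_ok
  segs$scored <- scored
  segs$good <- scored & segs$width >= params$min_segment_width
  boundaries <- if (k > 1) segs$start[-1][gap_before[-1] <= params$max_boundary_width]
                else integer(0)

  structure(list(n_good = sum(segs$good),
                 n_narrow = sum(scored & !segs$good),
                 boundaries = boundaries,
                 per_cell_state = c(lab, rep("zone", nz)),
                 segments = segs),
            class = "cw_segment_report")
}

#' @export
print.cw_segment_report <- function(x, ...) {
  cat(sprintf("<cw_segment_report> %d good, %d narrow; boundaries at: %s\n",
              x$n_good, x$n_narrow,
              if (length(x$boundaries)) paste(x$boundaries, collapse = " ")
              else "none"))
  invisible(x)
}

#' Count cells with unstable expression
#'
#' Cells whose segmentation-gene variance over the control period exceeds
#' `var_threshold` (strictly) indicate a pattern that has not settled and
#' are penalised in the fitness score.
#'
#' @param variance per-cell variances (e.g. the `var` column of
#'   [average_segmentation_expression()]).
#' @param params a [fitness_params()] object.
#' @return Integer count.
#' @export
count_unstable_cells <- function(variance, params = fitness_params()) {
  sum(variance > params$var_threshold)
}

#' Fitness of a developed individual
#'
#' Computes `F = n_good - n_narrow - G*genes - T*tfbs - U*unstable` on the
#' full (unpruned) genome and the realised fitness `exp(max(0, F)) - 1`.
#' An individual missing any of the 16 gene types is not viable and scores
#' fitness 0 regardless of its pattern.
#'
#' @param g the individual's `cw_genome`.
#' @param report a `cw_segment_report`.
#' @param n_unstable count from [count_unstable_cells()].
#' @param params a [fitness_params()] object.
#' @return A `cw_fitness_result`: list with `F`, `fitness`, `viable`,
#'   `n_unstable` and the `report`.
#' @export
evaluate_fitness <- function(g, report, n_unstable,
                             params = fitness_params()) {
  F <- report$n_good - report$n_narrow -
    params$G * n_genes(g) - params$T * n_tfbs(g) - params$U * n_unstable
  viable <- is_viable(g)
  structure(list(F = F,
                 fitness = if (viable) exp(max(0, F)) - 1 else 0,
                 viable = viable,
                 n_unstable = n_unstable,
                 report = report),
            class = "cw_fitness_result")
}

#' @export
print.cw_fitness_result <- function(x, ...) {
  cat(sprintf("<cw_fitness_result> fitness %.4g (F = %.4g, %s), %d good / %d narrow segments\n",
              x$fitness, x$F, if (x$viable) "viable" else "not viable",
              x$report$n_good, x$report$n_narrow))
  invisible(x)
}

#' Develop and score a genome in one call
#'
#' Convenience pipeline used for every birth during evolution: develop the
#' genome, average the segmentation pattern over the control period, call
#' segments, count unstable cells and evaluate fitness.
#'
#' @inheritParams develop
#' @param fitness a [fitness_params()] object.
#' @return A `cw_fitness_result` with the per-cell `pattern` data.frame
#'   attached.
#' @export
score_genome <- function(g, schedule = dev_schedule(),
                         morphogen = morphogen_config(),
                         params = kinetic_params(), noise = noise_model(),
                         fitness = fitness_params(), headless = FALSE,
                         seed = NULL) {
  dev <- develop(g, schedule, morphogen, params, noise,
                 headless = headless, seed = seed)
  pat <- average_segmentation_expression(dev, schedule$control_period)
  rep_ <- call_segments(pat$mean, fitness)
  res <- evaluate_fitness(g, rep_, count_unstable_cells(pat$var, fitness),
                          fitness)
  res$pattern <- pat
  res
}

#' Maximum attainable number of well-formed segments
#'
#' Maximises the number of well-formed segments over all high/low expression
#' patterns on a tissue geometry (head expressionless and therefore low,
#' growth zone excluded from scoring) by dynamic programming over
#' run-length encodings, and verifies the optimum by evaluating a witness
#' pattern through [call_segments()]. On the standard fully grown geometry
#' (134 cells, 9 head, 5 zone, 7-cell minimum width) the maximum is 18: the
#' head plateau plus seventeen 7-cell body segments.
#'
#' @param n_cells total tissue length.
#' @param n_head anterior expressionless cells (forced into the first low
#'   plateau).
#' @param params a [fitness_params()] object (`n_growth_zone`,
#'   `min_segment_width` and the plateau thresholds are used).
#' @return List with `n_max` (the maximum), `pattern` (a witness expression
#'   vector of length `n_cells`) and `verified` (`TRUE` iff
#'   `call_segments()` scores the witness at exactly `n_max` good segments).
#' @export
max_good_segments <- function(n_cells = 134, n_head = 9,
                              params = fitness_params()) {
  L <- n_cells - params$n_growth_zone
  mw <- params$min_segment_width
  stopifnot(L >= 1, n_head <= L)
  # f[len+1]: best good-segment count over alternating-run partitions of
  # `len` cells (state-symmetric, so state is not part of the DP state)
  f <- integer(L + 1)
  arg <- integer(L + 1)
  for (len in seq_len(L)) {
    best <- -1L
    for (l in seq_len(len)) {
      v <- (l >= mw) + f[len - l + 1]
      if (v > best) { best <- v; arg[len + 1] <- l }
    }
    f[len + 1] <- best
  }
  # first run is the low plateau containing the head
  l1_min <- max(1L, n_head)
  best <- -1L; best_l1 <- l1_min
  for (l1 in seq(l1_min, L)) {
    v <- (l1 >= mw) + f[L - l1 + 1]
    if (v > best) { best <- v; best_l1 <- l1 }
  }
  # reconstruct a witness pattern
  runs <- best_l1
  rem <- L - best_l1
  while (rem > 0) {
    l <- arg[rem + 1]
    runs <- c(runs, l)
    rem <- rem - l
  }
  hi <- 2 * params$theta_hi
  states <- rep_len(c(0, hi), length(runs))
  pattern <- c(rep(states, times = runs),
               rep(states[length(states)], params$n_growth_zone))
  rep_ <- call_segments(pattern, params)
  list(n_max = best, pattern = pattern, verified = rep_$n_good == best)
}
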