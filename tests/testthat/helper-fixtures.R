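# Small genomes and scaled-down schedules shared across tests.

# genome in which the morphogen directly and solely activates the
# segmentation gene: posterior cells express, the head never does
morphogen_reporter_genome <- function() {
  genes <- lapply(0:15, function(t) {
    if (t == 5) gene(5, list(c(0L, 1L))) else gene(t)
  })
  genome(genes)
}

# genome with no binding sites at all: nothing is ever expressed
silent_genome <- function() genome(lapply(0:15, gene))

# short developmental schedule for fast structural tests
short_schedule <- function() {
  dev_schedule(n_steps_total = 60, n_steps_growth = 30,
               division_interval = 5, n_head = 3, n_growth_zone = 2,
               control_period = 10)
}

# random genome wired over types 1..6 only (avoids the inert type-0 target
# rule), for loop-census comparisons
random_signed_graph_genome <- function(p_edge = 0.3) {
  nodes <- 1:6
  genes <- lapply(nodes, function(t) {
    src <- nodes[stats::runif(6) < p_edge]
    if (length(src) == 0) return(gene(t))
    gene(t, cbind(src, sample(c(-1L, 1L), length(src), replace = TRUE)))
  })
  genome(genes)
}

# brute-force simple-cycle enumeration over vertex permutations: for every
# cycle length k and every k-subset ordering starting at its smallest
# vertex, check that all arcs exist, then expand parallel sign choices
brute_force_loops <- function(net) {
  arcs <- unique(net$edges[, c("source", "target", "weight")])
  nodes <- sort(unique(c(arcs$source, arcs$target)))
  has <- function(u, v) arcs$weight[arcs$source == u & arcs$target == v]
  out <- list()
  for (k in seq_along(nodes)) {
    combs <- utils::combn(nodes, k, simplify = FALSE)
    for (cmb in combs) {
      first <- min(cmb)
      rest <- setdiff(cmb, first)
      perms <- if (length(rest) == 0) list(integer(0)) else perms_of(rest)
      for (p in perms) {
        path <- c(first, p)
        sets <- lapply(seq_len(k), function(i)
          has(path[i], path[if (i < k) i + 1 else 1]))
        if (any(vapply(sets, length, 0L) == 0)) next
        combos <- expand.grid(sets)
        for (r in seq_len(nrow(combos))) {
          out[[length(out) + 1]] <- data.frame(
            size = k, sign = prod(as.numeric(combos[r, ])),
            members = paste(path, collapse = ">"))
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(size = integer(0), sign = integer(0),
                      members = character(0)))
  do.call(rbind, out)
}

perms_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in perms_of(x[-i]))
      out[[length(out) + 1]] <- c(x[i], p)
  out
}

# independent reference for the segment-calling rules: explicit scan over
# plateau runs with the width/boundary conditions applied literally
reference_call_segments <- function(mean_expr, params) {
  n <- length(mean_expr)
  nz <- min(params$n_growth_zone, n)
  body <- mean_expr[seq_len(n - nz)]
  lab <- ifelse(body >= params$theta_hi, "H",
                ifelse(body <= params$theta_lo, "L", "T"))
  # plateau groups: maximal stretches of one plateau state, allowing
  # interior T cells between same-state runs
  groups <- list()
  i <- 1
  while (i <= length(lab)) {
    if (lab[i] == "T") { i <- i + 1; next }
    state <- lab[i]
    width <- 0L
    j <- i
    last_plateau <- i
    while (j <= length(lab)) {
      if (lab[j] == state) { width <- width + 1L; last_plateau <- j; j <- j + 1 }
      else if (lab[j] == "T") {
        # absorb the dip only if the same state resumes
        k <- j
        while (k <= length(lab) && lab[k] == "T") k <- k + 1
        if (k <= length(lab) && lab[k] == state) j <- k else break
      } else break
    }
    groups[[length(groups) + 1]] <- list(state = state, width = width,
                                         first = i, last = last_plateau)
    i <- last_plateau + 1
  }
  n_good <- 0L; n_narrow <- 0L
  for (gidx in seq_along(groups)) {
    g <- groups[[gidx]]
    left_ok <- gidx == 1 ||
      (groups[[gidx - 1]]$state != g$state &&
         (g$first - groups[[gidx - 1]]$last - 1) <= params$max_boundary_width)
    right_ok <- gidx == length(groups) ||
      (groups[[gidx + 1]]$state != g$state &&
         (groups[[gidx + 1]]$first - g$last - 1) <= params$max_boundary_width)
    if (left_ok && right_ok) {
      if (g$width >= params$min_segment_width) n_good <- n_good + 1L
      else n_narrow <- n_narrow + 1L
    }
  }
  list(n_good = n_good, n_narrow = n_narrow)
}

# estimate the oscillation period (in time units) from mean peak spacing
estimate_period <- function(series, dt) {
  n <- length(series)
  x <- series
  peaks <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (length(peaks) < 3) return(NA_real_)
  mean(diff(peaks)) * dt
}
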