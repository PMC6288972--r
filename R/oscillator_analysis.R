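#' Single-cell run at a fixed morphogen level
#'
#' Integrates one cell for `n_steps` Euler steps with the morphogen clamped
#' at `level`, recording all 16 protein types. Long fixed-level series give
#' the Fourier analysis the same amount of data at every point of the
#' morphogen gradient, however fast the gradient decays in the tissue.
#'
#' @param g a `cw_genome`.
#' @param level clamped morphogen concentration (>= 0).
#' @param n_steps series length in Euler steps.
#' @param params a [kinetic_params()].
#' @param init initial 16-concentration vector (default all zero).
#' @param noise a [noise_model()] (off by default, as in the analysis
#'   pipeline).
#' @return A `n_steps` x 16 matrix of concentrations (one row per step),
#'   with the clamped `level` as attribute.
#' @export
simulate_fixed_morphogen <- function(g, level, n_steps = 1800,
                                     params = kinetic_params(),
                                     init = NULL, noise = noise_model()) {
  stopifnot(level >= 0, n_steps >= 1)
  if (is.null(init)) init <- numeric(16)
  fg <- flatten_genome(g)
  out <- simulate_cell_cpp(fg$gene_types, fg$site_gene, fg$site_type,
                           fg$site_weight, level, n_steps,
                           params$E, params$delta, params$H, params$n,
                           params$dt, noise$l, init)
  attr(out, "level") <- level
  out
}

#' Amplitude spectrum and dominant frequency of a time series
#'
#' FFT amplitude spectrum (one-sided, DC bin excluded) of the
#' post-transient series; frequencies are in cycles per Euler step. The
#' dominant frequency is the highest-amplitude non-DC bin, which for an
#' oscillator is its fundamental (harmonic eigenmodes have smaller
#' amplitude). A constant series has zero amplitude everywhere and an
#' undefined (`NA`) dominant frequency.
#'
#' @param series numeric vector.
#' @param discard initial transient steps to drop before the transform.
#' @return A `cw_spectrum`: list with `freq`, `amplitude`, `dominant_freq`
#'   (`NA` if nothing oscillates) and `dominant_amp`.
#' @export
fourier_spectrum <- function(series, discard = 0) {
  x <- series[(discard + 1):length(series)]
  if (length(x) < 64)
    stop("need at least 64 samples after discarding the transient")
  N <- length(x)
  half <- N %/% 2
  amp <- Mod(stats::fft(x))[2:(half + 1)] * 2 / N
  i <- which.max(amp)
  structure(list(freq = seq_len(half) / N,
                 amplitude = amp,
                 dominant_freq = if (amp[i] > 1e-9) i / N else NA_real_,
                 dominant_amp = amp[i]),
            class = "cw_spectrum")
}

#' Fourier frequency profile across morphogen levels
#'
#' Runs the network once per level of a linear morphogen grid from 0 to
#' `M_max`, Fourier-transforms every gene's post-transient dynamics,
#' selects the gene oscillating with the largest amplitude anywhere on the
#' grid, and assembles that gene's per-level amplitude spectra into the
#' frequency profile. Harmonic eigenmodes remain visible in the stored
#' spectra but do not affect dominant-frequency extraction.
#'
#' @param g a `cw_genome`.
#' @param n_levels number of morphogen levels (linear grid incl. 0 and
#'   `M_max`).
#' @param n_steps steps per fixed-level run.
#' @param params a [kinetic_params()].
#' @param M_max top of the level grid (growth-zone morphogen).
#' @param discard transient steps dropped before each transform.
#' @param osc_floor dominant amplitude (concentration units) below which a
#'   level counts as non-oscillating.
#' @return A `cw_freq_profile`: list with `levels`, `freqs`, `spectra`
#'   (frequency x level amplitude matrix for the selected gene),
#'   `dominant_freq`/`dominant_amp` per level, `selected_gene` and the
#'   `non_oscillatory` flag (no gene reaches `osc_floor` at any level).
#' @export
frequency_profile <- function(g, n_levels = 50, n_steps = 1800,
                              params = kinetic_params(), M_max = 100,
                              discard = 300, osc_floor = 1.0) {
  stopifnot(n_levels >= 2)
  levels <- seq(0, M_max, length.out = n_levels)
  sims <- lapply(levels, function(lv)
    simulate_fixed_morphogen(g, lv, n_steps, params))
  # pick the gene with the globally largest oscillation amplitude
  peak <- matrix(0, nrow = 15, ncol = n_levels) # rows: types 1..15
  for (j in seq_len(n_levels)) {
    for (t in 1:15) {
      peak[t, j] <- fourier_spectrum(sims[[j]][, t + 1], discard)$dominant_amp
    }
  }
  gene_max <- apply(peak, 1, max)
  sel <- which.max(gene_max)
  non_osc <- gene_max[sel] < osc_floor
  spectra <- NULL
  dom_freq <- rep(NA_real_, n_levels)
  dom_amp <- numeric(n_levels)
  freqs <- NULL
  for (j in seq_len(n_levels)) {
    sp <- fourier_spectrum(sims[[j]][, sel + 1], discard)
    if (is.null(spectra))
      spectra <- matrix(0, nrow = length(sp$freq), ncol = n_levels)
    spectra[, j] <- sp$amplitude
    dom_freq[j] <- sp$dominant_freq
    dom_amp[j] <- sp$dominant_amp
    freqs <- sp$freq
  }
  structure(list(levels = levels, freqs = freqs, spectra = spectra,
                 dominant_freq = dom_freq, dominant_amp = dom_amp,
                 selected_gene = sel, non_oscillatory = non_osc,
                 osc_floor = osc_floor, discard = discard,
                 n_steps = n_steps),
            class = "cw_freq_profile")
}

#' @export
print.cw_freq_profile <- function(x, ...) {
  cat(sprintf("<cw_freq_profile> gene %d over %d levels%s\n",
              x$selected_gene, length(x$levels),
              if (x$non_oscillatory) " (non-oscillatory)" else ""))
  invisible(x)
}

#' Sliding-window spectra in the growth zone
#'
#' Fourier transforms of successive windows of the fixed-level series at
#' the growth-zone morphogen concentration. The full series is kept
#' (no transient discarded): amplitude decay across windows is the
#' damping diagnostic.
#'
#' @param g a `cw_genome`.
#' @param params a [kinetic_params()].
#' @param level morphogen level (growth-zone concentration).
#' @param n_steps series length.
#' @param window,stride window length and step, in Euler steps.
#' @param gene gene type to analyse; default: the largest-amplitude
#'   oscillating gene of this series.
#' @return A `cw_window_profile`: list with `gene`, `starts`, `window`,
#'   `stride`, per-window `dominant_freq`/`dominant_amp` and the `spectra`
#'   matrix (frequency x window).
#' @export
window_profile <- function(g, params = kinetic_params(), level = 100,
                           n_steps = 1800, window = 256, stride = 128,
                           gene = NULL) {
  stopifnot(window <= n_steps, window >= 64, stride >= 1)
  sim <- simulate_fixed_morphogen(g, level, n_steps, params)
  if (is.null(gene)) {
    amps <- vapply(1:15, function(t)
      fourier_spectrum(sim[, t + 1])$dominant_amp, 0.0)
    gene <- which.max(amps)
  }
  series <- sim[, gene + 1]
  starts <- seq(1, n_steps - window + 1, by = stride)
  spectra <- NULL
  dom_freq <- rep(NA_real_, length(starts))
  dom_amp <- numeric(length(starts))
  for (i in seq_along(starts)) {
    sp <- fourier_spectrum(series[starts[i]:(starts[i] + window - 1)])
    if (is.null(spectra))
      spectra <- matrix(0, nrow = length(sp$freq), ncol = length(starts))
    spectra[, i] <- sp$amplitude
    dom_freq[i] <- sp$dominant_freq
    dom_amp[i] <- sp$dominant_amp
  }
  structure(list(gene = gene, starts = starts, window = window,
                 stride = stride, dominant_freq = dom_freq,
                 dominant_amp = dom_amp, spectra = spectra),
            class = "cw_window_profile")
}

#' Classify an oscillator from its frequency profiles
#'
#' An oscillator is damped when its growth-zone oscillations die out over
#' developmental time: the dominant amplitude of the last window falls
#' below `damping_fraction` of the maximum window amplitude. Persistent
#' oscillators are split by the frequency difference across the morphogen
#' gradient, `freq_diff = freq_max - freq_min`, where `freq_max` is the
#' dominant frequency at the highest oscillating morphogen level and
#' `freq_min` the dominant frequency at the lowest level still oscillating
#' (just before oscillations cease): differences above `slope_threshold`
#' (0.02 cycles/step) are sloped profiles (travelling waves), smaller ones
#' approximately constant profiles. Profiles with no oscillation, or with
#' fewer than two oscillating levels, are unclassified.
#'
#' @param profile a `cw_freq_profile`.
#' @param windows a `cw_window_profile` from the same genome.
#' @param damping_fraction last-window amplitude fraction below which the
#'   oscillator counts as damped.
#' @param slope_threshold frequency-difference cut (cycles per step).
#' @return A `cw_oscillator_class`: list with `category` (`damped`,
#'   `constant`, `sloped` or `unclassified`), `freq_max`, `freq_min`,
#'   `freq_diff`, `freeze_point` and `window_amp_ratio`.
#' @export
classify_oscillator <- function(profile, windows,
                                damping_fraction = 0.1,
                                slope_threshold = 0.02) {
  fp <- freeze_point(profile)
  osc <- which(profile$dominant_amp >= profile$osc_floor)
  ratio <- if (max(windows$dominant_amp) > 0)
    windows$dominant_amp[length(windows$dominant_amp)] /
      max(windows$dominant_amp) else 0

  if (profile$non_oscillatory || length(osc) < 2) {
    category <- "unclassified"
    freq_max <- freq_min <- freq_diff <- NA_real_
  } else {
    freq_max <- profile$dominant_freq[max(osc)]
    freq_min <- profile$dominant_freq[min(osc)]
    freq_diff <- freq_max - freq_min
    category <- if (ratio < damping_fraction) "damped"
    else if (freq_diff > slope_threshold) "sloped"
    else "constant"
  }
  structure(list(category = category, freq_max = freq_max,
                 freq_min = freq_min, freq_diff = freq_diff,
                 freeze_point = fp, window_amp_ratio = ratio),
            class = "cw_oscillator_class")
}

#' @export
print.cw_oscillator_class <- function(x, ...) {
  cat(sprintf("<cw_oscillator_class> %s (freq_diff %s, freeze point %.3g)\n",
              x$category,
              if (is.na(x$freq_diff)) "NA" else sprintf("%.4f", x$freq_diff),
              x$freeze_point))
  invisible(x)
}

#' Freeze point of a frequency profile
#'
#' The morphogen level at which oscillations cease and expression becomes
#' stable: scanning down from the top of the level grid, the highest level
#' such that it and every level below it are non-oscillating (dominant
#' amplitude below the oscillation floor). A genome that never oscillates
#' freezes at the top level; one that oscillates even at level 0 gets
#' freeze point 0, flagged via the `"flagged"` attribute.
#'
#' @param profile a `cw_freq_profile`.
#' @return The freeze level (numeric scalar) with attribute `flagged`.
#' @export
freeze_point <- function(profile) {
  osc <- profile$dominant_amp >= profile$osc_floor
  if (!any(osc)) {
    fp <- max(profile$levels)
  } else if (which(osc)[1] == 1) {
    fp <- structure(0, flagged = TRUE)
  } else {
    fp <- profile$levels[which(osc)[1] - 1]
  }
  fp
}
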