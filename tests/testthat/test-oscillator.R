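test_that("the amplitude spectrum recovers known frequencies within one bin", {
  n <- 1024
  sine <- 10 * sin(2 * pi * 0.125 * seq_len(n)) # 8 samples per cycle
  sp <- fourier_spectrum(sine)
  expect_lte(abs(sp$dominant_freq - 0.125), 1 / n)
  expect_equal(sp$dominant_amp, 10, tolerance = 0.01)

  flat <- fourier_spectrum(rep(3.2, 512))
  expect_true(is.na(flat$dominant_freq))
  expect_equal(flat$dominant_amp, 0, tolerance = 1e-9)

  n2 <- 1000 # both tones on exact bins: no leakage
  mix <- 10 * sin(2 * pi * 0.05 * seq_len(n2)) +
    3 * sin(2 * pi * 0.10 * seq_len(n2))
  spm <- fourier_spectrum(mix)
  expect_lte(abs(spm$dominant_freq - 0.05), 1 / n2)
  second <- spm$amplitude[which.min(abs(spm$freq - 0.10))]
  expect_equal(second / spm$dominant_amp, 0.3, tolerance = 0.05)

  expect_error(fourier_spectrum(rep(1, 60)), "64")
  expect_error(fourier_spectrum(rep(1, 100), discard = 50), "64")
})

test_that("fixed-morphogen runs are silent at level 0 and reproducible", {
  g <- init_random_genome(seed = 70)
  s0 <- simulate_fixed_morphogen(silent_genome(), 0, 200)
  expect_equal(sum(s0), 0)
  s1 <- simulate_fixed_morphogen(g, 40, 300)
  s2 <- simulate_fixed_morphogen(g, 40, 300)
  expect_identical(s1, s2)
})

test_that("frequency profiles flag non-oscillatory genomes and pick a stable gene", {
  prof <- frequency_profile(morphogen_reporter_genome(), n_levels = 10,
                            n_steps = 600, discard = 100)
  expect_true(prof$non_oscillatory)

  fx <- make_fixture_genome("gated_clock_and_switch")
  prof1 <- frequency_profile(fx, n_levels = 20)
  expect_false(prof1$non_oscillatory)
  # invariant to gene order in the genome
  set.seed(71)
  fx_perm <- genome(fx$genes[sample(n_genes(fx))])
  prof2 <- frequency_profile(fx_perm, n_levels = 20)
  expect_equal(prof2$selected_gene, prof1$selected_gene)
  expect_equal(prof2$dominant_freq, prof1$dominant_freq)
})

test_that("a morphogen-gated oscillator oscillates only above its gate", {
  fx <- make_fixture_genome("gated_clock_and_switch")
  prof <- frequency_profile(fx, n_levels = 25)
  osc <- prof$dominant_amp >= prof$osc_floor
  expect_true(any(osc) && any(!osc))
  # oscillating levels sit above the silent ones
  expect_gt(min(prof$levels[osc]), max(prof$levels[!osc]))
})

test_that("window profiles diagnose damping", {
  # synthetic exponentially damped oscillation, amplitude halving per window
  n <- 1800; window <- 256
  tser <- seq_len(n)
  damp <- 100 * exp(-log(2) * tser / window) * sin(2 * pi * 0.04 * tser)
  sp <- lapply(seq(1, n - window + 1, 128), function(s)
    fourier_spectrum(damp[s:(s + window - 1)]))
  amps <- vapply(sp, function(x) x$dominant_amp, 0.0)
  expect_true(all(diff(amps) < 0))
  freqs <- vapply(sp, function(x) x$dominant_freq, 0.0)
  expect_true(all(abs(freqs - 0.04) <= 1 / window))

  # persistent fixture: the last window keeps at least half the first's amplitude
  win <- window_profile(make_fixture_genome("delay_oscillator"))
  expect_gte(win$dominant_amp[length(win$dominant_amp)],
             0.5 * win$dominant_amp[1])

  flat <- window_profile(silent_genome())
  expect_equal(max(flat$dominant_amp), 0, tolerance = 1e-9)
})

fake_profile <- function(freqs, amps, levels = seq(0, 100, length.out = length(freqs)),
                         floor = 1) {
  structure(list(levels = levels, dominant_freq = freqs, dominant_amp = amps,
                 osc_floor = floor, non_oscillatory = all(amps < floor)),
            class = "cw_freq_profile")
}
fake_windows <- function(amps) {
  structure(list(dominant_amp = amps), class = "cw_window_profile")
}

test_that("classification applies the 0.02 frequency-difference threshold", {
  persistent <- fake_windows(c(80, 82, 79, 81))
  # frequencies rise from 0.05 at the lowest oscillating level to 0.08 at
  # the highest: diff 0.03
  sloped <- classify_oscillator(
    fake_profile(c(NA, seq(0.05, 0.08, length.out = 9)), c(0, rep(50, 9))),
    persistent)
  expect_equal(sloped$category, "sloped")
  expect_equal(sloped$freq_diff, 0.03, tolerance = 1e-9)

  constant <- classify_oscillator(
    fake_profile(c(NA, seq(0.05, 0.06, length.out = 9)), c(0, rep(50, 9))),
    persistent)
  expect_equal(constant$category, "constant")
  expect_equal(constant$freq_diff, 0.01, tolerance = 1e-9)

  damped <- classify_oscillator(
    fake_profile(c(NA, rep(0.05, 9)), c(0, rep(50, 9))),
    fake_windows(c(80, 40, 10, 2)))
  expect_equal(damped$category, "damped")

  none <- classify_oscillator(fake_profile(rep(NA_real_, 10), rep(0, 10)),
                              fake_windows(rep(0, 4)))
  expect_equal(none$category, "unclassified")
})

test_that("with a vanishing damping fraction every nonzero tail is persistent", {
  prof <- fake_profile(c(NA, seq(0.05, 0.08, length.out = 9)), c(0, rep(50, 9)))
  win <- fake_windows(c(80, 40, 10, 2)) # damped at the default 0.1
  expect_equal(classify_oscillator(prof, win)$category, "damped")
  expect_equal(classify_oscillator(prof, win, damping_fraction = 1e-9)$category,
               "sloped")
})

test_that("the freeze point brackets the oscillation gate and refines monotonically", {
  fx <- make_fixture_genome("gated_clock_and_switch")
  prof <- frequency_profile(fx, n_levels = 25)
  fp <- freeze_point(prof)
  osc <- prof$dominant_amp >= prof$osc_floor
  expect_equal(as.numeric(fp), max(prof$levels[!osc & prof$levels < min(prof$levels[osc])]))

  # a non-oscillatory genome is stable everywhere: freeze point at the top
  prof0 <- frequency_profile(morphogen_reporter_genome(), n_levels = 10,
                             n_steps = 600, discard = 100)
  expect_equal(as.numeric(freeze_point(prof0)), 100)

  # grid refinement keeps the freeze point within one coarse-grid spacing
  prof49 <- frequency_profile(fx, n_levels = 49)
  expect_lte(abs(as.numeric(freeze_point(prof49)) - as.numeric(fp)),
             100 / 24 + 1e-9)
})

test_that("the coarse-step oscillator period matches a fine-step reference", {
  fx <- make_fixture_genome("delay_oscillator")
  coarse <- simulate_fixed_morphogen(fx, 100, n_steps = 3600,
                                     params = kinetic_params(dt = 0.2))
  fine <- simulate_fixed_morphogen(fx, 100, n_steps = 72000,
                                   params = kinetic_params(dt = 0.01))
  gene_col <- 2 # first ring gene
  p_coarse <- estimate_period(coarse[1001:3600, gene_col], 0.2)
  p_fine <- estimate_period(fine[20001:72000, gene_col], 0.01)
  expect_lt(abs(p_coarse - p_fine) / p_fine, 0.05)
})
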