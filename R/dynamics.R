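#' Hill activation and repression terms
#'
#' `activation_term()` returns `a^n / (a^n + H^n)`, the saturating
#' contribution of an activator at concentration `a`; `repression_term()`
#' returns `H^n / (i^n + H^n)`, the attenuation due to a repressor at
#' concentration `i`. Both are half-maximal at the Hill constant `H`.
#'
#' @param a,i regulator concentration (>= 0); vectorised.
#' @param params a [kinetic_params()] object.
#' @return Numeric in `[0, 1)` (activation) or `(0, 1]` (repression).
#' @export
activation_term <- function(a, params = kinetic_params()) {
  an <- a^params$n
  an / (an + params$H^params$n)
}

#' @rdname activation_term
#' @export
repression_term <- function(i, params = kinetic_params()) {
  Hn <- params$H^params$n
  Hn / (i^params$n + Hn)
}

#' Expected transcription rate of one gene copy
#'
#' The activator with the strongest input sets the activation (OR gate),
#' repressors multiply (AND gate), scaled by the maximal rate `E`. A gene
#' with no activating sites is silent (the empty OR gate is 0): there is no
#' basal transcription.
#'
#' @param g a [gene()] (must not be of type 0; the morphogen is clamped).
#' @param state numeric vector of the 16 protein concentrations, indexed by
#'   type + 1.
#' @param params a [kinetic_params()] object.
#' @return Expected rate in `[0, E)`.
#' @export
transcription_rate <- function(g, state, params = kinetic_params()) {
  if (g$type == 0) stop("the morphogen gene is not transcribed")
  s <- g$sites
  act <- s[s[, 2] > 0, 1]
  if (length(act) == 0) return(0)
  a <- max(activation_term(state[act + 1], params))
  if (a == 0) return(0)
  rep_ <- s[s[, 2] < 0, 1]
  r <- if (length(rep_) == 0) 1 else prod(repression_term(state[rep_ + 1], params))
  a * r * params$E
}

#' Apply multiplicative expression noise to a rate
#'
#' Draws `eps ~ Normal(0, (l*R)^2)` and returns `max(0, R + eps)`. With
#' `l = 0` the input is returned unchanged and no random numbers are
#' consumed. When `l > 0` one standard-normal draw is consumed per rate,
#' including rates of 0, so trajectories stay aligned with the compiled
#' integrator draw-for-draw.
#'
#' @param r_expr expected rate(s), >= 0; vectorised.
#' @param noise a [noise_model()] object.
#' @return Realised rate(s), >= 0.
#' @export
apply_noise <- function(r_expr, noise = noise_model()) {
  if (noise$l == 0) return(r_expr)
  pmax(0, r_expr + noise$l * r_expr * stats::rnorm(length(r_expr)))
}

#' One forward-Euler step of a single cell
#'
#' Updates every non-morphogen protein:
#' `G_t <- G_t + dt * (sum of realised rates of the type-t gene copies - delta * G_t)`,
#' clamped at 0. The morphogen (type 0) is left untouched; it is governed by
#' the tissue (clamping in the growth zone, decay outside). This is the R
#' reference for the compiled integrator and takes the identical path
#' through the RNG stream when noise is on.
#'
#' @param state numeric vector of 16 concentrations (type + 1 indexing).
#' @param g a `cw_genome`.
#' @param params a [kinetic_params()] object.
#' @param noise a [noise_model()] object.
#' @return The updated state vector.
#' @export
step_cell <- function(state, g, params = kinetic_params(),
                      noise = noise_model()) {
  active <- Filter(function(x) x$type != 0, g$genes)
  rates <- vapply(active, transcription_rate, 0.0, state = state,
                  params = params)
  rates <- apply_noise(rates, noise)
  prod_ <- numeric(16)
  for (k in seq_along(active)) {
    t <- active[[k]]$type + 1
    prod_[t] <- prod_[t] + rates[k]
  }
  new <- state + params$dt * (prod_ - params$delta * state)
  new[1] <- state[1]
  pmax(new, 0)
}
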