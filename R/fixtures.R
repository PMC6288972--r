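#' Hand-built fixture genomes
#'
#' Minimal genomes instantiating the circuit motifs that evolve in the
#' simulations, used to exercise the whole analysis pipeline without
#' running evolution. All fixtures carry one siteless gene of every
#' otherwise unused type, so they are viable (all 16 types present).
#'
#' * `delay_oscillator`: a chain of `ring_size` genes (types 1, 2, ...)
#'   closed into a single negative feedback loop (the last gene represses
#'   the first) and driven by the morphogen, which activates the first
#'   gene. The chain supplies the delay that a negative loop needs to
#'   oscillate, and the morphogen drive gates the oscillation: at low
#'   morphogen the loop falls silent.
#' * `bistable_switch`: a self-activating segmentation gene (type 5), a
#'   positive feedback loop of size 1 with stable high/low states.
#' * `gated_clock_and_switch`: the gated oscillator wired into the
#'   bistable switch: a clock gene activates the segmentation gene, a
#'   second clock gene represses it, and self-activation latches the state
#'   once morphogen decay freezes the clock - the full sequential
#'   segmentation mechanism.
#' * `decorated_core`: `gated_clock_and_switch` plus deliberately inert
#'   decoration (an extra gene copy wired only to silent genes, and inert
#'   sites on the clock), for pruning tests.
#'
#' @param kind fixture name.
#' @param ring_size number of genes in the oscillator loop (>= 3; the
#'   default 5 gives robust sustained oscillations, while 3 relaxes to a
#'   fixed point - a handy damped counter-example).
#' @return A `cw_genome`.
#' @export
make_fixture_genome <- function(kind = c("delay_oscillator",
                                         "bistable_switch",
                                         "gated_clock_and_switch",
                                         "decorated_core"),
                                ring_size = 5) {
  kind <- match.arg(kind)
  stopifnot(ring_size >= 3, ring_size <= 9)
  ring_types <- seq_len(ring_size) # 1..ring_size (type 5 reserved for the switch)
  ring_types[ring_types >= 5] <- ring_types[ring_types >= 5] + 1L

  ring_genes <- lapply(seq_len(ring_size), function(i) {
    if (i == 1) {
      gene(ring_types[1], list(c(0L, 1L), c(ring_types[ring_size], -1L)))
    } else {
      gene(ring_types[i], list(c(ring_types[i - 1], 1L)))
    }
  })
  switch_gene <- switch(kind,
    bistable_switch = gene(5, list(c(5L, 1L))),
    delay_oscillator = gene(5),
    # the second clock gene drives the switch on, the third (a quarter
    # period later) knocks it down again - the doubled repressive site
    # makes the reset strong enough to push the switch back below its
    # latch threshold - and self-activation latches whichever state the
    # cell is in when morphogen decay freezes the clock
    gene(5, list(c(5L, 1L),
                 c(ring_types[2], 1L),
                 c(ring_types[3], -1L),
                 c(ring_types[3], -1L))))

  core <- switch(kind,
    bistable_switch = list(switch_gene),
    c(ring_genes, list(switch_gene)))

  used <- vapply(core, function(g) g$type, 0L)
  padding <- lapply(setdiff(0:15, used), gene)

  if (kind == "decorated_core") {
    # inert decoration: a second type-9 copy listening only to silent
    # genes, plus sites on the second clock gene that reference silent
    # genes (an always-zero activator never wins the OR gate; an
    # always-zero repressor multiplies by 1)
    deco <- gene(9, list(c(10L, 1L), c(11L, -1L)))
    core[[2]]$sites <- rbind(core[[2]]$sites, c(12L, 1L), c(13L, -1L))
    core <- c(core, list(deco))
  }

  genome(c(padding, core))
}
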