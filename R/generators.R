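#' Two-state reference generator
#'
#' The canonical two-level single-molecule system: two states exchanging
#' with a per-bin stay probability, observed through Gaussian noise around
#' two levels.  Defaults reproduce the standard simulated-FRET benchmark
#' (levels 0.3 and 0.7, sd 0.1, stay probability 0.9 per state).
#'
#' @param stay per-bin probability of remaining in the current state (one
#'   value recycled, or one per state).
#' @param means emission means of the low and high level.
#' @param sd emission standard deviation(s).
#' @return A [csm()] with states `"A"` (low) and `"B"` (high).
#' @export
two_state_machine <- function(stay = 0.9, means = c(0.3, 0.7), sd = 0.1) {
  stay <- rep_len(stay, 2)
  sd <- rep_len(sd, 2)
  csm(data.frame(from = c("A", "A", "B", "B"),
                 symbol = c(0L, 1L, 1L, 0L),
                 to = c("A", "B", "B", "A"),
                 p = c(stay[1], 1 - stay[1], stay[2], 1 - stay[2])),
      emissions = data.frame(symbol = 0:1, mean = means, sd = sd))
}

#' Degenerate four-state reference generator
#'
#' A four-state machine over three observable levels in which two hidden
#' states (`A` and `D`) share the lowest emission level but differ in their
#' self-transition probability -- hence are distinguishable only through the
#' transition structure, not through the observable.  Such "degenerate"
#' states are invisible to methods that tie one model state to each
#' observed level.
#'
#' Topology (symbol emitted on the transition equals the level of the
#' destination state, keeping the machine unifilar):
#' \preformatted{
#'   A --0--> A (stay_a)     A --1--> B (1 - stay_a)
#'   B --2--> C (0.7)        B --0--> D (0.3)
#'   C --0--> A (0.8)        C --1--> B (0.2)
#'   D --0--> D (stay_d)     D --1--> B (1 - stay_d)
#' }
#'
#' @param stay_a,stay_d self-transition probabilities of the two degenerate
#'   states (defaults 0.95 and 0.60).
#' @param means emission means of the three levels.
#' @param sd shared emission standard deviation.
#' @return A [csm()] with states `A`, `B`, `C`, `D`.
#' @export
degenerate_machine <- function(stay_a = 0.95, stay_d = 0.60,
                               means = c(0.1, 0.5, 0.9), sd = 0.09) {
  csm(data.frame(
        from   = c("A", "A", "B", "B", "C", "C", "D", "D"),
        symbol = c(0L,  1L,  2L,  0L,  0L,  1L,  0L,  1L),
        to     = c("A", "B", "C", "D", "A", "B", "D", "B"),
        p      = c(stay_a, 1 - stay_a, 0.7, 0.3, 0.8, 0.2, stay_d, 1 - stay_d)),
      emissions = data.frame(symbol = 0:2, mean = means, sd = sd))
}
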