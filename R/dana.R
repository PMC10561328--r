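# Built-in DANA model (dopamine/norepinephrine action in depression) and a
# random ordinary-net generator for property-based testing.

# The DANA structure, frozen as a declarative arc list decoded from the
# model's 6x8 input/output matrices (rows T0..T5, columns P0..P7).  One
# biologically surprising reading is intentional: T0 (low norepinephrine)
# consumes a token from P2 (bradykinesia) -- unambiguous in the matrices,
# so implemented as printed.
dana_arcs <- function() {
  data.frame(
    from = c("P2", "P6", "T0", "T0",
             "P0", "T1",
             "P1", "P7", "T2",
             "P0", "P1", "T3",
             "P3", "P4", "T4", "T4",
             "P2", "T5"),
    to   = c("T0", "T0", "P0", "P1",
             "T1", "P3",
             "T2", "T2", "P4",
             "T3", "T3", "P2",
             "T4", "T4", "P2", "P5",
             "T5", "P5"),
    stringsAsFactors = FALSE
  )
}

#' The built-in DANA net
#'
#' DANA ("Dopamine And Norepinephrine Analyze") is a qualitative
#' place/transition model of how low norepinephrine and low dopamine levels
#' propagate into depressive symptom states.  It has 8 places (P0..P7:
#' Weakened Energy, Cognitive Decline, Bradykinesia, intellectual
#' disability, Anhedonia, Blocking Depression, Norepinephrine, Dopamine), 6
#' transitions (T0..T5: Low Norepinephrine Levels, Decreased Willpower, Low
#' Dopamine Levels, Psychomotor Block, Feeling Down, Thinking Slow), 18
#' weight-1 arcs, and an initial marking with one token each on P2, P6 and
#' P7, i.e. `(0,0,1,0,0,0,1,1)`.
#'
#' Structurally the model has exactly two minimal S-invariants,
#' `(1,0,1,1,1,1,0,1)` and `(0,1,1,0,2,1,0,1)`, no T-invariant, and a
#' finite acyclic reachability graph of 10 markings, 3 of them dead.
#'
#' @return An [annotate()]d net with biological labels and the initial
#'   marking set.
#' @examples
#' dana <- build_dana()
#' minimal_s_invariants(dana$net)
#' @export
build_dana <- function() {
  net <- petri_net(
    places = paste0("P", 0:7),
    transitions = paste0("T", 0:5),
    arcs = dana_arcs()
  )
  annotate(
    net,
    place_labels = c(
      P0 = "Weakened Energy",
      P1 = "Cognitive Decline",
      P2 = "Bradykinesia",
      P3 = "intellectual disability",
      P4 = "Anhedonia",
      P5 = "Blocking Depression",
      P6 = "Norepinephrine",
      P7 = "Dopamine"
    ),
    transition_labels = c(
      T0 = "Low Norepinephrine Levels",
      T1 = "Decreased Willpower",
      T2 = "Low Dopamine Levels",
      T3 = "Psychomotor Block",
      T4 = "Feeling Down",
      T5 = "Thinking Slow"
    ),
    initial = c(0, 0, 1, 0, 0, 0, 1, 1)
  )
}

#' Generate a random ordinary net
#'
#' Each potential place -> transition and transition -> place arc is
#' included independently with probability `arc_prob`, weight 1.
#' Deterministic under a fixed seed; used as a test harness for
#' oracle-equivalence checks.
#'
#' @param n_places,n_transitions numbers of places / transitions (>= 1).
#' @param arc_prob arc inclusion probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return A [petri_net] with places `p1..` and transitions `t1..`.
#' @export
random_ordinary_net <- function(n_places, n_transitions, arc_prob, seed) {
  assert_count(n_places, "n_places", min = 1L)
  assert_count(n_transitions, "n_transitions", min = 1L)
  if (!is.numeric(arc_prob) || arc_prob < 0 || arc_prob > 1) {
    stop_pn("pn_value_error", "`arc_prob` must be in [0, 1]")
  }
  places <- paste0("p", seq_len(n_places))
  transitions <- paste0("t", seq_len(n_transitions))
  with_seed(seed, {
    pre_mask <- matrix(stats::runif(n_transitions * n_places) < arc_prob,
                       n_transitions, n_places)
    post_mask <- matrix(stats::runif(n_transitions * n_places) < arc_prob,
                        n_transitions, n_places)
  })
  pre_idx <- which(pre_mask, arr.ind = TRUE)
  post_idx <- which(post_mask, arr.ind = TRUE)
  arcs <- rbind(
    data.frame(from = places[pre_idx[, 2L]], to = transitions[pre_idx[, 1L]],
               stringsAsFactors = FALSE),
    data.frame(from = transitions[post_idx[, 1L]], to = places[post_idx[, 2L]],
               stringsAsFactors = FALSE)
  )
  petri_net(places, transitions, arcs)
}
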