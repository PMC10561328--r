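# Small nets built in code, shared across test files.

# p1 -> t1 -> p2 -> t2 -> p1 : a 2-place token-conserving cycle
cycle2_net <- function() {
  petri_net(
    places = c("p1", "p2"), transitions = c("t1", "t2"),
    arcs = data.frame(from = c("p1", "t1", "p2", "t2"),
                      to   = c("t1", "p2", "t2", "p1"))
  )
}

# single transition with pre = post on its only place
self_loop_net <- function() {
  petri_net(
    places = "p", transitions = "t",
    arcs = data.frame(from = c("p", "t"), to = c("t", "p"))
  )
}

# one transition with no input places (always enabled source)
source_net <- function() {
  petri_net(places = "p", transitions = "t",
            arcs = data.frame(from = "t", to = "p"))
}

# one transition consuming s1 and producing nothing
sink_net <- function() {
  petri_net(places = "s1", transitions = "t",
            arcs = data.frame(from = "s1", to = "t"))
}

no_arc_net <- function(n_places = 3L, n_transitions = 0L) {
  petri_net(places = paste0("p", seq_len(n_places)),
            transitions = if (n_transitions > 0L) paste0("t", seq_len(n_transitions)) else character(0))
}

dana_m0 <- c(0, 0, 1, 0, 0, 0, 1, 1)

# deterministic parameterization of random nets for property tests
property_net <- function(s) {
  random_ordinary_net(
    n_places = ((s - 1L) %% 5L) + 1L,
    n_transitions = ((s * 3L) %% 5L) + 1L,
    arc_prob = c(0.2, 0.4, 0.6)[(s %% 3L) + 1L],
    seed = s
  )
}

invariant_matrix <- function(invs) {
  if (length(invs) == 0L) return(NULL)
  do.call(rbind, lapply(invs, function(i) unname(i$vector)))
}
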