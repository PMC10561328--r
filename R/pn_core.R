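#' Construct a place/transition Petri net
#'
#' A place/transition net is a bipartite structure `N = (S, T; F)` of places
#' `S` (token-holding state variables), transitions `T` (events), and weighted
#' directed arcs `F` connecting places to transitions and transitions to
#' places.  Internally the net is stored as a pair of nonnegative integer
#' matrices `pre` and `post` with **rows = transitions, columns = places**:
#' `pre[t, s]` tokens are consumed from place `s` and `post[t, s]` produced
#' when transition `t` fires.  Classical unweighted nets correspond to 0/1
#' entries ("ordinary" nets); positive integer weights are supported so the
#' same machinery applies to stoichiometric biochemical networks.
#'
#' @param places character vector of place identifiers (canonical order).
#' @param transitions character vector of transition identifiers, disjoint
#'   from `places`.  `places` and `transitions` may not both be empty.
#' @param arcs `data.frame` with columns `from`, `to` and optionally `weight`
#'   (default 1).  Each arc must connect a place to a transition or a
#'   transition to a place; weights must be positive integers.
#' @return An object of class `petri_net` with components `places`,
#'   `transitions`, `pre` and `post` (integer matrices, transitions x places).
#' @examples
#' cycle2 <- petri_net(
#'   places = c("p1", "p2"), transitions = c("t1", "t2"),
#'   arcs = data.frame(from = c("p1", "t1", "p2", "t2"),
#'                     to   = c("t1", "p2", "t2", "p1"))
#' )
#' incidence_matrix(cycle2)$a
#' @export
petri_net <- function(places, transitions, arcs = NULL) {
  places <- as.character(places)
  transitions <- as.character(transitions)
  if (anyDuplicated(places) || anyDuplicated(transitions)) {
    stop_pn("pn_identifier_error", "duplicate place or transition identifiers")
  }
  if (length(intersect(places, transitions)) > 0L) {
    stop_pn("pn_identifier_error",
            "place and transition identifier sets must be disjoint")
  }
  if (length(places) + length(transitions) == 0L) {
    stop_pn("pn_identifier_error",
            "a net must contain at least one place or transition")
  }
  n <- length(transitions)
  m <- length(places)
  pre <- post <- matrix(0L, n, m, dimnames = list(transitions, places))
  if (!is.null(arcs) && nrow(as.data.frame(arcs)) > 0L) {
    arcs <- as.data.frame(arcs)
    if (!all(c("from", "to") %in% names(arcs))) {
      stop_pn("pn_format_error", "`arcs` needs columns `from` and `to`")
    }
    w <- if ("weight" %in% names(arcs)) arcs$weight else rep(1L, nrow(arcs))
    if (any(is.na(w)) || any(w < 1) || any(w != floor(w))) {
      stop_pn("pn_value_error", "arc weights must be positive integers")
    }
    for (k in seq_len(nrow(arcs))) {
      from <- as.character(arcs$from[k])
      to <- as.character(arcs$to[k])
      if (from %in% places && to %in% transitions) {
        pre[to, from] <- pre[to, from] + as.integer(w[k])
      } else if (from %in% transitions && to %in% places) {
        post[from, to] <- post[from, to] + as.integer(w[k])
      } else {
        stop_pn("pn_identifier_error", sprintf(
          "arc %s -> %s does not connect a declared place and transition",
          from, to))
      }
    }
  }
  structure(
    list(places = places, transitions = transitions, pre = pre, post = post),
    class = "petri_net"
  )
}

#' @export
print.petri_net <- function(x, ...) {
  cat(sprintf("<petri_net> %d places, %d transitions, %d arcs\n",
              length(x$places), length(x$transitions),
              sum(x$pre > 0L) + sum(x$post > 0L)))
  invisible(x)
}

# Validate a marking vector against a net; returns a named integer vector.
as_marking <- function(net, m) {
  if (length(m) != length(net$places)) {
    stop_pn("pn_dimension_error", sprintf(
      "marking length %d does not match the net's %d places",
      length(m), length(net$places)))
  }
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m))) {
    stop_pn("pn_value_error", "markings must be nonnegative integers")
  }
  stats::setNames(as.integer(m), net$places)
}

transition_index <- function(net, t) {
  i <- match(t, net$transitions)
  if (is.na(i)) {
    stop_pn("pn_identifier_error", sprintf("unknown transition '%s'", t))
  }
  i
}

#' Token-game semantics: enabling, firing, sequences, dead markings
#'
#' A transition `t` is enabled at marking `M` when every place `s` holds at
#' least `pre[t, s]` tokens.  Firing an enabled transition yields the marking
#' `M'(s) = M(s) - pre(t, s) + post(t, s)`; places outside the pre- and
#' post-set of `t` are untouched.
#'
#' @param net a [petri_net].
#' @param m marking: nonnegative integer vector in the net's place order.
#' @param t a transition identifier.
#' @return `is_enabled()` a logical scalar; `enabled_set()` a character
#'   vector of enabled transitions in transition-index order; `fire()` the
#'   successor marking (named integer vector); `is_dead()` `TRUE` when no
#'   transition is enabled.
#' @examples
#' dana <- build_dana()
#' enabled_set(dana$net, dana$initial)      # "T0" "T5"
#' fire(dana$net, dana$initial, "T0")
#' @export
is_enabled <- function(net, m, t) {
  m <- as_marking(net, m)
  i <- transition_index(net, t)
  all(m >= net$pre[i, ])
}

#' @rdname is_enabled
#' @export
enabled_set <- function(net, m) {
  m <- as_marking(net, m)
  if (length(net$transitions) == 0L) return(character(0))
  ok <- apply(net$pre, 1L, function(row) all(m >= row))
  net$transitions[ok]
}

#' @rdname is_enabled
#' @export
fire <- function(net, m, t) {
  m <- as_marking(net, m)
  i <- transition_index(net, t)
  deficit <- net$pre[i, ] - m
  if (any(deficit > 0L)) {
    stop_pn("pn_enabling_error", sprintf(
      "transition '%s' is not enabled: insufficient tokens at %s",
      t, paste(net$places[deficit > 0L], collapse = ", ")))
  }
  m - net$pre[i, ] + net$post[i, ]
}

#' @rdname is_enabled
#' @export
is_dead <- function(net, m) {
  length(enabled_set(net, m)) == 0L
}

new_trace <- function(initial, steps, seed = NULL, terminated_dead) {
  structure(
    list(initial = initial, steps = steps, seed = seed,
         terminated_dead = terminated_dead),
    class = "pn_trace"
  )
}

#' @export
print.pn_trace <- function(x, ...) {
  cat(sprintf("<pn_trace> %d steps%s%s\n", length(x$steps),
              if (x$terminated_dead) ", ends dead" else "",
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  cat("  M0: (", paste(x$initial, collapse = ","), ")\n", sep = "")
  for (s in x$steps) {
    cat("  ", s$transition, " -> (", paste(s$marking, collapse = ","), ")\n",
        sep = "")
  }
  invisible(x)
}

# Final marking of a trace.
trace_final <- function(trace) {
  n <- length(trace$steps)
  if (n == 0L) trace$initial else trace$steps[[n]]$marking
}

#' Fire a fixed sequence of transitions
#'
#' @inheritParams is_enabled
#' @param m0 initial marking.
#' @param seq character vector of transition identifiers fired in order.
#' @return A `pn_trace`: the initial marking, one `(transition, marking)`
#'   step per firing, and `terminated_dead` set when the final marking
#'   enables nothing.
#' @export
fire_sequence <- function(net, m0, seq = character(0)) {
  m <- as_marking(net, m0)
  steps <- vector("list", length(seq))
  for (k in seq_along(seq)) {
    m <- tryCatch(fire(net, m, seq[[k]]), pn_error = function(e) {
      stop_pn(class(e)[1L], sprintf("step %d (%s): %s", k - 1L, seq[[k]],
                                    conditionMessage(e)))
    })
    steps[[k]] <- list(transition = seq[[k]], marking = m)
  }
  new_trace(as_marking(net, m0), steps, seed = NULL,
            terminated_dead = is_dead(net, m))
}

#' Simulate a random run of the token game
#'
#' At each step one transition is drawn uniformly at random from the enabled
#' set; the run stops at a dead marking or after `max_steps` firings.  The
#' generator is seeded deterministically, so identical arguments always yield
#' identical traces; the seed is recorded in the returned trace.
#'
#' @inheritParams fire_sequence
#' @param max_steps maximum number of firings (>= 0).
#' @param seed integer RNG seed.
#' @return A `pn_trace` with `seed` recorded.
#' @export
random_run <- function(net, m0, max_steps, seed) {
  assert_count(max_steps, "max_steps")
  seed <- assert_count(seed, "seed")
  m <- as_marking(net, m0)
  steps <- list()
  with_seed(seed, {
    for (k in seq_len(max_steps)) {
      en <- enabled_set(net, m)
      if (length(en) == 0L) break
      t <- en[[sample.int(length(en), 1L)]]
      m <- fire(net, m, t)
      steps[[length(steps) + 1L]] <- list(transition = t, marking = m)
    }
  })
  new_trace(as_marking(net, m0), steps, seed = seed,
            terminated_dead = is_dead(net, m))
}
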