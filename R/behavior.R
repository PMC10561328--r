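#' Exhaustive reachability analysis
#'
#' Breadth-first exploration of the set of markings reachable from `m0`,
#' firing enabled transitions in transition-index order.  Exploration stops
#' once `max_markings` distinct markings have been discovered; the graph is
#' then flagged `truncated` rather than erroring, since unbounded nets are
#' legal inputs.
#'
#' @inheritParams input_matrix
#' @param m0 initial marking.
#' @param max_markings cap on the number of distinct markings explored
#'   (default 100000).
#' @return A `reachability_graph`: list with `nodes` (integer matrix, one
#'   marking per row, row 1 = `m0`), `edges` (`data.frame` with columns
#'   `from`, `transition`, `to`; `from`/`to` are node row indices), `initial`
#'   (index 1), `dead` (indices of markings enabling nothing; complete only
#'   when not truncated), and `truncated` (logical).
#' @examples
#' dana <- build_dana()
#' g <- reachability_graph(dana$net, dana$initial)
#' nrow(g$nodes)      # 10 reachable markings
#' length(g$dead)     # 3 dead markings
#' @export
reachability_graph <- function(net, m0, max_markings = 100000L) {
  assert_count(max_markings, "max_markings", min = 1L)
  m0 <- as_marking(net, m0)
  key <- function(m) paste(m, collapse = ",")
  index <- new.env(parent = emptyenv())
  nodes <- list(m0)
  assign(key(m0), 1L, envir = index)
  edges_from <- integer(0)
  edges_t <- character(0)
  edges_to <- integer(0)
  queue <- 1L
  truncated <- FALSE
  while (length(queue) > 0L) {
    i <- queue[[1L]]
    queue <- queue[-1L]
    m <- nodes[[i]]
    for (t in enabled_set(net, m)) {
      m2 <- fire(net, m, t)
      k2 <- key(m2)
      j <- if (exists(k2, envir = index, inherits = FALSE)) {
        get(k2, envir = index, inherits = FALSE)
      } else {
        if (length(nodes) >= max_markings) {
          truncated <- TRUE
          next
        }
        nodes[[length(nodes) + 1L]] <- m2
        assign(k2, length(nodes), envir = index)
        queue <- c(queue, length(nodes))
        length(nodes)
      }
      edges_from <- c(edges_from, i)
      edges_t <- c(edges_t, t)
      edges_to <- c(edges_to, j)
    }
  }
  node_mat <- do.call(rbind, nodes)
  rownames(node_mat) <- NULL
  has_out <- unique(edges_from)
  dead <- setdiff(seq_len(nrow(node_mat)), has_out)
  structure(
    list(nodes = node_mat,
         edges = data.frame(from = edges_from, transition = edges_t,
                            to = edges_to, stringsAsFactors = FALSE),
         initial = 1L, dead = dead, truncated = truncated,
         places = net$places),
    class = "reachability_graph"
  )
}

#' @export
print.reachability_graph <- function(x, ...) {
  cat(sprintf("<reachability_graph> %d markings, %d edges, %d dead%s\n",
              nrow(x$nodes), nrow(x$edges), length(x$dead),
              if (x$truncated) " (TRUNCATED)" else ""))
  invisible(x)
}

#' Per-place bounds over the reachable state space
#'
#' @param graph a complete (non-truncated) [reachability_graph()].
#' @return Named integer vector: the componentwise maximum token count each
#'   place attains over all reachable markings.
#' @export
place_bounds <- function(graph) {
  if (graph$truncated) {
    stop_pn("pn_completeness_error",
            "place bounds require a complete (non-truncated) reachability graph")
  }
  stats::setNames(apply(graph$nodes, 2L, max), graph$places)
}

#' Check token conservation of S-invariants over a reachability graph
#'
#' For every reachable marking `M'` and every S-invariant `Y`, verifies
#' `Y' M' == Y' M0` exactly.
#'
#' @param graph a [reachability_graph()].
#' @param invariants list of S-kind `pn_invariant` objects.
#' @return A list with `conserved` (logical) and `values` (the conserved
#'   weighted token sum per invariant; `NA` where conservation fails).
#' @export
check_conservation <- function(graph, invariants) {
  kinds <- vapply(invariants, `[[`, character(1), "kind")
  if (any(kinds != "S")) {
    stop_pn("pn_kind_error", "conservation check requires S-kind invariants only")
  }
  values <- vapply(invariants, function(inv) {
    sums <- as.integer(graph$nodes %*% inv$vector)
    if (all(sums == sums[[graph$initial]])) sums[[graph$initial]] else NA_integer_
  }, integer(1))
  list(conserved = length(values) == 0L || !anyNA(values), values = values)
}

#' Detect directed cycles in a reachability graph
#'
#' A cycle means some nonempty firing sequence reproduces a marking --
#' behaviorally what a realizable T-invariant expresses.
#'
#' @param graph a [reachability_graph()].
#' @return Logical: `TRUE` if the graph contains a directed cycle.
#' @export
has_cycle <- function(graph) {
  n <- nrow(graph$nodes)
  adj <- split(graph$edges$to, factor(graph$edges$from, levels = seq_len(n)))
  state <- integer(n)  # 0 unseen, 1 on stack, 2 done
  for (start in seq_len(n)) {
    if (state[start] != 0L) next
    stack <- list(list(v = start, i = 0L))
    state[start] <- 1L
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      nbrs <- adj[[top$v]]
      if (top$i < length(nbrs)) {
        stack[[length(stack)]]$i <- top$i + 1L
        w <- nbrs[[top$i + 1L]]
        if (state[w] == 1L) return(TRUE)
        if (state[w] == 0L) {
          state[w] <- 1L
          stack[[length(stack) + 1L]] <- list(v = w, i = 0L)
        }
      } else {
        state[top$v] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  FALSE
}

#' Export a reachability graph
#'
#' `write_reachability_tsv()` writes the edge list (source marking, fired
#' transition, target marking).  `write_reachability_dot()` writes GraphViz
#' DOT with marking vectors as node labels and transition ids as edge
#' labels.
#'
#' @param graph a [reachability_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reachability_tsv <- function(graph, path) {
  fmt <- function(i) paste(graph$nodes[i, ], collapse = ",")
  lines <- c("from\ttransition\tto",
             vapply(seq_len(nrow(graph$edges)), function(k) {
               paste(fmt(graph$edges$from[k]), graph$edges$transition[k],
                     fmt(graph$edges$to[k]), sep = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_reachability_tsv
#' @export
write_reachability_dot <- function(graph, path) {
  fmt <- function(i) paste0("(", paste(graph$nodes[i, ], collapse = ","), ")")
  lines <- c("digraph reachability {",
             sprintf('  n%d [label="%s"%s];', seq_len(nrow(graph$nodes)),
                     vapply(seq_len(nrow(graph$nodes)), fmt, character(1)),
                     ifelse(seq_len(nrow(graph$nodes)) %in% graph$dead,
                            ", shape=doublecircle", "")),
             sprintf('  n%d -> n%d [label="%s"];', graph$edges$from,
                     graph$edges$to, graph$edges$transition),
             "}")
  writeLines(lines, path)
  invisible(path)
}
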