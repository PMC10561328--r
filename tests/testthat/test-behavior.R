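dana_reachable <- function() {
  # independently derived by hand-iterating the firing rule from (0,0,1,0,0,0,1,1)
  matrix(c(0,0,1,0,0,0,1,1,
           1,1,0,0,0,0,0,1,
           0,0,0,0,0,1,1,1,
           0,1,0,1,0,0,0,1,
           1,0,0,0,1,0,0,0,
           0,0,1,0,0,0,0,1,
           0,0,0,1,1,0,0,0,
           0,0,0,0,0,1,0,1,
           0,0,1,0,0,1,0,0,
           0,0,0,0,0,2,0,0), ncol = 8, byrow = TRUE)
}

test_that("DANA reachability graph is complete, 10 markings, 3 dead", {
  dana <- build_dana()
  g <- reachability_graph(dana$net, dana_m0, 1000)
  expect_false(g$truncated)
  expect_identical(nrow(g$nodes), 10L)
  key <- function(m) apply(m, 1, paste, collapse = ",")
  expect_setequal(key(g$nodes), key(dana_reachable()))
  expect_length(g$dead, 3L)
  dead_keys <- key(g$nodes[g$dead, , drop = FALSE])
  expect_setequal(dead_keys,
                  c("0,0,0,0,0,1,1,1", "0,0,0,0,0,2,0,0", "0,0,0,0,0,1,0,1"))
  # every edge satisfies the firing rule
  for (k in seq_len(nrow(g$edges))) {
    expect_identical(
      unname(fire(dana$net, g$nodes[g$edges$from[k], ], g$edges$transition[k])),
      unname(g$nodes[g$edges$to[k], ]))
  }
  # BFS determinism: identical inputs give identical orderings
  expect_identical(g, reachability_graph(dana$net, dana_m0, 1000))
})

test_that("reachable markings satisfy the state equation along BFS paths", {
  dana <- build_dana()
  g <- reachability_graph(dana$net, dana_m0)
  # recover one firing-count vector per node by BFS parent traversal
  parent <- rep(NA_integer_, nrow(g$nodes))
  via <- rep(NA_character_, nrow(g$nodes))
  for (k in seq_len(nrow(g$edges))) {
    to <- g$edges$to[k]
    if (to != 1L && is.na(parent[to])) {
      parent[to] <- g$edges$from[k]
      via[to] <- g$edges$transition[k]
    }
  }
  for (i in seq_len(nrow(g$nodes))) {
    counts <- rep(0L, length(dana$net$transitions))
    j <- i
    while (!is.na(parent[j])) {
      ti <- match(via[j], dana$net$transitions)
      counts[ti] <- counts[ti] + 1L
      j <- parent[j]
    }
    expect_identical(unname(apply_firing_count(dana$net, dana_m0, counts)),
                     unname(g$nodes[i, ]))
  }
})

test_that("truncation is flagged, not raised, and blocks place_bounds", {
  dana <- build_dana()
  g1 <- reachability_graph(dana$net, dana_m0, 1)
  expect_true(g1$truncated)
  expect_error(place_bounds(g1), class = "pn_completeness_error")
  # an unbounded net truncates instead of hanging
  gsrc <- reachability_graph(source_net(), 0, 50)
  expect_true(gsrc$truncated)
  expect_identical(nrow(gsrc$nodes), 50L)
})

test_that("place bounds are the componentwise reachable maxima", {
  dana <- build_dana()
  g <- reachability_graph(dana$net, dana_m0)
  expect_identical(unname(place_bounds(g)), c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L))
  expect_identical(unname(place_bounds(reachability_graph(cycle2_net(), c(1, 0)))),
                   c(1L, 1L))
  expect_identical(unname(place_bounds(reachability_graph(no_arc_net(1, 0), 3))),
                   3L)
})

test_that("conservation check over the graph", {
  dana <- build_dana()
  g <- reachability_graph(dana$net, dana_m0)
  s <- minimal_s_invariants(dana$net)
  res <- check_conservation(g, s)
  expect_true(res$conserved)
  expect_identical(res$values, c(2L, 2L))
  # a non-invariant weight vector is caught
  fake <- list(structure(list(kind = "S",
                              vector = stats::setNames(c(1L, rep(0L, 7)), dana$net$places),
                              support = "P0", normalized = TRUE),
                         class = "pn_invariant"))
  expect_false(check_conservation(g, fake)$conserved)
  expect_true(check_conservation(g, list())$conserved)
  expect_error(check_conservation(g, minimal_t_invariants(cycle2_net())),
               class = "pn_kind_error")
})

test_that("DANA graph is acyclic; a cyclic net is detected", {
  dana <- build_dana()
  expect_false(has_cycle(reachability_graph(dana$net, dana_m0)))
  expect_true(has_cycle(reachability_graph(cycle2_net(), c(1, 0))))
})

test_that("graph exports list every edge", {
  dana <- build_dana()
  g <- reachability_graph(dana$net, dana_m0)
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".dot")
  on.exit(unlink(c(f1, f2)))
  write_reachability_tsv(g, f1)
  expect_length(readLines(f1), nrow(g$edges) + 1L)
  write_reachability_dot(g, f2)
  dot <- readLines(f2)
  expect_identical(sum(grepl("label=\"T", dot)), nrow(g$edges))
  expect_identical(sum(grepl("^  n[0-9]+ \\[", dot)), 10L)
})
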