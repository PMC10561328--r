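test_that("net construction enforces the structural invariants", {
  expect_s3_class(cycle2_net(), "petri_net")
  expect_error(petri_net(c("a", "a"), "t"), class = "pn_identifier_error")
  expect_error(petri_net("x", "x"), class = "pn_identifier_error")
  expect_error(petri_net(character(0), character(0)),
               class = "pn_identifier_error")
  expect_error(
    petri_net("p", "t", arcs = data.frame(from = "p", to = "q")),
    class = "pn_identifier_error")
  expect_error(
    petri_net("p", "t", arcs = data.frame(from = "p", to = "p")),
    class = "pn_identifier_error")
  expect_error(
    petri_net("p", "t", arcs = data.frame(from = "p", to = "t", weight = 0)),
    class = "pn_value_error")
})

test_that("enabling follows the marking-threshold rule", {
  dana <- build_dana()
  expect_true(is_enabled(dana$net, dana_m0, "T0"))
  expect_false(is_enabled(dana$net, dana_m0, "T2"))
  expect_error(is_enabled(dana$net, dana_m0, "T9"),
               class = "pn_identifier_error")
  # the all-zero marking enables nothing with a nonempty pre-set
  zero <- rep(0, 8)
  for (t in dana$net$transitions) expect_false(is_enabled(dana$net, zero, t))
  # a source transition is enabled everywhere
  expect_true(is_enabled(source_net(), 0, "t"))
})

test_that("enabled_set matches brute-force is_enabled, in index order", {
  dana <- build_dana()
  expect_identical(enabled_set(dana$net, dana_m0), c("T0", "T5"))
  expect_identical(enabled_set(dana$net, c(0, 0, 0, 0, 0, 1, 1, 1)),
                   character(0))
  g <- reachability_graph(dana$net, dana_m0)
  for (i in seq_len(nrow(g$nodes))) {
    m <- g$nodes[i, ]
    expected <- dana$net$transitions[
      vapply(dana$net$transitions, function(t) is_enabled(dana$net, m, t),
             logical(1))]
    expect_identical(enabled_set(dana$net, m), expected)
  }
})

test_that("fire applies the token-change rule and reports deficits", {
  dana <- build_dana()
  expect_identical(unname(fire(dana$net, dana_m0, "T0")),
                   c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 1L))
  expect_identical(unname(fire(dana$net, dana_m0, "T5")),
                   c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L))
  err <- tryCatch(fire(dana$net, dana_m0, "T2"), condition = identity)
  expect_s3_class(err, "pn_enabling_error")
  expect_match(conditionMessage(err), "P1")  # the deficient place is named
  # self-loop leaves the marking unchanged
  expect_identical(unname(fire(self_loop_net(), 1, "t")), 1L)
})

test_that("places outside the pre/post sets of t are never touched", {
  dana <- build_dana()
  g <- reachability_graph(dana$net, dana_m0)
  for (i in seq_len(nrow(g$nodes))) {
    m <- g$nodes[i, ]
    for (t in enabled_set(dana$net, m)) {
      ti <- match(t, dana$net$transitions)
      untouched <- dana$net$pre[ti, ] == 0L & dana$net$post[ti, ] == 0L
      expect_identical(unname(fire(dana$net, m, t))[untouched],
                       unname(m)[untouched])
    }
  }
})

test_that("token balance holds on random nets", {
  for (s in 1:25) {
    net <- property_net(s)
    m <- rep(3L, length(net$places))  # rich marking: everything enabled
    for (t in enabled_set(net, m)) {
      ti <- match(t, net$transitions)
      delta <- sum(fire(net, m, t)) - sum(m)
      expect_identical(delta, sum(net$post[ti, ]) - sum(net$pre[ti, ]))
    }
  }
})

test_that("fire_sequence iterates the firing rule and flags dead ends", {
  dana <- build_dana()
  tr <- fire_sequence(dana$net, dana_m0, c("T0", "T1", "T2", "T4", "T5"))
  expect_length(tr$steps, 5L)
  expect_identical(unname(tr$steps[[5]]$marking),
                   c(0L, 0L, 0L, 0L, 0L, 2L, 0L, 0L))
  expect_true(tr$terminated_dead)
  # each intermediate step equals fire applied to its predecessor
  m <- tr$initial
  for (s in tr$steps) {
    expect_identical(s$marking, fire(dana$net, m, s$transition))
    m <- s$marking
  }
  empty <- fire_sequence(dana$net, dana_m0, character(0))
  expect_length(empty$steps, 0L)
  expect_identical(unname(empty$initial), as.integer(dana_m0))
  err <- tryCatch(fire_sequence(dana$net, dana_m0, "T2"), condition = identity)
  expect_s3_class(err, "pn_enabling_error")
  expect_match(conditionMessage(err), "step 0")
})

test_that("random_run is seeded, capped, and step-valid", {
  dana <- build_dana()
  expect_length(random_run(dana$net, dana_m0, 0, 7)$steps, 0L)
  for (seed in c(1, 17, 99)) {
    tr <- random_run(dana$net, dana_m0, 10, seed)
    expect_lte(length(tr$steps), 5L)  # longest possible run in this model
    expect_true(tr$terminated_dead)
    expect_identical(tr$seed, as.integer(seed))
    m <- tr$initial
    for (s in tr$steps) {
      expect_true(is_enabled(dana$net, m, s$transition))
      expect_identical(s$marking, fire(dana$net, m, s$transition))
      m <- s$marking
    }
    expect_identical(tr, random_run(dana$net, dana_m0, 10, seed))
  }
  # the caller's RNG stream is not disturbed
  set.seed(123)
  before <- .Random.seed
  random_run(dana$net, dana_m0, 10, 5)
  expect_identical(.Random.seed, before)
})

test_that("is_dead and marking validation behave", {
  dana <- build_dana()
  expect_true(is_dead(dana$net, c(0, 0, 0, 0, 0, 2, 0, 0)))
  expect_false(is_dead(dana$net, dana_m0))
  expect_true(is_dead(no_arc_net(2, 0), c(1, 1)))
  expect_error(is_dead(dana$net, c(1, 2)), class = "pn_dimension_error")
  expect_error(is_dead(dana$net, c(-1, 0, 0, 0, 0, 0, 0, 0)),
               class = "pn_value_error")
})
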