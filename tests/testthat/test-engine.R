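# Core propagation engine: transforms, update formulas, iteration semantics.

test_that("integer-to-probability transform is the 0.5 + 0.1v line with hard bounds", {
  expect_equal(to_probability(-4:4), seq(0.1, 0.9, by = 0.1))
  expect_error(to_probability(5), "-4\\.\\.4")
  expect_error(to_probability(2.5), "integer")
  expect_error(to_probability(NA), "integer")
})

test_that("probability-to-change conversion scales deviation from 0.5 by 10", {
  expect_equal(from_probability(0.5), 0)
  expect_equal(from_probability(0.9), 4)
  expect_equal(from_probability(0.82), 3.2)
  expect_error(from_probability(1.2), "probability")
})

test_that("per-parent conditional marginalises the parent and is odd about 0.5", {
  expect_equal(conditional_given_parent(0.9, 0.9), 0.82)
  # a neutral edge contributes nothing regardless of the parent
  for (q in c(0.1, 0.3, 0.7, 0.9)) {
    expect_equal(conditional_given_parent(0.5, q), 0.5)
  }
  # mirror of the first case
  expect_equal(conditional_given_parent(0.9, 0.1), 0.18)
  expect_equal(conditional_given_parent(0.9, 0.1),
               1 - conditional_given_parent(0.9, 0.9))
})

test_that("prior-bearing posterior blends evidence and clamps to [0.1, 0.9]", {
  expect_equal(posterior_with_prior(0.5, 0.82), 0.58)
  # raw value 0.9288 exceeds the certainty ceiling
  expect_equal(posterior_with_prior(0.9, 0.82), 0.9)
  expect_equal(posterior_with_prior(0.5, c(0.5, 0.5)), 0.5)
  expect_error(posterior_with_prior(0.5, numeric(0)), "non-empty")
})

test_that("interactions-only posterior is the clamped mean of conditionals", {
  expect_equal(posterior_from_interactions(0.82), 0.82)
  expect_equal(posterior_from_interactions(c(0.82, 0.6)), 0.71)
  expect_equal(posterior_from_interactions(c(0.18, 0.82)), 0.5)
  expect_error(posterior_from_interactions(numeric(0)), "non-empty")
})

test_that("max-certainty selection picks the value furthest from 0.5, ties to the prior-bearing candidate", {
  expect_equal(select_most_certain(0.58, 0.82), 0.82)
  expect_equal(select_most_certain(0.3, 0.6), 0.3)
  expect_equal(select_most_certain(0.7, 0.3), 0.7)
})

test_that("one synchronous step reproduces the hand-traced chain values", {
  toys <- toy_fixtures()
  net <- toys$chain2$network
  s0 <- initial_state(net, toys$chain2$scenario)
  s1 <- bbn_step(s0, net)
  # interactions-only route (0.82) beats the prior-blend (0.58)
  expect_equal(unname(s1$p_inc["B"]), 0.82)
  expect_equal(unname(s1$p_inc["A"]), 0.9)
  # second step: now the prior-bearing route wins
  s2 <- bbn_step(s1, net)
  expect_equal(unname(s2$p_inc["B"]), 0.82 + 0.18 * (0.82 * 0.32))
})

test_that("a state with every node neutral is a fixed point", {
  net <- random_network(generator_spec(n_nodes = 6, density = 0.5, seed = 42))
  s <- initial_state(net)
  expect_equal(bbn_step(s, net)$p_inc, s$p_inc)
})

test_that("four default iterations drive a strong two-node chain to saturation", {
  toys <- toy_fixtures()
  res <- bbn_predict(toys$chain2$network, toys$chain2$scenario)[[1]]
  expect_equal(res$change, c(A = 4, B = 4))
})

test_that("signal travels one hop per iteration on a six-node chain", {
  toys <- toy_fixtures()
  res <- bbn_predict(toys$chain6$network, toys$chain6$scenario)[[1]]
  expect_true(all(abs(res$change[c("B", "C", "D", "E")]) > 0))
  expect_equal(unname(res$change["F"]), 0)
  # and with more iterations the signal does reach the tail
  res6 <- bbn_predict(toys$chain6$network, toys$chain6$scenario,
                      iterations = 6)[[1]]
  expect_gt(unname(res6$change["F"]), 0)
})

test_that("an all-zero scenario predicts no change anywhere", {
  for (seed in 1:5) {
    net <- random_network(generator_spec(n_nodes = 7, density = 0.4,
                                         seed = seed))
    null_sc <- bbn_scenario(integer(0), name = "null")
    res <- bbn_predict(net, null_sc)[[1]]
    expect_equal(unname(res$change), rep(0, 7))
  }
})

test_that("pinning holds a manipulated node against reciprocal feedback", {
  toys <- toy_fixtures()
  res <- bbn_predict(toys$recip2$network, toys$recip2$scenario)[[1]]
  expect_equal(unname(res$change["SpeciesA"]), 4)   # held by the pin
  expect_lt(unname(res$change["SpeciesB"]), 0)      # driven down
})

test_that("prediction validates its inputs", {
  toys <- toy_fixtures()
  expect_error(bbn_predict(toys$chain2$network, list()), "at least one")
  expect_error(bbn_predict(toys$chain2$network, toys$chain2$scenario,
                           iterations = 0), "positive integer")
  many <- rep(list(toys$chain2$scenario), 13)
  expect_warning(bbn_predict(toys$chain2$network, many), "12")
})

test_that("probabilities stay in [0.1, 0.9] and changes in [-4, 4] on random webs", {
  for (seed in 1:40) {
    spec <- generator_spec(n_nodes = 6, density = 0.5, seed = seed,
                           n_manipulated = 2)
    net <- random_network(spec)
    sc <- random_scenario(net, spec)
    state <- initial_state(net, sc)
    for (it in 1:4) {
      state <- bbn_step(state, net)
      expect_true(all(state$p_inc >= 0.1 & state$p_inc <= 0.9))
    }
    res <- bbn_predict(net, sc)[[1]]
    expect_true(all(res$change >= -4 & res$change <= 4))
  }
})

test_that("negating a scenario negates every prediction exactly", {
  for (seed in 1:30) {
    spec <- generator_spec(n_nodes = 6, density = 0.5, seed = seed,
                           n_manipulated = 2)
    net <- random_network(spec)
    sc <- random_scenario(net, spec)
    neg <- bbn_scenario(-sc$priors, name = "neg")
    a <- bbn_predict(net, sc)[[1]]$change
    b <- bbn_predict(net, neg)[[1]]$change
    expect_equal(b, -a, tolerance = 1e-12)
  }
})

test_that("nodes beyond the iteration horizon of every prior are unchanged", {
  for (seed in 1:15) {
    spec <- generator_spec(n_nodes = 8, density = 0.2, seed = seed)
    net <- random_network(spec)
    sc <- random_scenario(net, spec)
    iters <- 4
    g <- igraph::graph_from_data_frame(net$edges[c("parent", "child")],
                                       directed = TRUE, vertices = net$nodes)
    d <- igraph::distances(g, v = names(sc$priors), mode = "out")
    reachable <- apply(d, 2, min) <= iters
    res <- bbn_predict(net, sc, iterations = iters)[[1]]
    expect_equal(unname(res$change[!reachable[net$nodes]]),
                 rep(0, sum(!reachable[net$nodes])))
  }
})

test_that("a single positive edge responds monotonically to its strength", {
  changes <- vapply(1:4, function(s) {
    net <- bbn_network(c("A", "B"),
                       data.frame(parent = "A", child = "B", strength = s))
    sc <- bbn_scenario(c(A = 4), network = net)
    unname(bbn_predict(net, sc)[[1]]$change["B"])
  }, numeric(1))
  expect_true(all(diff(changes) >= 0))
  expect_gt(changes[1], 0)
})

test_that("engine agrees with the naive oracle on random small networks", {
  for (seed in 1:25) {
    spec <- generator_spec(n_nodes = 4, density = 0.6, seed = seed,
                           n_manipulated = 2)
    net <- random_network(spec)
    sc <- random_scenario(net, spec)
    m <- matrix(NA_integer_, 4, 4, dimnames = list(net$nodes, net$nodes))
    m[cbind(net$edges$parent, net$edges$child)] <- net$edges$strength
    priors <- rep(0L, 4)
    names(priors) <- net$nodes
    priors[names(sc$priors)] <- sc$priors
    expect_equal(unname(bbn_predict(net, sc)[[1]]$change),
                 oracle_predict(m, unname(priors)), tolerance = 1e-12)
  }
})
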