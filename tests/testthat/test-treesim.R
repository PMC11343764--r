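test_that("a zero-rate configuration yields a single unbranched lineage", {
  cl <- simulate_quasse_tree(sim_config(constant_speciation(0),
                                        mu = 0, sigma2 = 0.01,
                                        max_time = 5, seed = 1))
  expect_equal(ape::Ntip(cl$tree), 1L)
  expect_equal(unname(max(ape::node.depth.edgelength(cl$tree))), 5,
               tolerance = 1e-9)
})

test_that("mean extant tip count matches the branching-process expectation", {
  # pure birth at rate 0.2 run to T = 8: E[N] = exp(0.2 * 8)
  n <- vapply(1:200, function(s) {
    cl <- simulate_quasse_tree(sim_config(constant_speciation(0.2), mu = 0,
                                          sigma2 = 0.01, max_time = 8,
                                          seed = s))
    ape::Ntip(cl$tree)
  }, 0L)
  expect_lt(abs(mean(n) - exp(1.6)), 3 * sd(n) / sqrt(200))
})

test_that("tip traits drift by phi * T on average", {
  m <- vapply(1:200, function(s) {
    cl <- simulate_quasse_tree(sim_config(constant_speciation(0.15), mu = 0,
                                          sigma2 = 0.01, phi = 0.5,
                                          max_time = 5, seed = s))
    mean(cl$tip_states)
  }, 0)
  expect_lt(abs(mean(m) - 2.5), 3 * sd(m) / sqrt(200))
})

test_that("trait increments have mean phi*t and variance sigma2*t", {
  # single non-branching lineage run for t = 2, many replicates
  inc <- vapply(1:1000, function(s) {
    cl <- simulate_quasse_tree(sim_config(constant_speciation(0), mu = 0,
                                          sigma2 = 0.04, phi = 0.3,
                                          root_state = 1, max_time = 2,
                                          dt = 0.05, seed = s))
    unname(cl$tip_states) - 1
  }, 0)
  expect_lt(abs(mean(inc) - 0.3 * 2), 3 * sd(inc) / sqrt(1000))
  v <- var(inc)
  se_v <- v * sqrt(2 / 999)
  expect_lt(abs(v - 0.04 * 2), 3 * se_v)
})

test_that("pruned trees are ultrametric, binary and labelled consistently", {
  cl <- simulate_quasse_tree_retry(
    sim_config(constant_speciation(0.3), mu = 0.1, sigma2 = 0.05,
               stop_n = 80, max_time = 100, seed = 7))
  expect_true(ape::is.ultrametric(cl$tree, tol = 1e-8))
  expect_true(ape::is.binary(cl$tree))
  expect_setequal(names(cl$tip_states), cl$tree$tip.label)
  expect_gt(cl$n_extinct, 0)
})

test_that("total extinction raises a clade-died error and retry recovers", {
  cfg <- sim_config(constant_speciation(0.01), mu = 2, sigma2 = 0.01,
                    max_time = 10, seed = 3)
  expect_error(simulate_quasse_tree(cfg), "died|retry")
  expect_s3_class(
    simulate_quasse_tree_retry(sim_config(constant_speciation(0.4),
                                          mu = 0.35, sigma2 = 0.01,
                                          max_time = 6, seed = 1),
                               max_tries = 50),
    "sim_clade")
})

test_that("tip subsampling is binomial, identity at rho = 1, deterministic", {
  cl <- simulate_quasse_tree(sim_config(constant_speciation(0.35), mu = 0,
                                        sigma2 = 0.02, stop_n = 1000,
                                        max_time = 100, seed = 2))
  expect_identical(subsample_tips(cl, 1), cl)
  n <- ape::Ntip(cl$tree)
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  for (s in 1:5) {
    kept <- ape::Ntip(subsample_tips(cl, 0.5, seed = s)$tree)
    expect_gte(kept, ci[1])
    expect_lte(kept, ci[2])
  }
  a <- subsample_tips(cl, 0.8, seed = 42)
  b <- subsample_tips(cl, 0.8, seed = 42)
  expect_identical(a$tree$tip.label, b$tree$tip.label)
  expect_true(ape::is.ultrametric(a$tree, tol = 1e-8))
})

test_that("sampling fraction inside the simulator thins extant tips", {
  cl <- simulate_quasse_tree(sim_config(constant_speciation(0.35), mu = 0,
                                        sigma2 = 0.02, stop_n = 400,
                                        max_time = 100, rho = 0.5,
                                        seed = 4))
  expect_lt(ape::Ntip(cl$tree), 320)  # well below the 400 simulated
  expect_true(ape::is.ultrametric(cl$tree, tol = 1e-8))
})
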