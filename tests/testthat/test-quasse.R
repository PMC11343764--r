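# Oracle checks for the spectral QuaSSE machinery.  The constant-rate
# special case factorizes exactly into a birth-death tree likelihood times
# a Brownian-motion REML trait likelihood, both available in closed form
# (bd_loglik, bm_reml_loglik); the grid code must reproduce their sum, and
# the tree component must be invariant to the trait inputs.

bd_component <- function(tree, states, lambda, mu, sigma2, phi = 0,
                         rho = 1, cond = FALSE, nx = 1024, dt = NULL) {
  h <- max(ape::node.depth.edgelength(tree))
  if (is.null(dt)) dt <- h / 1000
  g <- quasse_grid_auto(states, h, sigma2, nx)
  ll <- quasse_loglik(tree, states,
                      quasse_model(constant_speciation(lambda), mu = mu,
                                   sigma2 = sigma2, phi = phi, rho = rho),
                      grid = g,
                      control = list(root = "flat", condition_surv = cond,
                                     dt = dt))
  ll - bm_reml_loglik(tree, states, sigma2, tip_var = (2 * g$dx)^2)
}

test_that("speciation_eval applies the clamp and modal limits on the grid", {
  g <- quasse_grid(256, -1, 1)
  lam <- speciation_eval(modal_speciation(0.1, 0.4, 0, s2 = 1e8), g)
  expect_lt(max(abs(lam - 0.4)), 1e-6)
  lam2 <- speciation_eval(linear_speciation(0.1, -1), g)
  expect_true(all(lam2 >= 0))
  expect_error(modal_speciation(0.1, 0.4, 0, s2 = -1))
})

test_that("propagated E matches the constant-rate extinction probability", {
  g <- quasse_grid(512, -6, 6)
  mod <- quasse_model(constant_speciation(0.3), mu = 0.1, sigma2 = 0.05)
  res <- propagate_branch(dnorm(g$x, 0, 0.1), rep(0, g$nx), mod,
                          t_len = 5, grid = g, dt = 0.01)
  E_true <- divdrivers:::bd_E(5, 0.3, 0.1, 1)
  expect_lt(max(abs(res$E - E_true)), 1e-4)
})

test_that("vanishing diffusion leaves the shape of D unchanged", {
  g <- quasse_grid(512, -6, 6)
  D0 <- dnorm(g$x, 0, 0.3)
  mod <- quasse_model(constant_speciation(0.2), mu = 0.05, sigma2 = 1e-12)
  res <- propagate_branch(D0, rep(0.1, g$nx), mod, t_len = 2, grid = g,
                          dt = 0.05)
  tv <- sum(abs(res$D / sum(res$D) - D0 / sum(D0)))
  expect_lt(tv, 1e-6)
})

test_that("pure advection shifts the centroid of D by -phi * t", {
  g <- quasse_grid(512, -6, 6)
  mod <- quasse_model(constant_speciation(1e-9), mu = 0, sigma2 = 1e-6,
                      phi = 0.5)
  res <- propagate_branch(dnorm(g$x, 0, 0.3), rep(0, g$nx), mod,
                          t_len = 4, grid = g, dt = 0.02)
  centroid <- sum(g$x * res$D) / sum(res$D)
  expect_lt(abs(centroid - (-2)), g$dx)
})

test_that("an over-wide kernel is rejected with advice to enlarge the grid", {
  g <- quasse_grid(256, -1, 1)
  mod <- quasse_model(constant_speciation(0.2), mu = 0, sigma2 = 5)
  expect_error(propagate_branch(dnorm(g$x, 0, 0.1), rep(0, g$nx), mod,
                                t_len = 5, grid = g),
               "extent")
})

test_that("2-tip constant-rate likelihood matches the Yule closed form", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  states <- c(A = 0.1, B = -0.2)
  # bd_loglik itself equals the hand-derived Yule value log(lambda) - 2*lambda
  expect_equal(bd_loglik(tree, 1, 0, 1), log(1) - 2 * 1, tolerance = 1e-12)
  expect_lt(abs(bd_component(tree, states, 1, 0, 0.05) - (-2)), 1e-3)
  # and the tree component is invariant to sigma2
  expect_lt(abs(bd_component(tree, states, 1, 0, 0.2) - (-2)), 1e-3)
})

test_that("constant-rate likelihood factorizes on larger trees, with sampling
           and survival conditioning, invariant to trait inputs", {
  fx <- bm_fixture(30, height = 10, sigma2 = 0.04, seed = 5)
  for (rho in c(1, 0.6)) for (cond in c(FALSE, TRUE)) {
    got <- bd_component(fx$tree, fx$states, 0.25, 0.1, 0.04, phi = 0.05,
                        rho = rho, cond = cond)
    want <- bd_loglik(fx$tree, 0.25, 0.1, rho, condition_surv = cond)
    expect_lt(abs(got - want), 1e-3)
  }
  # state independence: shift states, change sigma2 and phi
  base <- bd_component(fx$tree, fx$states, 0.25, 0.1, 0.04)
  expect_lt(abs(bd_component(fx$tree, fx$states + 3, 0.25, 0.1, 0.04) - base),
            1e-3)
  expect_lt(abs(bd_component(fx$tree, fx$states, 0.25, 0.1, 0.09,
                             phi = -0.2) - base), 1e-3)
})

test_that("translating tip states and xmid together leaves lnL unchanged", {
  fx <- bm_fixture(20, height = 8, sigma2 = 0.05, seed = 9)
  mk <- function(shift) {
    states <- fx$states + shift
    g <- quasse_grid(1024, min(states) - 4, max(states) + 4)
    quasse_loglik(fx$tree, states,
                  quasse_model(modal_speciation(0.1, 0.4, 0.3 + shift,
                                                s2 = 0.5),
                               mu = 0.05, sigma2 = 0.05, phi = 0.1),
                  grid = g, control = list(dt = 8 / 500))
  }
  expect_lt(abs(mk(0) - mk(2.5)), 1e-6)
})

test_that("likelihood is stable under grid refinement and step halving", {
  fx <- bm_fixture(50, height = 12, sigma2 = 0.05, seed = 3)
  mod <- quasse_model(modal_speciation(0.15, 0.45, median(fx$states),
                                       s2 = 0.4),
                      mu = 0.05, sigma2 = 0.05)
  ll <- function(nx, dtf) {
    g <- quasse_grid_auto(fx$states, 12, 0.05, nx)
    quasse_loglik(fx$tree, fx$states, mod, grid = g,
                  control = list(dt = 12 * dtf))
  }
  expect_lt(abs(ll(1024, 1 / 1000) - ll(2048, 1 / 1000)), 0.05)
  expect_lt(abs(ll(1024, 1 / 100) - ll(1024, 1 / 1000)), 0.05)
})

test_that("degenerate inputs are rejected", {
  fx <- bm_fixture(10, height = 5, sigma2 = 0.05, seed = 2)
  mod <- quasse_model(constant_speciation(0.3), mu = 0, sigma2 = 0.05)
  bad_tree <- fx$tree
  bad_tree$edge.length[1] <- bad_tree$edge.length[1] * 2
  expect_error(quasse_loglik(bad_tree, fx$states, mod), "ultrametric")
  g <- quasse_grid(256, max(fx$states) + 1, max(fx$states) + 3)
  expect_error(quasse_loglik(fx$tree, fx$states, mod, grid = g),
               "outside|grid")
})

test_that("drift sign convention round-trips through the simulator", {
  # with a state-dependent lambda, data generated under phi > 0 must be
  # far more likely under the generating sign than under its negation
  # (under constant lambda, drift is unidentifiable on an ultrametric
  # tree: the factorized likelihood is drift-invariant, checked above)
  fn <- modal_speciation(0.1, 0.5, xmid = 2, s2 = 1)
  cl <- suppressWarnings(simulate_quasse_tree_retry(
    sim_config(fn, mu = 0.02, sigma2 = 0.1, phi = 0.3, root_state = 0,
               stop_n = 100, max_time = 40, seed = 21)))
  h <- max(ape::node.depth.edgelength(cl$tree))
  g <- quasse_grid(1024,
                   min(cl$tip_states) - 0.3 * h - 3,
                   max(cl$tip_states) + 3)
  ll <- function(phi)
    quasse_loglik(cl$tree, cl$tip_states,
                  quasse_model(fn, mu = 0.02, sigma2 = 0.1, phi = phi),
                  grid = g, control = list(dt = h / 200))
  expect_gt(ll(0.3) - ll(-0.3), 10)
})
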