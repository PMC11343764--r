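# Shared fixtures: all built in code, deterministic under fixed seeds.

# booster parameters representative of what the two-stage tuner returns at
# desk scale; used where the test exercises the bootstrap protocol rather
# than the tuner itself
quick_params <- function(depth = 3L, nrounds = 80L) {
  structure(list(eta = 0.15, max_depth = depth, subsample = 0.8,
                 colsample_bytree = 0.8, min_child_weight = 1,
                 nrounds = nrounds),
            class = "tuned_params")
}

# small ultrametric tree with BM-consistent tip states (the regime the
# grid likelihood is designed for)
bm_fixture <- function(ntip, height, sigma2, seed = 1) {
  set.seed(seed)
  tree <- ape::rcoal(ntip)
  tree$edge.length <- tree$edge.length /
    max(ape::node.depth.edgelength(tree)) * height
  states <- setNames(
    as.vector(ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2))),
    tree$tip.label)
  list(tree = tree, states = states)
}

# cheap settings for optimizer-backed tests on small trees
fast_settings <- function(...) {
  utils::modifyList(list(nx = 256L, dt_frac = 1 / 50, nstart = 1L,
                         seed = 1L, rel_tol = 1e-7), list(...))
}

expect_close <- function(x, y, tol) expect_lt(abs(x - y), tol)
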