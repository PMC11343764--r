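# Closed-form likelihoods for the constant-rate special case.  These use
# only analytic birth-death formulas and Felsenstein pruning -- no trait
# grid, no numerical propagation -- and therefore serve as an independent
# reference for the spectral QuaSSE machinery, which must agree with them
# when lambda does not depend on the trait.

bd_E <- function(t, lambda, mu, rho) {
  # extinction/non-sampling probability of a lineage alive t Myr ago
  E0 <- 1 - rho
  g0 <- 1 - E0
  r <- lambda - mu
  if (abs(r) > 1e-12 * (lambda + mu + 1)) {
    A <- exp(r * t)
    cc <- mu - lambda * E0
    (mu * g0 * A - cc) / (lambda * g0 * A - cc)
  } else {
    1 - g0 / (1 + lambda * t * g0)
  }
}

#' Constant-rate birth-death log-likelihood of an ultrametric tree
#'
#' Nee-type closed form with incomplete sampling: each sampled tip
#' contributes `rho`, each internal node a speciation factor `lambda`, and
#' each branch the analytic per-lineage survival factor
#' `exp(-(lambda - mu) t) ((1 - E(t_old)) / (1 - E(t_young)))^2` of the
#' linear birth-death process with `E(0) = 1 - rho`.
#'
#' @param tree Ultrametric `phylo`.
#' @param lambda,mu Speciation and extinction rates per Myr.
#' @param rho Sampling fraction in `(0, 1]`.
#' @param condition_surv Condition on survival of the two lineages
#'   descending from the root (divides by `lambda (1 - E(T))^2`).
#' @return Log-likelihood (scalar).
#' @export
bd_loglik <- function(tree, lambda, mu, rho = 1, condition_surv = FALSE) {
  stopifnot(inherits(tree, "phylo"), lambda > 0, mu >= 0, rho > 0, rho <= 1)
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth)
  age <- height - depth                    # 0 at the tips
  r <- lambda - mu
  lnE <- function(t) log1p(-bd_E(t, lambda, mu, rho))  # log(1 - E(t))
  ll <- ntip * log(rho) + (ntip - 1) * log(lambda)
  for (i in seq_len(nrow(tree$edge))) {
    t_young <- age[tree$edge[i, 2L]]
    t_old <- age[tree$edge[i, 1L]]
    ll <- ll - r * (t_old - t_young) + 2 * (lnE(t_old) - lnE(t_young))
  }
  if (condition_surv)
    ll <- ll - log(lambda) - 2 * lnE(height)
  ll
}

#' Brownian-motion REML log-likelihood of tip states on a tree
#'
#' Felsenstein pruning over independent contrasts, with optional extra
#' per-tip variance (e.g. the numerical mollifier applied to tip states in
#' the grid likelihood).  The contrast likelihood corresponds to a flat
#' (improper) prior on the root state; on an ultrametric tree it is
#' invariant to directional drift, which shifts all tips equally.
#'
#' @param tree Rooted binary `phylo`.
#' @param states Named numeric tip states.
#' @param sigma2 Brownian variance per Myr.
#' @param tip_var Extra observation variance added at each tip.
#' @return REML log-likelihood (scalar).
#' @export
bm_reml_loglik <- function(tree, states, sigma2, tip_var = 0) {
  stopifnot(inherits(tree, "phylo"), sigma2 > 0, tip_var >= 0)
  ntip <- length(tree$tip.label)
  states <- states[tree$tip.label]
  stopifnot(all(is.finite(states)))
  tr <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + tr$Nnode
  xhat <- c(unname(states), rep(NA_real_, tr$Nnode))
  vhat <- c(rep(tip_var, ntip), rep(NA_real_, tr$Nnode))
  ll <- 0
  # postorder edge sweep: children always precede their parent
  seen <- vector("list", nn)
  for (i in seq_len(nrow(tr$edge))) {
    child <- tr$edge[i, 2L]
    parent <- tr$edge[i, 1L]
    v <- vhat[child] + sigma2 * tr$edge.length[i]
    entry <- list(x = xhat[child], v = v)
    if (is.null(seen[[parent]])) {
      seen[[parent]] <- entry
    } else {
      prev <- seen[[parent]]
      V <- prev$v + entry$v
      ll <- ll + dnorm(prev$x - entry$x, 0, sqrt(V), log = TRUE)
      seen[[parent]] <- list(x = (prev$x * entry$v + entry$x * prev$v) / V,
                             v = prev$v * entry$v / V)
    }
    xhat[parent] <- seen[[parent]]$x
    vhat[parent] <- seen[[parent]]$v
  }
  ll
}
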