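#' Configuration for forward trait-dependent birth-death simulation
#'
#' Describes the generating process: a lineage's trait follows Brownian
#' motion with drift `phi` (trait units per Myr, positive = increases
#' toward the present) and variance `sigma2` per Myr; at each Euler step
#' `dt` the lineage speciates with probability `lambda(x) dt` and goes
#' extinct with probability `mu dt`.  Daughters inherit the parent trait
#' exactly (anagenetic change only).
#'
#' @param speciation A [speciation_fn] giving `lambda(x)`.
#' @param mu Extinction rate `>= 0` per Myr.
#' @param sigma2 Trait diffusion variance per Myr, `> 0`.
#' @param phi Trait drift per Myr (forward-time sign).
#' @param root_state Trait value of the founding lineage.
#' @param stop_n Stop when this many lineages are extant (ultrametric
#'   height = the time this is first reached); `NULL` to run to `max_time`.
#' @param max_time Maximum simulation time (Myr).
#' @param rho Sampling fraction in `(0, 1]`; extant tips are retained
#'   independently with this probability after the simulation.
#' @param dt Euler step; default `min(0.001 * max_time, 0.01 / max rate)`.
#' @param seed Integer seed; all randomness in the simulation flows from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(speciation, mu = 0, sigma2 = 0.01, phi = 0,
                       root_state = 0, stop_n = NULL, max_time = NULL,
                       rho = 1, dt = NULL, seed = 1L) {
  stopifnot(inherits(speciation, "speciation_fn"), mu >= 0, sigma2 > 0,
            is.finite(phi), rho > 0, rho <= 1)
  if (is.null(stop_n) && is.null(max_time))
    stop("provide stop_n and/or max_time")
  if (!is.null(stop_n)) stopifnot(stop_n >= 1)
  if (!is.null(max_time)) stopifnot(max_time > 0)
  if (!is.null(dt)) stopifnot(dt > 0)
  structure(list(speciation = speciation, mu = mu, sigma2 = sigma2,
                 phi = phi, root_state = root_state, stop_n = stop_n,
                 max_time = max_time, rho = rho, dt = dt,
                 seed = as.integer(seed)),
            class = "sim_config")
}

default_sim_dt <- function(config) {
  # scale of trait excursion over a generous horizon, to bound max(lambda)
  horizon <- if (!is.null(config$max_time)) config$max_time else 100
  spread <- abs(config$phi) * horizon + 6 * sqrt(config$sigma2 * horizon)
  xr <- config$root_state + c(-spread, spread)
  maxlam <- max(eval_speciation(config$speciation, seq(xr[1], xr[2],
                                                       length.out = 512)))
  dt <- 0.01 / max(maxlam + config$mu, 1e-6)
  if (!is.null(config$max_time)) dt <- min(dt, 0.001 * config$max_time)
  min(dt, 1)
}

#' Simulate a trait-dependent birth-death tree
#'
#' Forward discrete-time simulation under a [sim_config()].  Extinct
#' lineages are pruned; extant tips are subsampled with probability `rho`;
#' the returned tree is extant-only and ultrametric.
#'
#' @param config A `sim_config`.
#' @return A `sim_clade`: list with `tree` (`phylo`), `tip_states` (named
#'   numeric), `true_config`, `n_extinct`, `seed` and `reached_target`
#'   (FALSE when `max_time` elapsed before `stop_n` was reached, with a
#'   warning).
#' @export
simulate_quasse_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dt <- if (is.null(config$dt)) default_sim_dt(config) else config$dt
  max_steps <- if (!is.null(config$max_time))
    ceiling(config$max_time / dt) else ceiling(1e4 / dt)
  cap <- 4096L
  parent <- integer(cap); t_birth <- numeric(cap); t_end <- numeric(cap)
  status <- integer(cap)   # 0 alive, 1 extinct, 2 split
  state <- numeric(cap)
  parent[1] <- 0L; t_birth[1] <- 0; state[1] <- config$root_state
  n_lin <- 1L
  alive <- 1L
  t <- 0
  reached <- is.null(config$stop_n)
  sqdt <- sqrt(config$sigma2 * dt)

  for (step in seq_len(max_steps)) {
    na <- length(alive)
    if (na == 0L) break
    if (!is.null(config$stop_n) && na >= config$stop_n) {
      # run on for half a step (no further events) so lineages born at the
      # stopping event get positive pendant edges
      t <- t + dt / 2
      reached <- TRUE
      break
    }
    t <- t + dt
    state[alive] <- state[alive] + config$phi * dt + sqdt * rnorm(na)
    lam <- eval_speciation(config$speciation, state[alive])
    u <- runif(na)
    split <- u < lam * dt
    dead <- !split & (u < lam * dt + config$mu * dt)
    ids_dead <- alive[dead]
    if (any(split)) {
      ids <- alive[split]
      nnew <- 2L * length(ids)
      while (n_lin + nnew > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(t_birth) <- cap; length(t_end) <- cap
        length(status) <- cap; length(state) <- cap
      }
      new_idx <- n_lin + seq_len(nnew)
      parent[new_idx] <- rep(ids, each = 2L)
      t_birth[new_idx] <- t
      state[new_idx] <- rep(state[ids], each = 2L)
      status[new_idx] <- 0L
      t_end[ids] <- t; status[ids] <- 2L
      n_lin <- n_lin + nnew
      alive <- c(alive[!(split | dead)], new_idx)
    } else {
      alive <- alive[!dead]
    }
    if (length(ids_dead)) {
      status[ids_dead] <- 1L
      t_end[ids_dead] <- t
    }
  }
  if (length(alive) == 0L)
    stop("clade died before reaching the stopping condition; retry with ",
         "another seed")
  if (!reached)
    warning("max_time reached before stop_n extant lineages")
  t_end[alive] <- t
  status[alive] <- 0L

  keep <- seq_len(n_lin)
  lin <- list(parent = parent[keep], t_birth = t_birth[keep],
              t_end = t_end[keep], status = status[keep],
              state = state[keep])
  extant <- which(lin$status == 0L)
  n_extinct <- sum(lin$status == 1L)

  # sampling-fraction subsampling
  if (config$rho < 1) {
    kept <- extant[runif(length(extant)) < config$rho]
    if (length(kept) == 0L)
      stop("sampling fraction removed every extant tip; retry")
    drop <- setdiff(extant, kept)
    lin$status[drop] <- 1L   # treat unsampled as pruned
    extant <- kept
  }
  clade_from_lineages(lin, extant, config, n_extinct)
}

# Build an extant-only ultrametric phylo from lineage records by writing
# Newick for the full tree and pruning non-extant tips.
clade_from_lineages <- function(lin, extant, config, n_extinct) {
  n_lin <- length(lin$parent)
  if (length(extant) == 1L) {
    # unbranched survivor: collapse its whole root-to-tip path into one edge
    tree <- ape::read.tree(text = sprintf("(t%d:%.10g);", extant,
                                          lin$t_end[extant]))
  } else {
    children <- split(seq_len(n_lin), lin$parent[seq_len(n_lin)])
    lab <- function(i) sprintf("t%d", i)
    nw <- function(i) {
      len <- lin$t_end[i] - lin$t_birth[i]
      if (lin$status[i] == 2L) {
        ch <- children[[as.character(i)]]
        sprintf("(%s,%s):%.10g", nw(ch[1]), nw(ch[2]), len)
      } else sprintf("%s:%.10g", lab(i), len)
    }
    tree <- ape::read.tree(text = paste0(nw(1L), ";"))
    tips_keep <- sprintf("t%d", extant)
    if (length(tips_keep) < ape::Ntip(tree))
      tree <- ape::drop.tip(tree, setdiff(tree$tip.label, tips_keep))
    tree$root.edge <- NULL
  }
  states <- setNames(lin$state[extant], sprintf("t%d", extant))
  states <- states[tree$tip.label]
  structure(list(tree = tree, tip_states = states, true_config = config,
                 n_extinct = n_extinct, seed = config$seed,
                 reached_target = TRUE),
            class = "sim_clade")
}

#' Simulate with retries over successive seeds
#'
#' Re-runs [simulate_quasse_tree()] with `seed, seed + 1000, ...` until a
#' clade survives (total extinction raises an error in the single-shot
#' simulator).
#'
#' @inheritParams simulate_quasse_tree
#' @param max_tries Number of seeds to attempt.
#' @return A `sim_clade`.
#' @export
simulate_quasse_tree_retry <- function(config, max_tries = 25L) {
  base <- config$seed
  for (k in seq_len(max_tries)) {
    config$seed <- as.integer(base + (k - 1L) * 1000L)
    res <- tryCatch(simulate_quasse_tree(config), error = function(e) e)
    if (!inherits(res, "error")) return(res)
  }
  stop("no surviving clade in ", max_tries, " attempts: ",
       conditionMessage(res))
}

#' Randomly subsample the tips of a simulated clade
#'
#' Each tip is retained independently with probability `rho`; the tree is
#' pruned to the retained tips (ultrametricity is preserved by pruning).
#'
#' @param clade A `sim_clade`.
#' @param rho Retention probability in `(0, 1]`.
#' @param seed Integer seed.
#' @return A `sim_clade` with the pruned tree and matching `tip_states`.
#' @export
subsample_tips <- function(clade, rho, seed = 1L) {
  stopifnot(inherits(clade, "sim_clade"), rho > 0, rho <= 1)
  if (rho == 1) return(clade)
  set.seed(seed)
  tips <- clade$tree$tip.label
  keep <- tips[runif(length(tips)) < rho]
  if (length(keep) == 0L) stop("subsampling dropped every tip")
  if (length(keep) < 2L) stop("fewer than two tips retained")
  tree <- ape::drop.tip(clade$tree, setdiff(tips, keep))
  clade$tree <- tree
  clade$tip_states <- clade$tip_states[tree$tip.label]
  clade
}

#' @export
print.sim_clade <- function(x, ...) {
  cat("<sim_clade> ", ape::Ntip(x$tree), " extant tips, ",
      x$n_extinct, " extinct pruned, height ",
      signif(max(ape::node.depth.edgelength(x$tree)), 4), " Myr\n", sep = "")
  invisible(x)
}
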