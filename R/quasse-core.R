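#' Trait grid for QuaSSE likelihood computation
#'
#' The D (data) and E (extinction) functions are discretized on a regular
#' grid of `nx` points (a power of two, for the spectral convolution step).
#' The extent must cover every tip state with a generous margin so that
#' probability mass diffusing beyond the observed range is representable;
#' [quasse_grid_auto()] builds one from the data with margin
#' `5 * sqrt(sigma2_max * tree_height)`.
#'
#' @param nx Number of grid points; power of two, `>= 256`.
#' @param from,to Grid extent (trait units).
#' @return A `quasse_grid` object with fields `nx`, `from`, `to`, `dx`, `x`.
#' @export
quasse_grid <- function(nx = 1024L, from, to) {
  nx <- as.integer(nx)
  if (nx < 256L || bitwAnd(nx, nx - 1L) != 0L)
    stop("nx must be a power of two >= 256, got ", nx)
  if (!is.finite(from) || !is.finite(to) || to <= from)
    stop("invalid grid extent [", from, ", ", to, "]")
  dx <- (to - from) / nx
  structure(list(nx = nx, from = from, to = to, dx = dx,
                 x = from + (seq_len(nx) - 1) * dx),
            class = "quasse_grid")
}

#' @param states Named numeric vector of tip states.
#' @param tree_height Root-to-tip depth of the (ultrametric) tree.
#' @param sigma2_max Largest diffusion variance the grid must support.
#' @rdname quasse_grid
#' @export
quasse_grid_auto <- function(states, tree_height, sigma2_max, nx = 1024L) {
  stopifnot(length(states) > 0, all(is.finite(states)),
            tree_height > 0, sigma2_max > 0)
  margin <- 5 * sqrt(sigma2_max * tree_height) +
    0.05 * max(diff(range(states)), 1e-3)
  quasse_grid(nx, min(states) - margin, max(states) + margin)
}

#' Specify a QuaSSE model
#'
#' Bundles a trait-dependent speciation function \eqn{\lambda(x)} with the
#' constant extinction rate \eqn{\mu}, Brownian diffusion variance
#' \eqn{\sigma^2}, directional drift \eqn{\phi} (trait units per Myr,
#' positive = trait tends to increase toward the present) and sampling
#' fraction \eqn{\rho} (probability that an extant species is included in
#' the tree).
#'
#' @param speciation A [speciation_fn].
#' @param mu Extinction rate, `>= 0`.
#' @param sigma2 Diffusion variance, `> 0`.
#' @param phi Drift, default 0.
#' @param rho Sampling fraction in `(0, 1]`.
#' @return A `quasse_model` object.
#' @export
quasse_model <- function(speciation, mu, sigma2, phi = 0, rho = 1) {
  stopifnot(inherits(speciation, "speciation_fn"),
            mu >= 0, sigma2 > 0, rho > 0, rho <= 1, is.finite(phi))
  structure(list(speciation = speciation, mu = mu, sigma2 = sigma2,
                 phi = phi, rho = rho),
            class = "quasse_model")
}

#' Evaluate a model's speciation function on a grid
#'
#' @param fn A [speciation_fn].
#' @param grid A [quasse_grid].
#' @return Numeric vector of rates over `grid$x`, all `>= 0`.
#' @export
speciation_eval <- function(fn, grid) {
  stopifnot(inherits(grid, "quasse_grid"))
  lam <- eval_speciation(fn, grid$x)
  stopifnot(all(lam >= 0))
  lam
}

guard_cells <- function(model, dt, grid) {
  nd <- max(4, ceiling((8 * sqrt(model$sigma2 * dt) +
                          abs(model$phi) * dt) / grid$dx))
  if (nd > grid$nx / 8)
    stop("diffusion kernel too wide for the grid; enlarge the grid extent ",
         "or reduce sigma2/dt (needed guard band ", nd, " of ", grid$nx,
         " cells)")
  as.integer(nd)
}

#' Propagate D and E functions backward along a branch
#'
#' Advances the QuaSSE partial differential equations backward in time by
#' `t_len` using symmetric operator splitting: an exact pointwise
#' birth-death reaction update alternated with spectral Gaussian
#' advection-diffusion (variance `sigma2*dt`, centroid shift `-phi*dt` per
#' step).
#'
#' @param D,E Numeric vectors on `grid$x`.
#' @param model A [quasse_model].
#' @param t_len Branch length (Myr), `> 0`.
#' @param grid A [quasse_grid].
#' @param dt Maximum step size; defaults to `t_len / 20`.
#' @return List with updated `D`, `E` and `log_scale` (log of any
#'   renormalization applied to D in transit).
#' @export
propagate_branch <- function(D, E, model, t_len, grid, dt = t_len / 20) {
  stopifnot(inherits(model, "quasse_model"), inherits(grid, "quasse_grid"),
            length(D) == grid$nx, length(E) == grid$nx, t_len > 0)
  if (6 * sqrt(model$sigma2 * t_len) > (grid$to - grid$from))
    stop("total diffusion exceeds the grid extent; enlarge the grid")
  lam <- speciation_eval(model$speciation, grid)
  nd <- guard_cells(model, min(dt, t_len), grid)
  quasse_propagate_cpp(D, E, lam, model$mu, t_len, dt,
                       model$sigma2, model$phi, grid$dx, nd)
}

#' QuaSSE log-likelihood of a tree and tip states
#'
#' Computes the joint log-likelihood of an ultrametric phylogeny and its
#' continuous tip states under a trait-dependent speciation model.  Tips
#' are initialized as `D(x) = rho * N(x; state, tip_sd^2)` (a narrow
#' numerical mollifier integrating to `rho`) and `E(x) = 1 - rho`; branches
#' are propagated backward with [propagate_branch()]; at each internal node
#' `D <- D_left * D_right * lambda(x)`.  At the root the likelihood is
#' `integral D(x) w(x) dx` with `w = D / integral D` (`root = "obs"`), or
#' `integral D(x) dx` (`root = "flat"`).  With `condition_surv = TRUE`
#' (default) the result is divided by
#' `integral w(x) lambda(x) (1 - E(x))^2 dx`, conditioning on survival of
#' the two root lineages.
#'
#' @param tree An ultrametric `phylo` tree.
#' @param states Named numeric vector of tip states covering all tips.
#' @param model A [quasse_model].
#' @param grid A [quasse_grid]; built automatically when `NULL`.
#' @param control List: `dt` (default tree height / 1000), `tip_sd`
#'   (default `2 * dx`), `root` ("obs" or "flat"), `condition_surv`
#'   (default TRUE), `nx` (used when `grid` is NULL).
#' @return Log-likelihood (scalar); `-Inf` when the computation underflows.
#' @export
quasse_loglik <- function(tree, states, model, grid = NULL, control = list()) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "quasse_model"))
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    stop("tree must be ultrametric")
  ntip <- length(tree$tip.label)
  if (is.null(names(states)) || !all(tree$tip.label %in% names(states)))
    stop("states must be named and cover every tip")
  states <- states[tree$tip.label]
  if (any(!is.finite(states))) stop("non-finite tip states")

  height <- max(ape::node.depth.edgelength(tree))
  con <- list(dt = height / 1000, tip_sd = NULL, root = "obs",
              condition_surv = TRUE, nx = 1024L)
  con[names(control)] <- control
  if (is.null(grid))
    grid <- quasse_grid_auto(states, height, model$sigma2, con$nx)
  tip_sd <- if (is.null(con$tip_sd)) 2 * grid$dx else con$tip_sd
  if (min(states) < grid$from + 4 * grid$dx ||
      max(states) > grid$to - 4 * grid$dx)
    stop("tip state outside the trait grid; enlarge the extent")

  lam <- speciation_eval(model$speciation, grid)
  nd <- guard_cells(model, con$dt, grid)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- tr$Nnode
  Ds <- vector("list", ntip + nnode)
  Es <- vector("list", ntip + nnode)
  logcomp <- 0
  E0 <- rep(1 - model$rho, grid$nx)

  for (i in seq_len(nrow(tr$edge))) {
    child <- tr$edge[i, 2L]
    parent <- tr$edge[i, 1L]
    len <- tr$edge.length[i]
    if (child <= ntip) {
      D <- model$rho * dnorm(grid$x, states[child], tip_sd)
      E <- E0
    } else {
      D <- Ds[[child]]
      E <- Es[[child]]
      Ds[child] <- list(NULL)
      Es[child] <- list(NULL)
    }
    if (len > 0) {
      res <- quasse_propagate_cpp(D, E, lam, model$mu, len, con$dt,
                                  model$sigma2, model$phi, grid$dx, nd)
      q <- sum(res$D) * grid$dx
      if (!is.finite(q) || q <= 0) return(-Inf)
      D <- res$D / q
      E <- res$E
      logcomp <- logcomp + log(q) + res$log_scale
    }
    if (is.null(Ds[[parent]])) {
      Ds[[parent]] <- D
      Es[[parent]] <- E
    } else {
      Ds[[parent]] <- Ds[[parent]] * D * lam
      Es[[parent]] <- (Es[[parent]] + E) / 2
    }
  }

  root <- ntip + 1L
  Droot <- Ds[[root]]
  Eroot <- Es[[root]]
  tot <- sum(Droot) * grid$dx
  if (!is.finite(tot) || tot <= 0) return(-Inf)
  lroot <- switch(con$root,
    obs  = sum(Droot^2) * grid$dx / tot,
    flat = tot,
    stop("unknown root treatment: ", con$root)
  )
  if (con$condition_surv) {
    w <- Droot / tot
    surv <- sum(w * lam * (1 - Eroot)^2) * grid$dx
    if (!is.finite(surv) || surv <= 0) return(-Inf)
    lroot <- lroot / surv
  }
  log(lroot) + logcomp
}
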