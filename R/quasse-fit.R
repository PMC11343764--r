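# Maximum-likelihood fitting of trait-dependent speciation models and the
# seven-model AIC comparison (constant; linear, sigmoid, modal, each with
# and without drift).  All seven models share one trait grid and one step
# size so their likelihoods are directly comparable.

quasse_forms <- c("constant", "linear", "sigmoid", "modal")

par_names <- function(form, with_drift) {
  base <- switch(form,
    constant = c("y0", "mu", "sigma2"),
    linear   = c("intercept", "slope", "mu", "sigma2"),
    sigmoid  = c("y0", "y1", "xmid", "r", "mu", "sigma2"),
    modal    = c("y0", "y1", "xmid", "s2", "mu", "sigma2"))
  if (with_drift) c(base, "phi") else base
}

LOG_PARS <- c("y0", "y1", "mu", "sigma2", "s2", "r")

model_from_pars <- function(form, pars, rho) {
  fn <- switch(form,
    constant = constant_speciation(pars[["y0"]]),
    linear   = linear_speciation(pars[["intercept"]], pars[["slope"]]),
    sigmoid  = sigmoid_speciation(pars[["y0"]], pars[["y1"]],
                                  pars[["xmid"]], pars[["r"]]),
    modal    = modal_speciation(pars[["y0"]], pars[["y1"]],
                                pars[["xmid"]], pars[["s2"]]))
  quasse_model(fn, mu = pars[["mu"]], sigma2 = pars[["sigma2"]],
               phi = if ("phi" %in% names(pars)) pars[["phi"]] else 0,
               rho = rho)
}

to_opt <- function(pars) {
  for (nm in intersect(names(pars), LOG_PARS)) pars[nm] <- log(pars[nm])
  pars
}
from_opt <- function(pars) {
  for (nm in intersect(names(pars), LOG_PARS)) pars[nm] <- exp(pars[nm])
  pars
}

default_starts <- function(tree, states, height) {
  L <- sum(tree$edge.length)
  lam <- max((length(tree$tip.label) - 2) / L, 0.01)
  v <- max(var(states), 1e-8)
  list(lam = lam, mu = lam / 5, sigma2 = max(v / height, 1e-6),
       xmid = median(states), s2 = v, r = 2 / sqrt(v),
       sd_states = sqrt(v))
}

par_bounds <- function(nms, grid, sigma2_max, lam_scale) {
  lower <- c(y0 = 1e-6, y1 = 1e-6, mu = 1e-8, sigma2 = 1e-8, s2 = 1e-6,
             r = 1e-3, xmid = grid$from, phi = -5,
             intercept = -20 * lam_scale, slope = -50)
  upper <- c(y0 = 20, y1 = 20, mu = 20, sigma2 = sigma2_max, s2 = 1e4,
             r = 100, xmid = grid$to, phi = 5,
             intercept = 20 * lam_scale, slope = 50)
  list(lower = lower[nms], upper = upper[nms])
}

#' Fit one trait-dependent speciation model by maximum likelihood
#'
#' Bounded local optimization (on a log scale for positive parameters)
#' from a data-driven default start — speciation level from tip count and
#' total branch length, diffusion from trait variance over tree height —
#' plus jittered restarts; the best finite optimum is returned.
#'
#' @param tree Ultrametric `phylo`.
#' @param states Named tip states.
#' @param form One of `"constant"`, `"linear"`, `"sigmoid"`, `"modal"`.
#' @param with_drift Include the drift parameter `phi` (forced off for the
#'   constant model).
#' @param rho Sampling fraction.
#' @param settings List: `nx` (1024), `dt_frac` (step = height * dt_frac,
#'   default 1/200), `nstart` (default 5: one default start + 4 jittered),
#'   `seed`, `grid`, `sigma2_max`, `start` (named overrides),
#'   `condition_surv`, `root`, `eval_max`, `rel_tol`.
#' @return A `quasse_fit`: `pars` (natural scale), `model`, `lnL`, `k`,
#'   `AIC`, `converged`, `form`, `with_drift`, `start`.
#' @export
fit_model <- function(tree, states, form = "constant", with_drift = FALSE,
                      rho = 1, settings = list()) {
  form <- match.arg(form, quasse_forms)
  if (form == "constant") with_drift <- FALSE
  states <- states[tree$tip.label]
  stopifnot(all(is.finite(states)))
  height <- max(ape::node.depth.edgelength(tree))
  s <- list(nx = 1024L, dt_frac = 1 / 200, nstart = 5L, seed = 1L,
            grid = NULL, sigma2_max = NULL, start = list(),
            condition_surv = TRUE, root = "obs",
            eval_max = 500L, iter_max = 300L, rel_tol = 1e-8)
  s[names(settings)] <- settings

  ds <- default_starts(tree, states, height)
  if (is.null(s$sigma2_max)) s$sigma2_max <- max(4 * ds$sigma2, 1e-6)
  grid <- if (is.null(s$grid))
    quasse_grid_auto(states, height, s$sigma2_max, s$nx) else s$grid
  control <- list(dt = height * s$dt_frac, root = s$root,
                  condition_surv = s$condition_surv)

  nms <- par_names(form, with_drift)
  start <- c(y0 = ds$lam, y1 = 1.5 * ds$lam, xmid = ds$xmid,
             s2 = ds$s2, r = ds$r, mu = ds$mu, sigma2 = ds$sigma2,
             intercept = ds$lam, slope = 0, phi = 0)[nms]
  for (nm in intersect(names(s$start), nms)) start[nm] <- s$start[[nm]]
  bounds <- par_bounds(nms, grid, s$sigma2_max, ds$lam)
  clamp_start <- function(p) pmin(pmax(p, bounds$lower * 1.0000001),
                                  bounds$upper * 0.9999999)
  start <- clamp_start(start)
  lower_t <- to_opt(bounds$lower)
  upper_t <- to_opt(bounds$upper)

  negll <- function(pt) {
    pars <- from_opt(setNames(pt, nms))
    if (form == "modal" && pars[["s2"]] <= 0) return(1e10)
    val <- tryCatch(
      quasse_loglik(tree, states, model_from_pars(form, pars, rho),
                    grid = grid, control = control),
      error = function(e) -Inf)
    if (!is.finite(val)) 1e10 else -val
  }

  # the midpoint start dominates whether the optimizer finds a peaked
  # solution at all (a mis-placed hump collapses to the flat constant
  # optimum); screen a few data-quantile candidates, and widths for the
  # modal form, by single likelihood evaluations before optimizing
  if (form %in% c("sigmoid", "modal") && !("xmid" %in% names(s$start))) {
    cand_x <- unname(quantile(states, c(0.1, 0.3, 0.5, 0.7, 0.9)))
    cand_s2 <- if (form == "modal") ds$s2 * c(0.25, 1) else NA
    best_val <- Inf
    for (cx in cand_x) for (cs in cand_s2) {
      cand <- start
      cand["xmid"] <- cx
      if (form == "modal" && !("s2" %in% names(s$start))) cand["s2"] <- cs
      cand <- clamp_start(cand)
      v <- negll(to_opt(cand))
      if (v < best_val) { best_val <- v; start <- cand }
    }
  }

  set.seed(s$seed)
  jitter_sd <- c(y0 = 0.3, y1 = 0.3, mu = 0.5, sigma2 = 0.4, s2 = 0.5,
                 r = 0.4, xmid = 0.5 * ds$sd_states, phi = 0.05,
                 intercept = 0.3 * ds$lam,
                 slope = 0.5 * ds$lam / ds$sd_states)[nms]
  best <- NULL
  diag <- character()
  for (k in seq_len(s$nstart)) {
    st <- to_opt(start)
    if (k > 1) st <- st + rnorm(length(st), 0, jitter_sd)
    st <- pmin(pmax(st, lower_t), upper_t)
    res <- tryCatch(
      nlminb(st, negll, lower = lower_t, upper = upper_t,
             control = list(eval.max = s$eval_max, iter.max = s$iter_max,
                            rel.tol = s$rel_tol)),
      error = function(e) e)
    if (inherits(res, "error")) { diag <- c(diag, conditionMessage(res)); next }
    if (res$objective >= 1e10) { diag <- c(diag, "no finite likelihood"); next }
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    stop("no finite likelihood at any start for ", form,
         if (with_drift) " with drift", ": ",
         paste(unique(diag), collapse = "; "))
  pars <- from_opt(setNames(best$par, nms))
  lnL <- -best$objective
  k <- length(nms)
  structure(list(form = form, with_drift = with_drift, pars = pars,
                 model = model_from_pars(form, pars, rho), lnL = lnL,
                 k = k, AIC = 2 * k - 2 * lnL,
                 converged = best$convergence == 0, start = start,
                 grid = grid, settings = s),
            class = "quasse_fit")
}

#' @export
print.quasse_fit <- function(x, ...) {
  cat("<quasse_fit> ", x$form, if (x$with_drift) "+drift",
      "  lnL=", signif(x$lnL, 8), "  AIC=", signif(x$AIC, 8),
      if (!x$converged) "  [not converged]", "\n  ", sep = "")
  cat(paste(names(x$pars), signif(x$pars, 4), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Back-transformed modal optimum of a fit
#'
#' When the trait was log-transformed before fitting, the reported optimum
#' is `exp(xmid)` on the original scale.
#'
#' @param fit A `quasse_fit` with an `xmid` parameter.
#' @param log_scale Was the fitted trait on a log scale?
#' @return Optimum on the original trait scale.
#' @export
modal_optimum <- function(fit, log_scale = FALSE) {
  if (!"xmid" %in% names(fit$pars)) stop("fit has no midpoint parameter")
  if (log_scale) exp(fit$pars[["xmid"]]) else fit$pars[["xmid"]]
}

#' Fit and compare the seven trait-dependent diversification models
#'
#' Fits constant, linear, sigmoid and modal speciation functions (the
#' last three with and without drift) to one tree and trait, sharing a
#' single grid and step size, and tabulates AIC, the AIC difference of
#' each model versus the best, and the difference of the best versus the
#' constant null.  Drift variants warm-start from their no-drift fit and
#' all forms warm-start their level parameters from the constant fit.
#' Support is flagged "decisive" when best-versus-second ΔAIC exceeds 4.
#'
#' @param tree Ultrametric `phylo`.
#' @param tip_states Named tip states.
#' @param rho Sampling fraction.
#' @param settings As in [fit_model()].
#' @return A `model_table` data frame (`model`, `k`, `lnL`, `AIC`,
#'   `dAIC_best`, `dAIC_null`, `converged`) with attributes `fits`,
#'   `best`, `decisive`.
#' @export
compare_models <- function(tree, tip_states, rho = 1, settings = list()) {
  states <- tip_states[tree$tip.label]
  height <- max(ape::node.depth.edgelength(tree))
  s <- settings
  if (is.null(s$nx)) s$nx <- 1024L
  ds <- default_starts(tree, states, height)
  if (is.null(s$sigma2_max)) s$sigma2_max <- max(4 * ds$sigma2, 1e-6)
  if (is.null(s$grid))
    s$grid <- quasse_grid_auto(states, height, s$sigma2_max, s$nx)

  members <- list(
    constant      = list(form = "constant", drift = FALSE),
    linear        = list(form = "linear", drift = FALSE),
    linear_drift  = list(form = "linear", drift = TRUE),
    sigmoid       = list(form = "sigmoid", drift = FALSE),
    sigmoid_drift = list(form = "sigmoid", drift = TRUE),
    modal         = list(form = "modal", drift = FALSE),
    modal_drift   = list(form = "modal", drift = TRUE))

  fits <- vector("list", length(members))
  names(fits) <- names(members)
  warm <- list()
  for (nm in names(members)) {
    m <- members[[nm]]
    si <- s
    si$start <- warm_start(m$form, m$drift, warm, s$start)
    fits[[nm]] <- tryCatch(
      fit_model(tree, states, m$form, m$drift, rho, si),
      error = function(e) e)
    if (!inherits(fits[[nm]], "error")) warm[[nm]] <- fits[[nm]]
  }
  failed <- vapply(fits, inherits, TRUE, "error")
  if (any(failed))
    warning("model fit failed for: ",
            paste(names(fits)[failed], collapse = ", "))
  if (all(failed)) stop("all seven model fits failed")

  tab <- data.frame(
    model = names(members),
    k = vapply(names(members), function(nm)
      length(par_names(members[[nm]]$form, members[[nm]]$drift)), 0L),
    lnL = vapply(fits, function(f) if (inherits(f, "error")) NA_real_
                 else f$lnL, 0),
    AIC = vapply(fits, function(f) if (inherits(f, "error")) NA_real_
                 else f$AIC, 0),
    converged = vapply(fits, function(f) if (inherits(f, "error")) FALSE
                       else f$converged, TRUE),
    row.names = NULL)
  best_aic <- min(tab$AIC, na.rm = TRUE)
  tab$dAIC_best <- tab$AIC - best_aic
  tab$dAIC_null <- tab$AIC[tab$model == "constant"] - tab$AIC
  aics <- sort(tab$AIC[!is.na(tab$AIC)])
  decisive <- length(aics) >= 2 && (aics[2] - aics[1]) > 4
  structure(tab, fits = fits,
            best = tab$model[which.min(tab$AIC)],
            dAIC_second = if (length(aics) >= 2) aics[2] - aics[1] else NA,
            decisive = decisive,
            class = c("model_table", "data.frame"))
}

warm_start <- function(form, drift, warm, user_start = NULL) {
  st <- list()
  if (!is.null(warm$constant)) {
    cp <- warm$constant$pars
    st$mu <- cp[["mu"]]; st$sigma2 <- cp[["sigma2"]]
    if (form == "linear") st$intercept <- cp[["y0"]]
    if (form %in% c("sigmoid", "modal")) {
      st$y0 <- 0.8 * cp[["y0"]]; st$y1 <- 1.5 * cp[["y0"]]
    }
  }
  if (drift) {
    prev <- warm[[form]]
    if (!is.null(prev)) {
      st[names(prev$pars)] <- as.list(prev$pars)
      st$phi <- 0
    }
  }
  if (length(user_start)) st[names(user_start)] <- user_start
  st
}
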