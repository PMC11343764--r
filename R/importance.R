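# Bootstrapped gradient-boosting importance-ranking protocol.
#
# The response is log(tip speciation rate): rates are strictly positive
# and right-skewed, so accuracy metrics (bias, R^2) are reported on the
# log scale.  Missing predictor values are passed through to the
# learner's native sparse handling, not imputed.  Categorical variables
# are one-hot encoded and their importance summed back over the source
# variable.  Relative importance is normalized total split gain.

# Build the design matrix and aligned response.  Returns the matrix,
# response, and the mapping from encoded columns back to variables.
build_design <- function(table, rates, log_response = TRUE) {
  stopifnot(is.data.frame(table), "species" %in% names(table),
            inherits(rates, "tip_rates"))
  m <- merge(table, as.data.frame(rates), by = "species")
  if (nrow(m) == 0L) stop("no species shared between table and rates")
  vars <- setdiff(names(table), "species")
  cols <- list()
  col_var <- character()
  for (v in vars) {
    x <- m[[v]]
    if (is.numeric(x) || is.integer(x) || is.logical(x)) {
      cols[[v]] <- as.numeric(x)
      col_var <- c(col_var, setNames(v, v))
    } else {
      x <- as.character(x)
      for (lv in sort(unique(x[!is.na(x)]))) {
        cn <- paste0(v, "=", lv)
        enc <- as.numeric(x == lv)
        enc[is.na(x)] <- NA
        cols[[cn]] <- enc
        col_var <- c(col_var, setNames(v, cn))
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- m$species
  y <- if (log_response) log(m$rate) else m$rate
  list(X = X, y = y, vars = vars, col_var = col_var, species = m$species)
}

xgb_params <- function(p) {
  list(objective = "reg:squarederror", eta = p$eta,
       max_depth = p$max_depth, subsample = p$subsample,
       colsample_bytree = p$colsample_bytree,
       min_child_weight = p$min_child_weight, nthread = 1)
}

#' Default stage-one tuning grid
#'
#' Learning rate x depth (2-7) x row/column subsample x minimum child
#' weight; boosting rounds are chosen per combination by early stopping on
#' cross-validated rmse.
#'
#' @return Data frame of parameter combinations.
#' @export
default_tuning_grid <- function() {
  expand.grid(eta = c(0.01, 0.05, 0.1, 0.3), max_depth = 2:7,
              subsample = c(0.5, 0.8, 1.0), colsample_bytree = c(0.5, 0.8, 1.0),
              min_child_weight = c(1, 5))
}

cv_rmse <- function(X, y, p, folds, nrounds_max, early_stop) {
  cv <- xgboost::xgb.cv(params = xgb_params(p),
                        data = xgboost::xgb.DMatrix(X, label = y,
                                                    missing = NA),
                        nrounds = nrounds_max, folds = folds,
                        early_stopping_rounds = early_stop,
                        verbose = FALSE)
  ev <- cv$evaluation_log
  best <- which.min(ev$test_rmse_mean)
  list(rmse = ev$test_rmse_mean[best], nrounds = best)
}

#' Two-stage parameter tuning for the boosted-tree model
#'
#' Stage one grid-searches predefined parameter combinations, minimising
#' k-fold cross-validated rmse of log-rate predictions (rounds chosen by
#' early stopping).  Stage two draws `n_stage2` parameter vectors
#' uniformly within +/-10% of the stage-one optimum (integers rounded,
#' values clamped to valid ranges — depth stays in `[2, 7]`) and returns
#' the rmse-minimising vector.  The stage-one optimum is included in the
#' stage-two candidate set, and all evaluations share one fold
#' assignment, so the final rmse can never exceed stage one's.
#'
#' @param table Species-by-variable data frame (column `species`).
#' @param rates A [tip_rates].
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Integer seed (folds, parameter draws).
#' @param grid Stage-one grid (default [default_tuning_grid()]).
#' @param n_stage2 Stage-two draws (default 1000).
#' @param nrounds_max,early_stop Boosting-round search controls.
#' @return A `tuned_params` list: `eta`, `max_depth`, `subsample`,
#'   `colsample_bytree`, `min_child_weight`, `nrounds`, `cv_rmse`, and the
#'   per-stage best rmse values.
#' @export
tune_two_stage <- function(table, rates, cv_folds = 5, seed = 1L,
                           grid = default_tuning_grid(), n_stage2 = 1000L,
                           nrounds_max = 300L, early_stop = 10L) {
  d <- build_design(table, rates)
  if (length(d$y) < 50) stop("need >= 50 complete-response rows")
  set.seed(seed)
  fold_id <- sample(rep(seq_len(cv_folds), length.out = length(d$y)))
  folds <- split(seq_along(d$y), fold_id)

  eval1 <- lapply(seq_len(nrow(grid)), function(i)
    cv_rmse(d$X, d$y, as.list(grid[i, ]), folds, nrounds_max, early_stop))
  rmse1 <- vapply(eval1, `[[`, 0, "rmse")
  b1 <- which.min(rmse1)
  best1 <- as.list(grid[b1, ])
  best1$nrounds <- eval1[[b1]]$nrounds

  lo <- function(v) v * 0.9
  hi <- function(v) v * 1.1
  cand <- data.frame(
    eta = pmin(runif(n_stage2, lo(best1$eta), hi(best1$eta)), 1),
    max_depth = pmin(pmax(round(runif(n_stage2, lo(best1$max_depth),
                                      hi(best1$max_depth))), 2L), 7L),
    subsample = pmin(pmax(runif(n_stage2, lo(best1$subsample),
                                hi(best1$subsample)), 0.1), 1),
    colsample_bytree = pmin(pmax(runif(n_stage2, lo(best1$colsample_bytree),
                                       hi(best1$colsample_bytree)), 0.1), 1),
    min_child_weight = pmax(round(runif(n_stage2, lo(best1$min_child_weight),
                                        hi(best1$min_child_weight))), 1L))
  cand <- rbind(cand, as.data.frame(best1[names(cand)]))
  eval2 <- lapply(seq_len(nrow(cand)), function(i)
    cv_rmse(d$X, d$y, as.list(cand[i, ]), folds, nrounds_max, early_stop))
  rmse2 <- vapply(eval2, `[[`, 0, "rmse")
  b2 <- which.min(rmse2)
  out <- as.list(cand[b2, ])
  out$max_depth <- as.integer(out$max_depth)
  out$nrounds <- eval2[[b2]]$nrounds
  out$cv_rmse <- rmse2[b2]
  out$stage1_rmse <- rmse1[b1]
  out$stage2_rmse <- rmse2[b2]
  structure(out, class = "tuned_params")
}

fit_booster <- function(X, y, params, nrounds) {
  xgboost::xgb.train(params = xgb_params(params),
                     data = xgboost::xgb.DMatrix(X, label = y, missing = NA),
                     nrounds = nrounds, verbose = FALSE)
}

gain_by_variable <- function(booster, col_var, vars) {
  imp <- xgboost::xgb.importance(model = booster)
  out <- setNames(numeric(length(vars)), vars)
  if (!is.null(imp) && nrow(imp)) {
    g <- tapply(imp$Gain, col_var[imp$Feature], sum)
    out[names(g)] <- g
    s <- sum(out)
    if (s > 0) out <- out / s
  }
  out
}

#' Bootstrap relative-importance distribution
#'
#' For each of `B` replicates: rows are resampled with replacement, the
#' model is fitted on a random 80% of the resample and evaluated on the
#' held-out 20% (R^2 and bias = mean(predicted - observed), both on the
#' log-rate scale), and the gain-based relative importance (normalized to
#' sum 1 over variables) is recorded.
#'
#' @param table,rates As in [tune_two_stage()].
#' @param params A `tuned_params` (or a compatible list).
#' @param B Number of bootstrap replicates (default 1000; `< 100` warns).
#' @param seed Integer seed.
#' @param train_frac Training fraction of each resample (default 0.8).
#' @return An `importance_report`: `importance` (B x p matrix), `q25`,
#'   `q75`, `median`, `threshold` (= 1/p), `significant` (logical),
#'   `r2`, `bias`, `mean_r2`, `mean_bias`.
#' @export
bootstrap_importance <- function(table, rates, params, B = 1000L, seed = 1L,
                                 train_frac = 0.8) {
  if (B < 100) warning("B < 100: importance quantiles will be unstable")
  d <- build_design(table, rates)
  if (var(d$y) == 0) stop("constant response; importance undefined")
  n <- length(d$y)
  p <- length(d$vars)
  set.seed(seed)
  imp <- matrix(NA_real_, B, p, dimnames = list(NULL, d$vars))
  r2 <- numeric(B)
  bias <- numeric(B)
  for (b in seq_len(B)) {
    rows <- sample.int(n, n, replace = TRUE)
    ntr <- floor(train_frac * n)
    tr <- rows[seq_len(ntr)]
    te <- rows[(ntr + 1):n]
    fit <- fit_booster(d$X[tr, , drop = FALSE], d$y[tr], params,
                       params$nrounds)
    pred <- predict(fit, xgboost::xgb.DMatrix(d$X[te, , drop = FALSE],
                                              missing = NA))
    obs <- d$y[te]
    r2[b] <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    bias[b] <- mean(pred - obs)
    imp[b, ] <- gain_by_variable(fit, d$col_var, d$vars)
  }
  q <- apply(imp, 2, quantile, probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
  threshold <- 1 / p
  structure(list(importance = imp, q25 = q[1, ], median = q[2, ],
                 q75 = q[3, ], threshold = threshold,
                 significant = q[1, ] > threshold,
                 r2 = r2, bias = bias,
                 mean_r2 = mean(r2), mean_bias = mean(bias),
                 params = params, B = B, seed = seed),
            class = "importance_report")
}

#' Variables called significant by the quartile rule
#'
#' A variable is significant when its 25% importance quantile strictly
#' exceeds the chance-expectation threshold 1/p; results are ordered by
#' median importance (descending, ties broken by name).
#'
#' @param report An `importance_report`.
#' @return Character vector of significant variable names.
#' @export
significant_variables <- function(report) {
  stopifnot(inherits(report, "importance_report"))
  sig <- names(report$significant)[report$significant]
  sig[order(-report$median[sig], sig)]
}

#' Complex-versus-stump model contrast
#'
#' Repeats the bootstrap protocol with maximum tree depth forced to 1 (a
#' "stump" ensemble cannot encode variable interactions) and reports both
#' mean R^2 values and importance rankings; the R^2 gap measures the
#' contribution of interactions to predictive power.
#'
#' @inheritParams bootstrap_importance
#' @return A `comparison_report` with `complex`, `stump` (both
#'   `importance_report`s), `mean_r2_complex`, `mean_r2_stump`,
#'   `rank_complex`, `rank_stump`.
#' @export
stump_contrast <- function(table, rates, params, B = 1000L, seed = 1L) {
  stump_params <- params
  stump_params$max_depth <- 1L
  complex <- bootstrap_importance(table, rates, params, B, seed)
  stump <- bootstrap_importance(table, rates, stump_params, B, seed)
  rank_of <- function(rep)
    names(rep$median)[order(-rep$median, names(rep$median))]
  structure(list(complex = complex, stump = stump,
                 mean_r2_complex = complex$mean_r2,
                 mean_r2_stump = stump$mean_r2,
                 rank_complex = rank_of(complex),
                 rank_stump = rank_of(stump)),
            class = "comparison_report")
}

#' Fit the final predictive model on the full data
#'
#' @inheritParams bootstrap_importance
#' @return A `final_model`: the booster plus the encoding metadata needed
#'   for [prediction_curve()].
#' @export
fit_final_model <- function(table, rates, params, seed = 1L) {
  d <- build_design(table, rates)
  set.seed(seed)
  fit <- fit_booster(d$X, d$y, params, params$nrounds)
  structure(list(booster = fit, design = d, params = params),
            class = "final_model")
}

#' Predicted-rate curve over one variable
#'
#' Predicts the speciation rate at `n_grid` evenly spaced values across
#' the observed range of `variable`, pinning every other variable at its
#' median (continuous) or mode (discrete), and back-transforms predictions
#' to the original rate scale.
#'
#' @param model A `final_model`.
#' @param table The trait table the model was fitted to.
#' @param variable Name of a numeric variable in the table.
#' @param n_grid Number of grid values (default 250).
#' @return Data frame `value`, `rate`.
#' @export
prediction_curve <- function(model, table, variable, n_grid = 250L) {
  stopifnot(inherits(model, "final_model"))
  if (!variable %in% setdiff(names(table), "species"))
    stop("variable not in table: ", variable)
  x <- table[[variable]]
  if (!is.numeric(x)) stop("prediction curves require a numeric variable")
  rng <- range(x, na.rm = TRUE)
  grid_vals <- seq(rng[1], rng[2], length.out = n_grid)
  X <- model$design$X
  base <- apply(X, 2, function(col) {
    u <- sort(unique(col[!is.na(col)]))
    if (length(u) <= 2) stat_mode(col) else median(col, na.rm = TRUE)
  })
  base <- as.numeric(base)
  Xg <- matrix(rep(base, each = n_grid), n_grid, ncol(X),
               dimnames = list(NULL, colnames(X)))
  if (!variable %in% colnames(Xg))
    stop("variable not representable in the design matrix: ", variable)
  Xg[, variable] <- grid_vals
  pred <- predict(model$booster, xgboost::xgb.DMatrix(Xg, missing = NA))
  data.frame(value = grid_vals, rate = exp(pred))
}

#' Drop fast-rate outlier species before re-running the protocol
#'
#' Sensitivity filter: removes species whose tip speciation rate exceeds
#' `cutoff` so the importance protocol can be re-run on the remainder;
#' dropped names are recorded in the `"dropped"` attribute.
#'
#' @param rates A [tip_rates].
#' @param cutoff Rate cutoff (default 0.65).
#' @return Filtered [tip_rates].
#' @export
sensitivity_filter <- function(rates, cutoff = 0.65) {
  stopifnot(inherits(rates, "tip_rates"))
  drop <- rates$rate > cutoff
  if (all(drop)) stop("cutoff removed every species")
  out <- rates[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- attr(rates, "source")
  attr(out, "dropped") <- rates$species[drop]
  class(out) <- class(rates)
  out
}
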