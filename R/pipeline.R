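#' Configuration for an end-to-end driver-identification run
#'
#' Bundles inputs and protocol constants.  Defaults are the protocol's
#' reference values: 1000 bootstrap replicates, 25/75% significance
#' quantiles against the 1/p threshold, stump depth 1, outlier
#' sensitivity cutoff 0.65, 250-point prediction curves, and the
#' seven-model state-dependent comparison for each significant variable.
#'
#' @param tree A `phylo` or path to a Newick file.
#' @param table Trait data frame (column `species`) or CSV path.
#' @param rates A [tip_rates], a CSV path, or `"dr"` to estimate from the
#'   tree.
#' @param occurrences Optional occurrence data frame/CSV (`species, lon,
#'   lat`); when given, records are cleaned, thinned and summarized, and
#'   log AOO is appended to the table as `range_size_aoo`.
#' @param land_mask Optional polygon mask for cleaning.
#' @param layers Optional named list of [grid_layer]s to summarize.
#' @param layer_kinds Kinds for `layers` (see [summarize_layers()]).
#' @param params Optional pre-tuned `tuned_params`; when `NULL` the
#'   two-stage tuning runs with `tuning_grid`.
#' @param tuning_grid Stage-one grid (default [default_tuning_grid()]).
#' @param B Bootstrap replicates (default 1000).
#' @param sensitivity_cutoff Tip-rate outlier cutoff (default 0.65).
#' @param n_grid Prediction-curve length (default 250).
#' @param rho Sampling fraction for the state-dependent models.
#' @param log_vars Variables log-transformed before state-dependent
#'   fitting (their reported midpoints are back-transformed).
#' @param quasse Settings list passed to [compare_models()]; set
#'   `quasse$skip = TRUE` to omit the confirmation stage.
#' @param seed Master seed.
#' @param out_dir Output directory (created); `NULL` keeps results in
#'   memory only.
#' @return A `run_config`.
#' @export
run_config <- function(tree, table, rates = "dr", occurrences = NULL,
                       land_mask = NULL, layers = NULL, layer_kinds = NULL,
                       params = NULL, tuning_grid = default_tuning_grid(),
                       B = 1000L, sensitivity_cutoff = 0.65,
                       n_grid = 250L, rho = 1, log_vars = character(),
                       quasse = list(), seed = 1L, out_dir = NULL) {
  structure(list(tree = tree, table = table, rates = rates,
                 occurrences = occurrences, land_mask = land_mask,
                 layers = layers, layer_kinds = layer_kinds,
                 params = params, tuning_grid = tuning_grid, B = B,
                 sensitivity_cutoff = sensitivity_cutoff, n_grid = n_grid,
                 rho = rho, log_vars = log_vars, quasse = quasse,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

load_input <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the full driver-identification pipeline
#'
#' Stages: occurrence prep (clean, thin, summarize, AOO) when occurrence
#' data are supplied; tip-rate estimation or import; two-stage tuning
#' (unless params are given); bootstrap importance with significance
#' calls; the stump contrast; the outlier-filtered sensitivity re-run;
#' and the seven-model state-dependent comparison for each significant
#' numeric variable.  Any stage failure aborts with the stage name;
#' completed outputs are preserved in the returned object (and on disk
#' when `out_dir` is set).
#'
#' @param config A [run_config()].
#' @return A `run_result` list with per-stage outputs and a `manifest`
#'   (config echo, seeds, versions, wall-clock per stage, output hashes).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  res <- list()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  tree <- load_input(config$tree, ape::read.tree)
  table <- load_input(config$table, function(p)
    read.csv(p, stringsAsFactors = FALSE))

  if (!is.null(config$occurrences)) {
    occ <- load_input(config$occurrences, function(p)
      occurrence_set(read.csv(p, stringsAsFactors = FALSE)))
    res$occ_clean <- stage("clean", clean_occurrences(occ, config$land_mask))
    res$occ_thin <- stage("thin", thin_one_per_cell(res$occ_clean, 1.0))
    if (!is.null(config$layers))
      res$summaries <- stage("summarize",
        summarize_layers(res$occ_thin, config$layers, config$layer_kinds))
    res$aoo <- stage("aoo", compute_aoo(res$occ_clean, 0.1))
    table <- merge(table,
                   data.frame(species = res$aoo$species,
                              range_size_aoo = log(res$aoo$aoo_km2)),
                   by = "species", all.x = TRUE)
  }

  res$rates <- stage("tiprates", {
    if (identical(config$rates, "dr")) dr_statistic(tree)
    else if (is.character(config$rates))
      read_tiprate_table(config$rates, tree)
    else config$rates
  })

  params <- config$params
  if (is.null(params))
    params <- stage("tune",
      tune_two_stage(table, res$rates, seed = config$seed,
                     grid = config$tuning_grid))
  res$params <- params

  res$importance <- stage("importance",
    bootstrap_importance(table, res$rates, params, B = config$B,
                         seed = config$seed))
  res$significant <- significant_variables(res$importance)
  res$contrast <- stage("stump",
    stump_contrast(table, res$rates, params, B = config$B,
                   seed = config$seed))
  res$sensitivity <- stage("sensitivity", {
    filt <- sensitivity_filter(res$rates, config$sensitivity_cutoff)
    rep <- bootstrap_importance(table, filt, params, B = config$B,
                                seed = config$seed)
    list(rates = filt, report = rep,
         significant = significant_variables(rep))
  })

  if (!isTRUE(config$quasse$skip) && length(res$significant)) {
    res$model_tables <- stage("quasse", {
      out <- list()
      for (v in res$significant) {
        x <- table[[v]]
        if (!is.numeric(x)) next
        ok <- !is.na(x)
        states <- setNames(x[ok], table$species[ok])
        states <- states[names(states) %in% tree$tip.label]
        if (length(states) < 10) next
        if (v %in% config$log_vars) states <- log(states)
        tr <- if (length(states) < length(tree$tip.label))
          ape::drop.tip(tree, setdiff(tree$tip.label, names(states)))
        else tree
        qs <- config$quasse
        qs$skip <- NULL
        out[[v]] <- compare_models(tr, states, rho = config$rho,
                                   settings = qs)
      }
      out
    })
  }

  manifest <- list(
    config = config[setdiff(names(config),
                            c("tree", "table", "occurrences", "layers",
                              "land_mask", "tuning_grid"))],
    seed = config$seed,
    n_tips = length(tree$tip.label),
    n_rows = nrow(table),
    significant = res$significant,
    timings = timings,
    versions = list(R = R.version.string,
                    divdrivers =
                      as.character(utils::packageVersion("divdrivers"))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  res$manifest <- manifest

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    write.csv(res$importance$importance,
              file.path(od, "importance_matrix.csv"), row.names = FALSE)
    write.csv(data.frame(variable = names(res$importance$median),
                         median = res$importance$median,
                         q25 = res$importance$q25,
                         q75 = res$importance$q75,
                         significant = res$importance$significant),
              file.path(od, "importance_quantiles.csv"), row.names = FALSE)
    writeLines(res$significant, file.path(od, "significant_variables.txt"))
    if (!is.null(res$model_tables))
      for (v in names(res$model_tables))
        write.csv(as.data.frame(res$model_tables[[v]]),
                  file.path(od, paste0("model_table_", v, ".csv")),
                  row.names = FALSE)
    files <- list.files(od, full.names = TRUE)
    manifest$output_hashes <- as.list(tools::md5sum(files))
    res$manifest <- manifest
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  class(res) <- "run_result"
  res
}

#' Summary report of a pipeline run
#'
#' One row per significant variable: best-fitting state-dependent model,
#' its AIC margin over the constant null, the (back-transformed) modal or
#' sigmoid midpoint, and the drift estimate.  The midpoint column is
#' empty (NA) when the best model has no midpoint parameter.
#'
#' @param result A `run_result` from [run_pipeline()].
#' @return List with `drivers` (the per-variable table) and `accuracy`
#'   (mean R^2 and bias for the complex and stump models).
#' @export
make_report <- function(result) {
  stopifnot(inherits(result, "run_result"))
  sig <- result$significant
  log_vars <- result$manifest$config$log_vars
  rows <- lapply(sig, function(v) {
    mt <- result$model_tables[[v]]
    if (is.null(mt))
      return(data.frame(variable = v, best_model = NA, dAIC_null = NA,
                        midpoint = NA, drift = NA))
    best <- attr(mt, "best")
    fit <- attr(mt, "fits")[[best]]
    mid <- if ("xmid" %in% names(fit$pars))
      modal_optimum(fit, log_scale = v %in% log_vars) else NA_real_
    drift <- if ("phi" %in% names(fit$pars)) fit$pars[["phi"]] else NA_real_
    data.frame(variable = v, best_model = best,
               dAIC_null = mt$dAIC_null[mt$model == best],
               midpoint = mid, drift = drift)
  })
  drivers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(), best_model = character(),
               dAIC_null = numeric(), midpoint = numeric(),
               drift = numeric())
  list(drivers = drivers,
       accuracy = data.frame(
         model = c("complex", "stump"),
         mean_r2 = c(result$contrast$mean_r2_complex,
                     result$contrast$mean_r2_stump),
         mean_bias = c(result$contrast$complex$mean_bias,
                       result$contrast$stump$mean_bias)))
}
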