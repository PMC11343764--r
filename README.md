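# divdrivers

Identifying the drivers of lineage diversification from a time-calibrated
phylogeny and a table of candidate predictors — the analysis problem posed
by large, ecologically heterogeneous radiations (cacti being the
motivating example), where dozens of interacting abiotic and biotic
variables could each plausibly shape speciation rates.

The package implements both arms of a screen-then-confirm workflow, plus
the simulators needed to validate every stage without external data:

- **Tip rates** — the DR statistic (inverse equal-splits,
  `ES_i = Σ_j l_j (1/2)^(j-1)`, `DR_i = 1/ES_i` with the pendant edge at
  `j = 1`), and validated import of externally computed rate tables
  (e.g. BAMM mean tip rates).
- **Importance ranking** — gradient-boosted regression of log tip rate on
  mixed-type predictors with native missing-value handling: two-stage
  hyperparameter tuning (predefined grid, then 1000 uniform draws within
  ±10% of the stage-one optimum), B-replicate bootstrap importance
  (normalized split gain), significance when a variable's 25% importance
  quantile clears the 1/p chance threshold, a depth-1 "stump" contrast
  isolating the contribution of variable interactions, 250-point
  prediction curves, and a fast-rate outlier sensitivity filter
  (default cutoff 0.65).
- **State-dependent confirmation** — a from-scratch QuaSSE-type
  likelihood: the extinction function E(x,t) and data function D(x,t) are
  propagated backward along each branch by second-order operator
  splitting (exact pointwise birth–death reaction updates alternating
  with FFT Gaussian advection–diffusion on a 1024-point trait grid), with
  sampling fraction ρ entering the tip conditions.  Seven speciation
  functions λ(x) — constant; linear, sigmoid, modal (Gaussian hump), each
  with and without directional drift φ — are fitted by bounded maximum
  likelihood and compared by AIC, with a ΔAIC > 4 decisiveness flag.
- **Simulators and data prep** — a forward trait-dependent birth–death
  simulator matching the fitted model class exactly; synthetic
  species-by-variable tables with planted drivers, interactions, mixed
  types and MCAR missingness; clustered occurrence generators; occurrence
  cleaning and equal-area 1 km² thinning; per-species raster summaries;
  and area-of-occupancy (AOO) range sizes at configurable cell sizes.

See the methods vignette
(`vignettes/trait-dependent-diversification.Rmd`) for the model,
numerics, and design decisions.

## Worked example

Simulate a 120-tip clade whose speciation rate is a Gaussian hump in the
trait (baseline 0.1, peak 0.45 per Myr, optimum 0.55, width sd 0.1, small
positive drift), screen a synthetic predictor table, and confirm the
driver with the modal-with-drift fit:

```r
library(divdrivers)

cl <- simulate_quasse_tree_retry(
  sim_config(modal_speciation(0.1, 0.45, xmid = 0.55, s2 = 0.01),
             mu = 0.03, sigma2 = 0.004, phi = 0.0012,
             root_state = 0.55, stop_n = 120, max_time = 80, seed = 1))
cl
#> <sim_clade> 120 extant tips, 13 extinct pruned, height 14.14 Myr

rates <- dr_statistic(cl$tree)
round(summary(rates$rate), 3)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.071   0.243   0.362   0.430   0.487   1.936

gen <- generate_predictor_table(
  table_spec(n_species = 400, n_vars = 10, missing_frac = 0.1,
             planted = list(V2 = modal_speciation(0.1, 0.6, 0, s2 = 1)),
             type_map = rep("continuous", 10)),
  seed = 1)
params <- structure(list(eta = 0.15, max_depth = 3, subsample = 0.8,
                         colsample_bytree = 0.8, min_child_weight = 1,
                         nrounds = 80), class = "tuned_params")
rep <- bootstrap_importance(gen$table, gen$rates, params, B = 100, seed = 1)
rep$mean_r2                   #> 0.718
significant_variables(rep)    #> "V2"   (threshold 1/p = 0.1)

fit <- fit_model(cl$tree, cl$tip_states, "modal", with_drift = TRUE,
                 settings = list(nstart = 1, dt_frac = 1 / 100))
fit
#> <quasse_fit> modal+drift  lnL=-144.5783  AIC=303.1565
#>   y0=0.1782, y1=0.5932, xmid=0.5345, s2=0.002716, mu=0.1135,
#>   sigma2=0.003748, phi=0.001625
```

The screen flags only the planted table driver (V2: the held-out R² of
0.72 and an importance far above 1/p), and the tree-based fit recovers
the planted optimum (0.5345 vs 0.55), drift of the right sign and
magnitude, and a clade-level speciation profile close to the generating
one.  The DR summary shows the ~25-fold rate spread a strong modal
driver induces at the tips.

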