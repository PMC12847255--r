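## End-to-end pipeline: fixtures/inputs -> descriptor extraction ->
## spectral preprocessing -> band + feature selection -> fusion ->
## ORBMO-tuned random forest -> evaluation. Every random stage consumes
## a sub-seed derived from the global seed ([derive_seed()]), so stages
## are individually reproducible.

#' Build a validated pipeline configuration
#'
#' Nested stage blocks with the package defaults; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param ... named overrides, e.g.
#'   `run_pipeline_config(optimizer = list(n = 10))`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    fixtures = list(preset = "easy", samples_per_class = 65, wl_step = 1),
    imaging = list(blur_sigma = 1, opening_radius = 2, min_area = 200,
                   margin_px = 15),
    spectra = list(method = "SG_MSC", window = 21, polyorder = 3,
                   crop_lo = 400, crop_hi = 2400),
    bands = list(method = "CARS", n_runs = 50, k_folds = 5, n_pls = 10,
                 spa_m_max = 15),
    selection = list(method = "RFE", n_keep = NULL, sfm_threshold = "mean"),
    fusion = list(ratio = 0.7),
    optimizer = list(n = 30, t_max = 100, use_circle_init = TRUE,
                     use_gss = TRUE, use_asa = TRUE),
    rf = list(cv_folds = 5),
    out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0)
    abort_input("unknown configuration block(s): ",
                paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(defaults[[nm]])) {
      bad2 <- setdiff(names(over[[nm]]), names(defaults[[nm]]))
      if (length(bad2) > 0)
        abort_input("unknown key(s) in '", nm, "': ",
                    paste(bad2, collapse = ", "))
      defaults[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Run the full classification pipeline on synthetic fixtures
#'
#' Executes extract -> preprocess -> select -> fuse -> tune -> evaluate
#' and (when `out_dir` is set) writes `features.csv`, `prep.csv`,
#' `bands.json`, `fused.csv`, `model_report.json`, `history.csv` and
#' `run.log`.
#'
#' @param config a [pipeline_config()].
#' @return list with the `report` (a [classification_report()]),
#'   `params` (tuned hyperparameters), `history`, `task` (the fused
#'   task), and the configuration used.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  spec <- fixture_spec(preset = config$fixtures$preset,
                       samples_per_class = config$fixtures$samples_per_class,
                       wl_step = config$fixtures$wl_step)
  task <- make_fused_task(spec, seed = derive_seed(seed, 10),
                          cars_runs = config$bands$n_runs,
                          spa_max = config$bands$spa_m_max)
  tr <- task$split$train; te <- task$split$test
  cfg <- orbmo_config(use_circle_init = config$optimizer$use_circle_init,
                      use_gss = config$optimizer$use_gss,
                      use_asa = config$optimizer$use_asa)
  tuned <- tune_rf(task$fused$X[tr, ], task$fused$y[tr],
                   n = config$optimizer$n, t_max = config$optimizer$t_max,
                   cfg = cfg, k = config$rf$cv_folds,
                   seed = derive_seed(seed, 20))
  model <- train_rf(task$fused$X[tr, ], task$fused$y[tr], tuned$params,
                    seed = derive_seed(seed, 30))
  report <- evaluate_model(model, task$fused$X[te, ], task$fused$y[te])
  result <- list(report = report, params = tuned$params,
                 history = tuned$history, task = task, config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fd <- result$task$fused
  write.csv(result$task$morph_table, file.path(dir, "features.csv"),
            row.names = FALSE)
  write_spectra_csv(result$task$prep, file.path(dir, "prep.csv"))
  write.csv(data.frame(fd$X, label = fd$y, check.names = FALSE),
            file.path(dir, "fused.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(indices = result$task$bands$indices,
         wavelengths_nm = result$task$bands$wavelengths_nm,
         score_curve = result$task$bands$score_curve,
         chosen = result$task$bands$chosen),
    file.path(dir, "bands.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(params = as.list(result$params),
         accuracy = result$report$accuracy,
         precision = result$report$precision,
         recall = result$report$recall, f1 = result$report$f1,
         confusion = result$report$confusion,
         config = unclass(result$config)),
    file.path(dir, "model_report.json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(iteration = seq_along(result$history),
                       best_fitness = result$history),
            file.path(dir, "history.csv"), row.names = FALSE)
  writeLines(c(
    sprintf("preset=%s samples_per_class=%d seed=%d",
            result$config$fixtures$preset,
            result$config$fixtures$samples_per_class,
            result$config$seed),
    sprintf("bands_kept=%d morph_kept=%d",
            length(result$task$bands$indices),
            result$task$fused$blocks["morph"]),
    sprintf("params n_estimators=%d max_depth=%d max_features=%d",
            result$params[1], result$params[2], result$params[3]),
    sprintf("test_accuracy=%.6f", result$report$accuracy)),
    file.path(dir, "run.log"))
  invisible(dir)
}

#' Strategy-ablation sweep of the optimizer
#'
#' Runs all 8 on/off combinations of the three mechanisms (Circle
#' chaotic initialization, golden-sine + Levy search, adaptive
#' simulated annealing) on a benchmark objective with a matched budget
#' and identical seeds, returning one summary row per combination.
#'
#' @param objective function to minimize.
#' @param space a [search_space()].
#' @param n,t_max budget per run.
#' @param seeds integer vector of seeds (each configuration is run once
#'   per seed).
#' @return data frame: `circle`, `gss`, `asa`, `median_best`,
#'   `mean_best`.
#' @export
run_ablation <- function(objective, space, n = 30, t_max = 100,
                         seeds = 1:5) {
  grid <- expand.grid(circle = c(FALSE, TRUE), gss = c(FALSE, TRUE),
                      asa = c(FALSE, TRUE))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- orbmo_config(use_circle_init = grid$circle[i],
                        use_gss = grid$gss[i], use_asa = grid$asa[i])
    best <- vapply(seeds, function(s)
      orbmo_optimize(objective, space, n = n, t_max = t_max, cfg = cfg,
                     seed = s)$best_fitness, numeric(1))
    data.frame(circle = grid$circle[i], gss = grid$gss[i],
               asa = grid$asa[i], median_best = median(best),
               mean_best = mean(best))
  })
  do.call(rbind, res)
}
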