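#' Build a pipeline configuration
#'
#' The pipeline runs up to six stages in dependency order: `simulate`
#' (synthetic cohort), `fingerprint` (feature extraction), `screen`
#' (Kruskal-Wallis group comparison), `predict_cross` (cross-sectional
#' clinical-scale prediction), `predict_longitudinal` (T to T+6-month
#' comparison) and `biomarker` (constrained Bayesian optimization of the
#' progression curve). Configuration lives in a single structured
#' key-value (YAML) file; every value can also be overridden
#' programmatically.
#'
#' @param ... named overrides (nested lists merged into the defaults).
#' @return a list of class `kine_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "kinedmd_run",
    manifest = NULL,             # required when `simulate` is off
    stages = list(simulate = TRUE, fingerprint = TRUE, screen = TRUE,
                  predict_cross = TRUE, predict_longitudinal = TRUE,
                  biomarker = TRUE),
    generator = list(),          # generator_config() overrides
    families = list(),           # family_config() overrides
    prediction = list(targets = c("6mwd", "nsaa", "pul", "myogrip"),
                      horizon_months = 6, tolerance_months = 2,
                      cap = 10L),
    biomarker = list(budget = 100L, n_init = 10L, cap = 10L))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0,
              "unknown pipeline option(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  class(cfg) <- "kine_pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  assert_that(file.exists(path), "config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Polynomial rolling hash of the canonical YAML serialisation, embedded in
# every report. Paths and stage toggles are excluded so the hash identifies
# the analysis parameters: re-running one stage from stored intermediates
# must reproduce its report byte-for-byte.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$manifest <- NULL
  cfg$stages <- NULL
  bytes <- utf8ToInt(yaml::as.yaml(cfg))
  h <- 104729
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", h)
}

report_header <- function(config, stage) {
  list(stage = stage, config_hash = config_hash(config), seed = config$seed)
}

prediction_report_json <- function(report) {
  list(target = report$target, type = report$type %||% "cross_sectional",
       rmse = report$rmse, r2 = report$r2,
       n_rows = report$n_rows, n_subjects = report$n_subjects,
       final_subset = report$selection$final,
       subset_frequency = as.list(report$selection$frequency))
}

#' Run the analysis pipeline
#'
#' Executes the toggled stages in order, writing versioned CSV/JSON reports
#' under `config$out_dir`. Every report embeds the configuration hash and
#' the seed, so re-running a stage from stored intermediates reproduces its
#' report exactly. A stage whose upstream artifact is missing (e.g.
#' `fingerprint` without `simulate` and without a `manifest` path) raises a
#' dependency error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  results <- list()
  stage_log <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    message("[kinedmd] stage ", stage, " ...")
    res <- force(expr)
    dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    message("[kinedmd] stage ", stage, " done in ", dt, " s")
    stage_log[[stage]] <<- "completed"
    res
  }

  manifest <- NULL
  if (isTRUE(st$simulate)) {
    results$simulate <- tick("simulate", {
      gcfg <- do.call(generator_config, config$generator)
      cohort <- generate_cohort(gcfg, config$seed, out_dir = file.path(out, "cohort"))
      compact_json(c(report_header(config, "simulate"),
                     list(n_dmd = gcfg$n_dmd, n_hc = gcfg$n_hc,
                          n_visits = nrow(cohort$manifest))),
                   file.path(out, "simulate_report.json"))
      cohort$manifest
    })
    manifest <- results$simulate
  } else if (!is.null(config$manifest)) {
    assert_that(file.exists(config$manifest),
                "dependency error: stage fingerprint needs `manifest`, file not found: ",
                config$manifest)
    manifest <- read_manifest(config$manifest)
  }

  fcfg <- do.call(family_config, config$families)
  features <- NULL
  if (isTRUE(st$fingerprint)) {
    assert_that(!is.null(manifest),
                "dependency error: stage fingerprint requires the simulate stage or a `manifest` path")
    results$fingerprint <- tick("fingerprint", {
      feats <- extract_cohort_fingerprints(manifest, config = fcfg)
      fdf <- data.frame(visit_id = rownames(feats), feats,
                        check.names = FALSE)
      data.table::fwrite(fdf, file.path(out, "features.csv"))
      compact_json(c(report_header(config, "fingerprint"),
                     list(n_visits = nrow(feats), n_features = ncol(feats))),
                   file.path(out, "fingerprint_report.json"))
      feats
    })
    features <- results$fingerprint
  } else if (file.exists(file.path(out, "features.csv"))) {
    fdf <- data.table::fread(file.path(out, "features.csv"), data.table = FALSE)
    features <- as.matrix(fdf[, -1, drop = FALSE])
    rownames(features) <- fdf$visit_id
  }

  need_features <- function(stage) {
    assert_that(!is.null(features) && !is.null(manifest),
                "dependency error: stage ", stage,
                " requires the fingerprint stage (or stored features.csv)")
  }

  if (isTRUE(st$screen)) {
    results$screen <- tick("screen", {
      need_features("screen")
      scr <- kruskal_wallis_screen(features, manifest$group)
      data.table::fwrite(scr, file.path(out, "screen.csv"))
      compact_json(c(report_header(config, "screen"),
                     list(n_significant_p05 = sum(scr$p <= 0.05),
                          n_features = nrow(scr))),
                   file.path(out, "screen_report.json"))
      scr
    })
  }

  dataset <- NULL
  make_dataset <- function() {
    if (is.null(dataset)) {
      dmd <- manifest[manifest$group == "DMD", , drop = FALSE]
      dataset <<- as_cohort_dataset(dmd, features[dmd$visit_id, , drop = FALSE])
    }
    dataset
  }

  if (isTRUE(st$predict_cross)) {
    results$predict_cross <- tick("predict_cross", {
      need_features("predict_cross")
      ds <- make_dataset()
      reps <- lapply(config$prediction$targets, function(tg) {
        rep <- cross_sectional_predict(ds, tg, cap = config$prediction$cap)
        data.table::fwrite(rep$predictions,
                           file.path(out, paste0("cross_", tg, "_predictions.csv")))
        rep
      })
      names(reps) <- config$prediction$targets
      compact_json(c(report_header(config, "predict_cross"),
                     list(results = lapply(reps, prediction_report_json))),
                   file.path(out, "predict_cross_report.json"))
      reps
    })
  }

  if (isTRUE(st$predict_longitudinal)) {
    results$predict_longitudinal <- tick("predict_longitudinal", {
      need_features("predict_longitudinal")
      ds <- make_dataset()
      reps <- lapply(config$prediction$targets, function(tg) {
        longitudinal_compare(ds, tg,
                             horizon_months = config$prediction$horizon_months,
                             tolerance_months = config$prediction$tolerance_months,
                             cap = config$prediction$cap)
      })
      names(reps) <- config$prediction$targets
      compact_json(c(report_header(config, "predict_longitudinal"),
                     list(results = lapply(reps, function(pair) {
                       list(score_based = prediction_report_json(pair$score_based),
                            fingerprint_based = prediction_report_json(pair$fingerprint_based))
                     }))),
                   file.path(out, "predict_longitudinal_report.json"))
      reps
    })
  }

  if (isTRUE(st$biomarker)) {
    results$biomarker <- tick("biomarker", {
      need_features("biomarker")
      ds <- make_dataset()
      bm <- optimize_biomarker(ds, budget = config$biomarker$budget,
                               seed = config$seed,
                               n_init = config$biomarker$n_init,
                               cap = config$biomarker$cap)
      data.table::fwrite(bm$curve, file.path(out, "biomarker_curve.csv"))
      data.table::fwrite(bm$fitted, file.path(out, "biomarker_fitted.csv"))
      compact_json(c(report_header(config, "biomarker"),
                     list(alpha = bm$alpha, beta = bm$beta,
                          objective = bm$objective,
                          y5 = bm$feasibility$y5, y15 = bm$feasibility$y15,
                          feasible = bm$feasibility$feasible,
                          subset = bm$subset,
                          trace = bm$trace)),
                   file.path(out, "biomarker_report.json"))
      bm
    })
  }

  compact_json(c(report_header(config, "run"),
                 list(stages = stage_log)),
               file.path(out, "run_report.json"))
  invisible(results)
}
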