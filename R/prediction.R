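#' Assemble a cohort dataset of fingerprints and clinical scores
#'
#' Joins the visit rows of a cohort manifest with the extracted fingerprint
#' matrix (matched by `visit_id`). The result is a data.frame, one row per
#' visit, carrying metadata and score columns plus the named feature
#' columns; the feature column names are stored in the `feature_cols`
#' attribute and every row carries its subject key for LOSO grouping.
#'
#' @param manifest cohort manifest data.frame.
#' @param features visit x feature matrix with rownames = `visit_id`.
#' @return a data.frame of class `cohort_dataset`.
#' @export
as_cohort_dataset <- function(manifest, features) {
  features <- as.matrix(features)
  assert_that(!is.null(rownames(features)), "feature matrix needs visit_id rownames")
  idx <- match(manifest$visit_id, rownames(features))
  assert_that(!anyNA(idx), "every manifest visit needs a feature row")
  df <- cbind(manifest, as.data.frame(features[idx, , drop = FALSE]))
  rownames(df) <- NULL
  attr(df, "feature_cols") <- colnames(features)
  class(df) <- c("cohort_dataset", "data.frame")
  df
}

feature_cols <- function(dataset) {
  fc <- attr(dataset, "feature_cols")
  assert_that(!is.null(fc), "dataset lacks a `feature_cols` attribute")
  fc
}

#' Leave-one-subject-out fold plan
#'
#' One fold per subject, containing all and only that subject's rows; folds
#' partition the dataset and are ordered by first appearance.
#'
#' @param dataset a `cohort_dataset` (or any data.frame with `subject_id`).
#' @return named list of integer row-index vectors.
#' @export
make_loso_folds <- function(dataset) {
  subj <- as.character(dataset$subject_id)
  ids <- unique(subj)
  assert_that(length(ids) >= 3, "LOSO needs >= 3 subjects")
  folds <- lapply(ids, function(s) which(subj == s))
  names(folds) <- ids
  folds
}

resolve_target <- function(scale) {
  map <- c("6mwd" = "sixmwd_m", "sixmwd_m" = "sixmwd_m", "sixmwd" = "sixmwd_m",
           "nsaa" = "nsaa", "pul" = "pul",
           "myogrip" = "myogrip_pct", "myogrip_pct" = "myogrip_pct")
  key <- tolower(scale)
  assert_that(key %in% names(map), "unknown clinical scale: ", scale)
  unname(map[key])
}

#' Nested leave-one-subject-out evaluation with wrapper feature selection
#'
#' The outer loop is LOSO over subjects. For each outer training fold, a
#' feature subset is chosen by [select_features_floating()] scored with
#' inner LOSO; the modal subset across folds ([most_frequent_subset()]) is
#' the final subset. Each outer fold is then refit on its training rows
#' only (features and target standardized with training statistics, GP
#' hyperparameters grid-tuned by inner LOSO) and its held-out subject is
#' predicted. Out-of-fold predictions are pooled into the aggregate RMSE
#' and R-squared (`1 - SS_res/SS_tot`; may be negative).
#'
#' @param dataset a `cohort_dataset`.
#' @param target target column name (e.g. `"nsaa"`).
#' @param select run wrapper selection (`FALSE` uses `features` as given).
#' @param features fixed feature subset when `select = FALSE` (defaults to
#'   all feature columns).
#' @param cap,tol selection cap and improvement tolerance.
#' @param grid GP hyperparameter grid.
#' @param max_missing maximum tolerated fraction of missing targets.
#' @return a `kine_prediction_report`: pooled `predictions`, `rmse`, `r2`,
#'   `selection` (per-fold subsets, frequency table, final subset), and
#'   per-fold standardization metadata.
#' @export
nested_cv_evaluate <- function(dataset, target, select = TRUE, features = NULL,
                               cap = 10L, tol = 0.01, grid = gp_default_grid(),
                               max_missing = 0.2) {
  fc <- features %||% feature_cols(dataset)
  assert_that(target %in% names(dataset), "target column '", target, "' absent")
  y_all <- dataset[[target]]
  miss <- !is.finite(y_all)
  if (mean(miss) > max_missing) {
    stop_arg("target '", target, "' missing for ", round(100 * mean(miss)),
             "% of rows (> ", round(100 * max_missing), "%); no imputation is done")
  }
  data <- dataset[!miss, , drop = FALSE]
  assert_that(length(unique(data$subject_id)) >= 5,
              "nested evaluation needs >= 5 subjects")
  X <- as.matrix(data[, fc, drop = FALSE])
  y <- data[[target]]
  folds <- make_loso_folds(data)
  subsets <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    tr <- setdiff(seq_len(nrow(data)), folds[[i]])
    subsets[[i]] <- if (select) {
      select_features_floating(X[tr, , drop = FALSE], y[tr],
                               groups = data$subject_id[tr],
                               cap = cap, tol = tol)
    } else fc
  }
  scores <- vapply(subsets, function(s) attr(s, "score") %||% NA_real_,
                   numeric(1))
  subsets <- lapply(subsets, as.vector)  # drop score attributes
  final <- if (select && !anyNA(scores)) {
    most_frequent_subset(subsets, scores)
  } else {
    most_frequent_subset(subsets)
  }
  preds <- rep(NA_real_, nrow(data))
  fold_meta <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    te <- folds[[i]]
    tr <- setdiff(seq_len(nrow(data)), te)
    gp <- fit_gp(X[tr, final, drop = FALSE], y[tr],
                 groups = data$subject_id[tr], grid = grid)
    preds[te] <- predict(gp, X[te, final, drop = FALSE])
    fold_meta[[i]] <- list(subject = names(folds)[i], train_rows = tr,
                           feature_center = gp$x_center,
                           feature_scale = gp$x_scale,
                           y_center = gp$y_center,
                           lengthscale = gp$lengthscale, noise_sd = gp$noise_sd)
  }
  rmse <- sqrt(mean((preds - y)^2))
  r2 <- 1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = " + "), character(1))
  report <- list(
    target = target,
    predictions = data.frame(subject_id = data$subject_id,
                             visit_id = data$visit_id,
                             actual = y, predicted = preds),
    rmse = rmse, r2 = r2,
    n_rows = nrow(data), n_subjects = length(folds),
    selection = list(per_fold = subsets, final = final,
                     frequency = sort(table(keys), decreasing = TRUE)),
    folds = fold_meta)
  class(report) <- "kine_prediction_report"
  report
}

#' @export
print.kine_prediction_report <- function(x, ...) {
  cat("<kine_prediction_report> target=", x$target,
      " n=", x$n_rows, " subjects=", x$n_subjects, "\n",
      "  RMSE=", signif(x$rmse, 4), "  R2=", signif(x$r2, 4), "\n",
      "  final subset (", length(x$selection$final), "): ",
      paste(x$selection$final, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Cross-sectional prediction of a clinical scale from fingerprints
#'
#' The ambulant-only rule applies to the ambulation-dependent scales: rows
#' are filtered to ambulatory visits for 6MWD and NSAA, while PUL and
#' MyoGrip (assessed in non-ambulant individuals too) keep all visits. The
#' filtered dataset is then evaluated with [nested_cv_evaluate()].
#'
#' @param dataset a `cohort_dataset`.
#' @param scale one of `"6MWD"`, `"NSAA"`, `"PUL"`, `"MyoGrip"` (case
#'   insensitive, column names also accepted).
#' @param ... passed to [nested_cv_evaluate()].
#' @return a `kine_prediction_report` with `type = "cross_sectional"`.
#' @export
cross_sectional_predict <- function(dataset, scale, ...) {
  target <- resolve_target(scale)
  if (target %in% c("sixmwd_m", "nsaa")) {
    keep <- which(dataset$ambulatory)
    dataset <- subset_dataset(dataset, keep)
  }
  report <- nested_cv_evaluate(dataset, target, ...)
  report$type <- "cross_sectional"
  report
}

subset_dataset <- function(dataset, rows) {
  out <- dataset[rows, , drop = FALSE]
  attr(out, "feature_cols") <- attr(dataset, "feature_cols")
  class(out) <- class(dataset)
  out
}

#' Pair visits for longitudinal (T to T+6 months) prediction
#'
#' One row per ordered visit pair of a subject whose gap lies within
#' `horizon_months +/- tolerance_months`: predictors (fingerprints and
#' scores suffixed `_T`) come from the earlier visit, targets (scores
#' suffixed `_future`) from the later one.
#'
#' @param dataset a `cohort_dataset` with `visit_month`.
#' @param horizon_months prediction horizon (default 6).
#' @param tolerance_months allowed deviation from the horizon (default 2).
#' @return a `cohort_dataset` of pairs (possibly 0 rows).
#' @export
build_longitudinal_pairs <- function(dataset, horizon_months = 6,
                                     tolerance_months = 2) {
  assert_that("visit_month" %in% names(dataset), "dataset lacks `visit_month`")
  fc <- feature_cols(dataset)
  scores <- intersect(c("sixmwd_m", "nsaa", "pul", "myogrip_pct"), names(dataset))
  lo <- horizon_months - tolerance_months
  hi <- horizon_months + tolerance_months
  rows <- list()
  for (s in unique(dataset$subject_id)) {
    vi <- which(dataset$subject_id == s)
    vi <- vi[order(dataset$visit_month[vi])]
    if (length(vi) < 2) next
    for (a in seq_along(vi)) {
      for (b in seq_along(vi)) {
        gap <- dataset$visit_month[vi[b]] - dataset$visit_month[vi[a]]
        if (gap < lo || gap > hi) next
        iT <- vi[a]; iF <- vi[b]
        row <- data.frame(subject_id = s,
                          visit_id = paste0(dataset$visit_id[iT], ">",
                                            dataset$visit_id[iF]),
                          group = dataset$group[iT],
                          age_years = dataset$age_years[iT],
                          visit_month = dataset$visit_month[iT],
                          gap_months = gap,
                          ambulatory = dataset$ambulatory[iT])
        for (sc in scores) {
          row[[paste0(sc, "_T")]] <- dataset[[sc]][iT]
          row[[paste0(sc, "_future")]] <- dataset[[sc]][iF]
        }
        row <- cbind(row, dataset[iT, fc, drop = FALSE])
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(subject_id = character(0)),
          as.data.frame(matrix(numeric(0), 0, length(fc),
                               dimnames = list(NULL, fc))))
  rownames(out) <- NULL
  attr(out, "feature_cols") <- fc
  class(out) <- c("cohort_dataset", "data.frame")
  out
}

#' Compare score-only and fingerprint-based longitudinal prediction
#'
#' Builds the T to T+6-month pairs, then evaluates two models under the
#' identical nested LOSO protocol: (A) predictor = the scale itself at T;
#' (B) predictors = the ethomic fingerprints at T. For the
#' ambulation-dependent scales (6MWD, NSAA) pairs are restricted to visits
#' ambulatory at T.
#'
#' @param dataset a `cohort_dataset`.
#' @param scale clinical scale (see [cross_sectional_predict()]).
#' @param horizon_months,tolerance_months pairing window.
#' @param ... passed to [nested_cv_evaluate()] for the fingerprint model.
#' @return list with `score_based` and `fingerprint_based` reports.
#' @export
longitudinal_compare <- function(dataset, scale, horizon_months = 6,
                                 tolerance_months = 2, ...) {
  target <- resolve_target(scale)
  pairs <- build_longitudinal_pairs(dataset, horizon_months, tolerance_months)
  assert_that(nrow(pairs) > 0, "no longitudinal pairs in the dataset")
  if (target %in% c("sixmwd_m", "nsaa")) {
    pairs <- subset_dataset(pairs, which(pairs$ambulatory))
  }
  future <- paste0(target, "_future")
  at_T <- paste0(target, "_T")
  rep_score <- nested_cv_evaluate(pairs, future, select = FALSE,
                                  features = at_T)
  rep_score$type <- "longitudinal_score_based"
  rep_fp <- nested_cv_evaluate(pairs, future, ...)
  rep_fp$type <- "longitudinal_fingerprint_based"
  list(score_based = rep_score, fingerprint_based = rep_fp)
}

#' Enumerate or sample subject subsets of size k
#'
#' All `choose(n, k)` combinations when that count is at most `max_comb`;
#' otherwise `max_comb` distinct combinations sampled uniformly without
#' replacement under the seed.
#'
#' @param subjects character vector of subject ids.
#' @param k subset size.
#' @param max_comb cap on the number of combinations (default 1000).
#' @param seed integer seed for the sampling branch.
#' @return list of character vectors.
#' @export
subject_subsets <- function(subjects, k, max_comb = 1000L, seed = 1L) {
  n <- length(subjects)
  assert_that(k >= 1 && k <= n, "`k` must be in [1, number of subjects]")
  total <- choose(n, k)
  if (total <= max_comb) {
    return(apply(combn(subjects, k), 2, identity, simplify = FALSE))
  }
  set.seed(seed)
  seen <- new.env(hash = TRUE)
  out <- vector("list", max_comb)
  got <- 0L
  while (got < max_comb) {
    s <- sort(sample(subjects, k))
    key <- paste(s, collapse = "\r")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- s
    }
  }
  out
}

#' Learning curve over the number of subjects
#'
#' For each `k`, nested LOSO evaluation is repeated on `min(choose(n, k),
#' max_comb)` subject subsets and the mean and standard deviation of the
#' aggregate RMSE are reported (s.d. 0 when only one combination exists).
#'
#' @param dataset a `cohort_dataset`.
#' @param target target column name.
#' @param ks vector of subject counts (each >= 5).
#' @param seed integer seed for subset sampling.
#' @param max_comb combination cap per k (default 1000).
#' @param ... passed to [nested_cv_evaluate()].
#' @return data.frame with `k`, `n_combinations`, `rmse_mean`, `rmse_sd`.
#' @export
learning_curve <- function(dataset, target, ks, seed = 1L, max_comb = 1000L,
                           ...) {
  subjects <- unique(as.character(dataset$subject_id))
  assert_that(all(ks >= 5), "each k must be >= 5 subjects")
  assert_that(all(ks <= length(subjects)), "k exceeds the subject count")
  res <- lapply(ks, function(k) {
    combos <- subject_subsets(subjects, k, max_comb, derive_seed(seed, "lc", k))
    rmses <- vapply(combos, function(ss) {
      sub <- subset_dataset(dataset, which(dataset$subject_id %in% ss))
      nested_cv_evaluate(sub, target, ...)$rmse
    }, numeric(1))
    data.frame(k = k, n_combinations = length(combos),
               rmse_mean = mean(rmses),
               rmse_sd = if (length(rmses) > 1) sd(rmses) else 0)
  })
  do.call(rbind, res)
}
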