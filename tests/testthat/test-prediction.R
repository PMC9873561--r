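test_that("LOSO folds partition rows by subject", {
  ds <- toy_dataset(n_sub = 3, visits = 2)
  folds <- make_loso_folds(ds)
  expect_length(folds, 3)
  expect_true(all(lengths(folds) == 2))
  expect_setequal(unlist(folds), seq_len(nrow(ds)))

  df <- data.frame(subject_id = c("a", "b", "b", "b", "c"))
  folds <- make_loso_folds(df)
  expect_equal(unname(lengths(folds)), c(1, 3, 1))
  expect_error(make_loso_folds(data.frame(subject_id = c("a", "b"))), "3 subjects")
})

test_that("floating selection finds informative features deterministically", {
  ds <- toy_dataset(n_sub = 15, p = 10, seed = 41,
                    target_fn = function(X) 3 * X[, 4])
  X <- as.matrix(ds[, attr(ds, "feature_cols")])
  s1 <- select_features_floating(X, ds$target, ds$subject_id)
  s2 <- select_features_floating(X, ds$target, ds$subject_id)
  expect_identical(s1, s2)
  expect_true("f04" %in% s1)

  set.seed(42)
  noise_y <- rnorm(nrow(ds))
  s3 <- select_features_floating(X, noise_y, ds$subject_id)
  expect_gte(length(s3), 1)  # minimum subset size is one feature
  expect_lte(length(s3), 10)
})

test_that("the modal subset rule breaks ties by size then lexicographically", {
  expect_equal(most_frequent_subset(list(c("A", "B"), c("B", "A"), "C")),
               c("A", "B"))
  expect_equal(most_frequent_subset(list("B", "A")), "A")
  expect_equal(most_frequent_subset(list(c("A", "B"), "C")), "C")  # size tie-break
  expect_equal(most_frequent_subset(list(c("X", "Q"))), c("Q", "X"))
  # with per-fold selection scores, the best-validated subset wins ties
  expect_equal(most_frequent_subset(list("A", c("B", "C")), scores = c(0.9, 0.2)),
               c("B", "C"))
  expect_equal(most_frequent_subset(list(c("A", "B"), c("B", "A"), "C"),
                                    scores = c(0.5, 0.5, 0.1)),
               c("A", "B"))  # a clear mode is never overridden by scores
})

test_that("nested LOSO recovers constructed signal and does not leak", {
  ds <- toy_dataset(n_sub = 15, p = 10, seed = 43)
  rep1 <- nested_cv_evaluate(ds, "target")
  expect_gte(rep1$r2, 0.99)
  expect_equal(nrow(rep1$predictions), nrow(ds))  # pooled count = row count
  expect_setequal(rep1$selection$final, c("f03", "f07"))

  # standardization statistics come from training rows only, in every fold
  X <- as.matrix(ds[, attr(ds, "feature_cols")])
  for (fm in rep1$folds) {
    expect_equal(fm$feature_center,
                 colMeans(X[fm$train_rows, rep1$selection$final, drop = FALSE]))
  }

  # pure-noise target: no optimism
  set.seed(44)
  ds$target <- rnorm(nrow(ds))
  expect_lte(nested_cv_evaluate(ds, "target")$r2, 0.1)

  # subject-deranged target: far below the aligned fit (the strict bound,
  # at the larger cohort size, lives in the acceptance suite)
  ds2 <- toy_dataset(n_sub = 12, p = 8, seed = 45)
  subs <- unique(ds2$subject_id)
  rows_of <- split(seq_len(nrow(ds2)), ds2$subject_id)
  r2s <- vapply(1:3, function(i) {
    set.seed(50 + i)
    perm <- derange(subs)
    ds2$target_perm <- ds2$target
    for (s in subs) ds2$target_perm[rows_of[[s]]] <- ds2$target[rows_of[[perm[[s]]]]]
    nested_cv_evaluate(ds2, "target_perm")$r2
  }, numeric(1))
  expect_true(all(r2s < 0.5))
  expect_lte(mean(r2s), 0.1)
})

test_that("aggregate metrics are invariant to row order", {
  ds <- toy_dataset(n_sub = 8, p = 6, seed = 46)
  r1 <- nested_cv_evaluate(ds, "target", select = FALSE,
                           features = c("f01", "f03"))
  perm <- sample(nrow(ds))
  ds2 <- ds[perm, , drop = FALSE]
  attr(ds2, "feature_cols") <- attr(ds, "feature_cols")
  class(ds2) <- class(ds)
  r2 <- nested_cv_evaluate(ds2, "target", select = FALSE,
                           features = c("f01", "f03"))
  expect_equal(r1$rmse, r2$rmse, tolerance = 1e-10)
})

test_that("missing targets are dropped, not imputed, up to a limit", {
  ds <- toy_dataset(n_sub = 10, p = 6, seed = 47)
  ds$target[1:2] <- NA
  rep1 <- nested_cv_evaluate(ds, "target", select = FALSE,
                             features = c("f03", "f05"))
  expect_equal(rep1$n_rows, nrow(ds) - 2)
  ds$target[1:6] <- NA  # 30% missing
  expect_error(nested_cv_evaluate(ds, "target"), "missing")
})

test_that("the ambulant-only rule filters 6MWD/NSAA but not PUL", {
  ds <- toy_dataset(n_sub = 10, p = 6, seed = 48)
  ds$ambulatory <- rep(c(TRUE, FALSE), length.out = nrow(ds))
  amb_rows <- sum(ds$ambulatory)
  ds$sixmwd_m <- ds$target + 100
  ds$pul <- ds$target + 20
  r6 <- cross_sectional_predict(ds, "6MWD", select = FALSE, features = "f03")
  expect_equal(r6$n_rows, amb_rows)
  rp <- cross_sectional_predict(ds, "PUL", select = FALSE, features = "f03")
  expect_equal(rp$n_rows, nrow(ds))
})

test_that("longitudinal pairing respects the horizon window", {
  ds <- toy_dataset(n_sub = 6, visits = 3, p = 4, seed = 49)  # months 0, 6, 12
  pairs <- build_longitudinal_pairs(ds)
  expect_equal(nrow(pairs), 6 * 2)  # (0->6) and (6->12) per subject
  expect_true(all(pairs$gap_months == 6))

  one <- toy_dataset(n_sub = 5, visits = 1, p = 4, seed = 50)
  expect_equal(nrow(build_longitudinal_pairs(one)), 0)

  wide <- toy_dataset(n_sub = 5, visits = 2, p = 4, seed = 51)
  wide$visit_month <- rep(c(0, 9), 5)  # 9-month gap, tolerance 2
  expect_equal(nrow(build_longitudinal_pairs(wide)), 0)
  expect_equal(nrow(build_longitudinal_pairs(wide, tolerance_months = 3)), 5)
})

test_that("longitudinal comparison exposes identical pair counts", {
  ds <- toy_dataset(n_sub = 8, visits = 3, p = 6, seed = 52)
  ds$nsaa <- round(20 + ds$target)
  cmp <- longitudinal_compare(ds, "nsaa")
  expect_equal(cmp$score_based$n_rows, cmp$fingerprint_based$n_rows)

  tiny <- toy_dataset(n_sub = 2, visits = 2, p = 4, seed = 53)
  tiny$nsaa <- round(20 + tiny$target)
  expect_error(longitudinal_compare(tiny, "nsaa"), "subjects")
})

test_that("subject subset enumeration respects the 1000-combination cap", {
  subs <- sprintf("S%02d", 1:10)
  expect_length(subject_subsets(subs, 8), choose(10, 8))  # 45, enumerated
  expect_length(subject_subsets(subs, 10), 1)             # k = n
  big <- sprintf("S%02d", 1:20)
  combos <- subject_subsets(big, 10, seed = 3)
  expect_length(combos, 1000)
  expect_equal(length(unique(vapply(combos, paste, collapse = ",",
                                    character(1)))), 1000)
})

test_that("learning curves improve with more subjects on synthetic signal", {
  ds <- toy_dataset(n_sub = 10, visits = 2, p = 6, seed = 54,
                    target_fn = function(X) X[, 2] + 0.6 * rnorm(nrow(X)))
  lc <- learning_curve(ds, "target", ks = c(5, 7, 9), seed = 9, max_comb = 6,
                       select = FALSE, features = c("f02", "f05"))
  expect_equal(lc$n_combinations, c(6, 6, 6))
  expect_lte(sum(diff(lc$rmse_mean) > 0), 1)  # non-increasing, <= 1 inversion

  lc_full <- learning_curve(ds, "target", ks = 10, seed = 9,
                            select = FALSE, features = "f02")
  expect_equal(lc_full$n_combinations, 1)
  expect_equal(lc_full$rmse_sd, 0)
})
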