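# Wrapper feature selection scored by inner leave-one-subject-out GP error.
#
# The engine pre-computes one squared-difference matrix per (z-scored)
# feature; the squared distance of any feature subset is the sum of its
# members' matrices, so candidate subsets are scored incrementally from a
# single Cholesky factorisation each (see gp_logo_rmse). Candidates are
# scored at fixed median-heuristic hyperparameters (lengthscale sqrt(d),
# noise sd 0.1); the full grid search happens at refit time.

build_selection_engine <- function(X, y, groups) {
  sx <- standardize_cols(X)
  ysd <- sd(y)
  ys <- if (ysd > 0) (y - mean(y)) / ysd else y - mean(y)
  n <- nrow(X)
  gidx <- split(seq_len(n), groups)
  Dk <- lapply(seq_len(ncol(X)), function(j) {
    dj <- outer(sx$X[, j], sx$X[, j], "-")
    dj * dj
  })
  names(Dk) <- colnames(X)
  list(Dk = Dk, ys = ys, gidx = gidx, n = n, features = colnames(X))
}

score_subset_engine <- function(engine, Dsum, d, noise_sd = c(0.01, 0.1)) {
  if (d == 0) return(Inf)
  min(vapply(noise_sd, function(ns)
    gp_logo_rmse(Dsum, engine$ys, engine$gidx, sqrt(d), ns), numeric(1)))
}

#' Combined forward/backward (floating) wrapper feature selection
#'
#' Starting from the empty set, the feature whose addition most improves
#' the inner leave-one-subject-out GP RMSE is added; after each addition,
#' features (other than the one just added) are conditionally removed while
#' removal improves the score. Selection stops when no addition improves by
#' more than `tol` or the subset cap is reached. At least one feature is
#' always returned, and the procedure is deterministic given the data (ties
#' resolve to the earliest feature in column order).
#'
#' @param X feature matrix with named columns.
#' @param y numeric target.
#' @param groups subject key per row (inner LOSO folds).
#' @param cap maximum subset size.
#' @param tol minimum RMSE improvement (standardized-target units) to accept
#'   a move. The default 0.01 demands a meaningful gain: accepting
#'   noise-level improvements makes every fold run to the cap with its own
#'   idiosyncratic subset, which degrades the modal-subset rule downstream.
#' @param floating allow conditional backward removals (`FALSE` gives pure
#'   forward selection, used inside the biomarker objective).
#' @return character vector of selected feature names (column order).
#' @export
select_features_floating <- function(X, y, groups, cap = 10L, tol = 0.01,
                                     floating = TRUE) {
  X <- as.matrix(X)
  assert_that(!is.null(colnames(X)), "X must have named columns")
  assert_that(length(unique(groups)) >= 2, "need >= 2 subjects for inner LOSO")
  engine <- build_selection_engine(X, y, groups)
  feats <- engine$features
  selected <- character(0)
  Dsum <- matrix(0, engine$n, engine$n)
  current <- Inf
  while (length(selected) < cap) {
    remaining <- setdiff(feats, selected)
    if (length(remaining) == 0) break
    scores <- vapply(remaining, function(f) {
      score_subset_engine(engine, Dsum + engine$Dk[[f]], length(selected) + 1L)
    }, numeric(1))
    best <- which.min(scores)
    if (length(selected) > 0 && scores[best] >= current - tol) break
    selected <- c(selected, remaining[best])
    Dsum <- Dsum + engine$Dk[[remaining[best]]]
    current <- scores[best]
    last_added <- remaining[best]
    if (floating) {
      repeat {
        if (length(selected) <= 2) break
        removable <- setdiff(selected, last_added)
        back <- vapply(removable, function(f) {
          score_subset_engine(engine, Dsum - engine$Dk[[f]], length(selected) - 1L)
        }, numeric(1))
        worst <- which.min(back)
        if (back[worst] < current - tol) {
          drop_f <- removable[worst]
          selected <- setdiff(selected, drop_f)
          Dsum <- Dsum - engine$Dk[[drop_f]]
          current <- back[worst]
        } else break
      }
    }
  }
  out <- feats[feats %in% selected]
  attr(out, "score") <- current
  out
}

#' Most frequent feature subset across folds
#'
#' The per-fold selected subsets are tallied (order-insensitively); the
#' modal subset is returned. When several subsets tie for the highest
#' frequency -- at small subject counts, correlated features routinely make
#' every fold's subset unique -- ties break by the supplied per-subset
#' selection scores (lower inner-LOSO RMSE wins), then toward the smaller
#' subset, then lexicographically. Without scores the rule is purely
#' size-then-lexicographic. Either way the result is deterministic and is
#' always one of the per-fold subsets.
#'
#' @param subsets list of character vectors.
#' @param scores optional numeric vector, one selection score per subset.
#' @return character vector: the winning subset (sorted).
#' @export
most_frequent_subset <- function(subsets, scores = NULL) {
  assert_that(length(subsets) >= 1, "need at least one subset")
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = "\r"), character(1))
  tab <- table(keys)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1 && !is.null(scores)) {
    assert_that(length(scores) == length(subsets),
                "need one score per subset")
    key_score <- tapply(scores, keys, min)[top]
    top <- top[key_score == min(key_score)]
  }
  if (length(top) > 1) {
    sizes <- lengths(strsplit(top, "\r", fixed = TRUE))
    top <- top[sizes == min(sizes)]
    top <- sort(top)[1]
  }
  strsplit(top, "\r", fixed = TRUE)[[1]]
}
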