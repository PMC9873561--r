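#' The monotone tanh disease-progression curve
#'
#' The progression biomarker over age is
#' `Y(age) = (tanh(X) - tanh(Xmin)) / (tanh(Xmax) - tanh(Xmin))` with
#' `X = alpha * age - beta`, `Xmin = X(0)` and `Xmax = X(25)`. The
#' normalisation anchors the curve at exactly 0 at age 0 and 1 at age 25,
#' and the curve is monotonically increasing in between; different
#' `(alpha, beta)` give near-linear, accelerating or S-shaped sigmoid
#' trajectories. `alpha` must be strictly positive (at `alpha = 0` the
#' normalisation degenerates); the searched box is `alpha` in `(0, 0.5]`,
#' `beta` in `[0, 5]`.
#'
#' @param age age(s) in years, within `[0, 25]`.
#' @param alpha per-year slope, in `(0, 0.5]`.
#' @param beta unitless offset, in `[0, 5]`.
#' @return biomarker value(s) in `[0, 1]`.
#' @export
evaluate_biomarker <- function(age, alpha, beta) {
  check_biomarker_params(alpha, beta)
  assert_that(all(age >= 0 & age <= 25), "`age` must be within [0, 25]")
  tmin <- tanh(-beta)
  tmax <- tanh(25 * alpha - beta)
  (tanh(alpha * age - beta) - tmin) / (tmax - tmin)
}

check_biomarker_params <- function(alpha, beta) {
  assert_that(length(alpha) == 1 && length(beta) == 1, "scalar parameters expected")
  assert_that(is.finite(alpha) && alpha > 0,
              "`alpha` must be > 0 (alpha = 0 degenerates the normalisation)")
  assert_that(alpha <= 0.5, "`alpha` must be <= 0.5")
  assert_that(is.finite(beta) && beta >= 0 && beta <= 5,
              "`beta` must be in [0, 5]")
  invisible(TRUE)
}

#' Clinical feasibility of a progression curve
#'
#' A curve is clinically meaningful when its value at age 5 lies in
#' `[0.01, 0.15]` (patients range from not overtly symptomatic to showing
#' first signs) and its value at age 15 lies in `[0.5, 0.8]` (loss of
#' lower-body ambulation through early upper-body/cardio-respiratory
#' involvement). Both intervals are closed; feasibility depends only on
#' `(alpha, beta)` and is evaluated analytically.
#'
#' @inheritParams evaluate_biomarker
#' @return list with `feasible` (logical), `y5` and `y15`.
#' @export
check_feasibility <- function(alpha, beta) {
  y5 <- evaluate_biomarker(5, alpha, beta)
  y15 <- evaluate_biomarker(15, alpha, beta)
  list(feasible = (y5 >= 0.01 && y5 <= 0.15 && y15 >= 0.5 && y15 <= 0.8),
       y5 = y5, y15 = y15)
}

biomarker_box <- function() {
  list(alpha = c(1e-6, 0.5), beta = c(0, 5))
}

# Pre-computed per-dataset state shared by every objective evaluation: the
# fingerprints never change across (alpha, beta) proposals, only the target.
biomarker_engine <- function(dataset, feature_subset = NULL) {
  fc <- feature_subset %||% feature_cols(dataset)
  X <- as.matrix(dataset[, fc, drop = FALSE])
  assert_that(all(is.finite(X)), "non-finite fingerprints in dataset")
  sx <- standardize_cols(X)
  n <- nrow(X)
  gidx <- split(seq_len(n), as.character(dataset$subject_id))
  Dk <- lapply(seq_len(ncol(X)), function(j) {
    dj <- outer(sx$X[, j], sx$X[, j], "-")
    dj * dj
  })
  names(Dk) <- fc
  list(Dk = Dk, gidx = gidx, n = n, features = fc,
       ages = dataset$age_years)
}

objective_for_target <- function(engine, y, cap = 10L, tol = 0.01,
                                 grid = gp_default_grid()) {
  ysd <- sd(y)
  if (ysd == 0) return(list(rmse = 0, subset = engine$features[1],
                            preds = y))
  ys <- (y - mean(y)) / ysd
  selected <- character(0)
  Dsum <- matrix(0, engine$n, engine$n)
  current <- Inf
  remaining <- engine$features
  while (length(selected) < cap && length(remaining) > 0) {
    scores <- vapply(remaining, function(f) {
      d <- length(selected) + 1L
      gp_logo_rmse(Dsum + engine$Dk[[f]], ys, engine$gidx, sqrt(d), 0.1)
    }, numeric(1))
    best <- which.min(scores)
    if (length(selected) > 0 && scores[best] >= current - tol) break
    selected <- c(selected, remaining[best])
    Dsum <- Dsum + engine$Dk[[remaining[best]]]
    current <- scores[best]
    remaining <- remaining[-best]
  }
  # grid-tuned LOSO residuals on the selected subset
  d <- length(selected)
  best <- NULL
  for (lm in grid$lengthscale_mult) {
    for (ns in grid$noise_sd) {
      res <- gp_logo_residuals(Dsum, ys, engine$gidx, lm * sqrt(d), ns)
      r <- sqrt(mean(res^2))
      if (is.null(best) || r < best$rmse) best <- list(rmse = r, res = res)
    }
  }
  list(rmse = best$rmse,           # on the standardized target (unitless)
       rmse_abs = best$rmse * ysd, # in the target's own units
       subset = selected,
       preds = (ys - best$res) * ysd + mean(y))
}

#' Objective of the biomarker search
#'
#' For feasible `(alpha, beta)`, every visit is assigned the target
#' `y_i = Y(age_i; alpha, beta)` and the leave-one-subject-out RMSE of GP
#' regression of `y` on the fingerprints (forward selection, capped subset)
#' is returned. The error is measured on the standardized target
#' (RMSE / sd(y)), which makes candidate curves with different dynamic
#' ranges over the observed ages comparable: otherwise the flattest
#' feasible curve would always win simply by having the smallest target
#' scale. Infeasible or invalid parameters receive a fixed penalty without
#' touching the data.
#'
#' @param alpha,beta curve parameters.
#' @param dataset a `cohort_dataset` of DMD visits with `age_years`.
#' @param cap forward-selection subset cap.
#' @param penalty value returned for infeasible parameters.
#' @return pooled scale-invariant LOSO RMSE (>= 0), or `penalty`.
#' @export
biomarker_objective <- function(alpha, beta, dataset, cap = 10L, penalty = 10) {
  ok <- tryCatch(check_feasibility(alpha, beta), error = function(e) NULL)
  if (is.null(ok) || !ok$feasible) return(penalty)
  engine <- biomarker_engine(dataset)
  y <- evaluate_biomarker(pmin(pmax(engine$ages, 0), 25), alpha, beta)
  objective_for_target(engine, y, cap = cap)$rmse
}

expected_improvement <- function(mu, sdev, f_best, xi = 0.01) {
  sdev <- pmax(sdev, 1e-12)
  z <- (f_best - mu - xi) / sdev
  (f_best - mu - xi) * pnorm(z) + sdev * dnorm(z)
}

#' Fit the progression biomarker by constrained Bayesian optimization
#'
#' Searches the `(alpha, beta)` box for the feasible curve whose targets
#' `Y(age)` are best predicted from the fingerprints (lowest LOSO GP
#' regression error). The initial design is a feasible space-filling
#' (Latin hypercube) sample; proposals are then chosen by maximising
#' expected improvement (exploration constant `xi = 0.01`) under a GP
#' surrogate fitted to the evaluated points, with candidates restricted
#' analytically to the feasible region. Runs until `budget` objective
#' evaluations have been spent.
#'
#' @param dataset a `cohort_dataset` of DMD visits (>= 8 subjects).
#' @param budget total number of objective evaluations (default 100).
#' @param seed integer seed.
#' @param n_init size of the initial design (default 10).
#' @param cap forward-selection cap inside the objective.
#' @param n_candidates candidate pool per acquisition step.
#' @return an object of class `kine_biomarker_curve`: `alpha`, `beta`,
#'   `objective`, `feasibility`, an age-grid `curve`, per-visit `fitted`
#'   scores, the selected feature `subset` and the optimization `trace`.
#' @export
optimize_biomarker <- function(dataset, budget = 100L, seed = 1L,
                               n_init = 10L, cap = 10L, n_candidates = 512L) {
  assert_that(length(unique(dataset$subject_id)) >= 8,
              "biomarker optimization needs >= 8 subjects")
  assert_that(budget > n_init, "`budget` must exceed the initial design size")
  engine <- biomarker_engine(dataset)
  box <- biomarker_box()
  ages <- pmin(pmax(engine$ages, 0), 25)
  eval_obj <- function(a, b) {
    y <- evaluate_biomarker(ages, a, b)
    objective_for_target(engine, y, cap = cap)$rmse
  }

  set.seed(derive_seed(seed, "bo-init"))
  init <- matrix(numeric(0), 0, 2)
  for (tries in seq_len(200)) {
    u <- lhs::randomLHS(2L * n_init, 2L)
    pts <- cbind(box$alpha[1] + u[, 1] * diff(box$alpha),
                 box$beta[1] + u[, 2] * diff(box$beta))
    feas <- apply(pts, 1, function(p) check_feasibility(p[1], p[2])$feasible)
    init <- rbind(init, pts[feas, , drop = FALSE])
    if (nrow(init) >= n_init) break
  }
  if (nrow(init) < n_init) {
    stop_arg("configuration error: no feasible initial design found after 200 resamples")
  }
  init <- init[seq_len(n_init), , drop = FALSE]

  pars <- init
  vals <- apply(init, 1, function(p) eval_obj(p[1], p[2]))
  phase <- rep("init", n_init)
  set.seed(derive_seed(seed, "bo-loop"))
  while (length(vals) < budget) {
    surrogate <- fit_gp(pars, vals,
                        grid = list(lengthscale_mult = c(0.5, 1, 2),
                                    noise_sd = c(0.01, 0.1)))
    cand <- NULL
    for (tries in seq_len(50)) {
      cc <- cbind(runif(n_candidates, box$alpha[1], box$alpha[2]),
                  runif(n_candidates, box$beta[1], box$beta[2]))
      feas <- apply(cc, 1, function(p) check_feasibility(p[1], p[2])$feasible)
      if (any(feas)) { cand <- cc[feas, , drop = FALSE]; break }
    }
    assert_that(!is.null(cand), "no feasible acquisition candidates found")
    pr <- predict(surrogate, cand, se = TRUE)
    ei <- expected_improvement(pr$mean, pr$sd, min(vals))
    nxt <- cand[which.max(ei), ]
    pars <- rbind(pars, nxt)
    vals <- c(vals, eval_obj(nxt[1], nxt[2]))
    phase <- c(phase, "bo")
  }

  best <- which.min(vals)
  alpha <- pars[best, 1]; beta <- pars[best, 2]
  y_best <- evaluate_biomarker(ages, alpha, beta)
  fit <- objective_for_target(engine, y_best, cap = cap)
  grid_ages <- seq(0, 25, by = 0.1)
  curve <- data.frame(age = grid_ages,
                      y = evaluate_biomarker(grid_ages, alpha, beta))
  out <- list(
    alpha = alpha, beta = beta,
    objective = vals[best], objective_abs = fit$rmse_abs,
    feasibility = check_feasibility(alpha, beta),
    x_min = -beta, x_max = 25 * alpha - beta,
    curve = curve,
    fitted = data.frame(subject_id = dataset$subject_id,
                        visit_id = dataset$visit_id,
                        age_years = dataset$age_years,
                        y_target = y_best, y_hat = fit$preds),
    subset = fit$subset,
    trace = data.frame(iteration = seq_along(vals), phase = phase,
                       alpha = pars[, 1], beta = pars[, 2],
                       objective = vals))
  class(out) <- "kine_biomarker_curve"
  out
}

#' @export
print.kine_biomarker_curve <- function(x, ...) {
  cat("<kine_biomarker_curve> alpha=", signif(x$alpha, 4),
      " beta=", signif(x$beta, 4),
      " LOSO RMSE=", signif(x$objective, 4), "\n",
      "  Y(5)=", signif(x$feasibility$y5, 3),
      "  Y(15)=", signif(x$feasibility$y15, 3),
      "  feasible=", x$feasibility$feasible, "\n", sep = "")
  invisible(x)
}
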