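#' Default hyperparameter grid for the GP
#'
#' Lengthscales are multiples of `sqrt(d)` (the natural scale of squared
#' Euclidean distances between z-scored d-dimensional features) and noise
#' standard deviations are on the standardized-target scale. The grid point
#' is chosen by the inner leave-one-subject-out RMSE.
#'
#' @return list with `lengthscale_mult` and `noise_sd` vectors (5 x 5 grid).
#' @export
gp_default_grid <- function() {
  list(lengthscale_mult = c(0.5, 1, 2, 4, 8),
       noise_sd = c(0.001, 0.01, 0.05, 0.1, 0.3))
}

standardize_cols <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

sq_dist <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

chol_jitter <- function(M) {
  jit <- 0
  for (j in c(0, 10^(-10:-2))) {
    L <- tryCatch(chol(M + diag(j, nrow(M))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- j
  }
  stop_arg("kernel matrix numerically singular even after jitter escalation")
}

# Exact block leave-one-group-out residuals of a GP with kernel matrix
# implied by D (squared distances), from a single factorisation:
# for group b, e_b = (Kinv[b,b])^{-1} (Kinv y)_b is the held-out residual.
gp_logo_residuals <- function(D, y, group_idx, lengthscale, noise_sd) {
  K <- exp(-D / (2 * lengthscale^2))
  diag(K) <- diag(K) + noise_sd^2
  Kinv <- chol2inv(chol_jitter(K))
  g <- Kinv %*% y
  res <- numeric(length(y))
  for (b in group_idx) {
    res[b] <- solve(Kinv[b, b, drop = FALSE], g[b, , drop = FALSE])
  }
  res
}

gp_logo_rmse <- function(D, y, group_idx, lengthscale, noise_sd) {
  sqrt(mean(gp_logo_residuals(D, y, group_idx, lengthscale, noise_sd)^2))
}

#' Fit a Gaussian-process regressor
#'
#' Squared-exponential kernel with isotropic lengthscale, unit signal
#' variance and additive white noise, on features and target standardized
#' with the training data. Unless hyperparameters are supplied, the
#' `(lengthscale, noise)` grid point minimizing the inner
#' leave-one-subject-out RMSE on the training data is selected (ordinary
#' leave-one-out when no groups are given).
#'
#' @param X training feature matrix (rows = observations).
#' @param y numeric target.
#' @param groups subject key per row for the inner LOSO; `NULL` for
#'   leave-one-out.
#' @param grid hyperparameter grid, see [gp_default_grid()].
#' @param lengthscale,noise_sd optional fixed hyperparameters (standardized
#'   scale), skipping the grid search.
#' @return an object of class `kine_gp` with a [predict()] method returning
#'   the predictive mean (and standard deviation with `se = TRUE`).
#' @export
fit_gp <- function(X, y, groups = NULL, grid = gp_default_grid(),
                   lengthscale = NULL, noise_sd = NULL) {
  X <- as.matrix(X)
  assert_that(nrow(X) >= 4, "GP fit needs >= 4 training rows")
  assert_that(all(is.finite(X)) && all(is.finite(y)), "features and target must be finite")
  sx <- standardize_cols(X)
  y_center <- mean(y)
  y_scale <- sd(y)
  if (y_scale == 0 || !is.finite(y_scale)) y_scale <- 1
  ys <- (y - y_center) / y_scale
  d <- ncol(X)
  if (is.null(lengthscale) || is.null(noise_sd)) {
    D <- sq_dist(sx$X)
    groups <- groups %||% seq_len(nrow(X))
    gidx <- split(seq_len(nrow(X)), groups)
    best <- NULL
    for (lm in grid$lengthscale_mult) {
      ls <- lm * sqrt(d)
      for (ns in grid$noise_sd) {
        r <- gp_logo_rmse(D, ys, gidx, ls, ns)
        if (is.null(best) || r < best$rmse) best <- list(ls = ls, ns = ns, rmse = r)
      }
    }
    lengthscale <- best$ls
    noise_sd <- best$ns
    inner_rmse <- best$rmse
  } else {
    inner_rmse <- NA_real_
  }
  K <- exp(-sq_dist(sx$X) / (2 * lengthscale^2))
  diag(K) <- diag(K) + noise_sd^2
  L <- chol_jitter(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  obj <- list(Xs = sx$X, x_center = sx$center, x_scale = sx$scale,
              y_center = y_center, y_scale = y_scale,
              L = L, alpha = alpha,
              lengthscale = lengthscale, noise_sd = noise_sd,
              inner_rmse = inner_rmse, features = colnames(X))
  class(obj) <- "kine_gp"
  obj
}

#' @rdname fit_gp
#' @param object a fitted `kine_gp`.
#' @param Xnew feature matrix of query points (same columns as training).
#' @param se also return the predictive standard deviation.
#' @param ... unused.
#' @export
predict.kine_gp <- function(object, Xnew, se = FALSE, ...) {
  Xnew <- as.matrix(Xnew)
  Xs <- sweep(sweep(Xnew, 2, object$x_center), 2, object$x_scale, "/")
  Ks <- exp(-sq_dist(Xs, object$Xs) / (2 * object$lengthscale^2))
  mu <- drop(Ks %*% object$alpha) * object$y_scale + object$y_center
  if (!se) return(mu)
  v <- forwardsolve(t(object$L), t(Ks))
  var_s <- pmax(1 + object$noise_sd^2 - colSums(v^2), 0)
  list(mean = mu, sd = sqrt(var_s) * object$y_scale)
}

#' @export
print.kine_gp <- function(x, ...) {
  cat("<kine_gp> n=", nrow(x$Xs), " d=", ncol(x$Xs),
      " lengthscale=", signif(x$lengthscale, 4),
      " noise_sd=", signif(x$noise_sd, 4), "\n", sep = "")
  invisible(x)
}
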