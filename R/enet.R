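#' Fit an elastic net age regression
#'
#' Minimizes the penalized least-squares objective
#' \deqn{\frac{1}{2N}\sum_{ij}(y_{ij}-\mu-x_{ij}^\top\beta)^2 +
#'   \lambda\left[\tfrac12(1-\alpha)\|\beta\|_2^2 + \alpha\|\beta\|_1\right]}
#' by cyclic coordinate descent in covariance form (compiled inner loop,
#' convergence when the largest coefficient change in a pass falls below
#' `tol`). `lambda` is the regularization constant and `alpha` the lasso
#' fraction; the problem is convex for fixed hyperparameters.
#'
#' With `standardize = TRUE` (default) columns are centered and scaled to
#' unit population standard deviation on the supplied data, coefficients are
#' reported on that standardized scale, and the transform is stored so
#' [predict.enet_fit()] accepts raw-scale data. Zero-variance columns keep
#' scale 1 (with a warning).
#'
#' @param X numeric predictor matrix (rows = pseudo-replicates).
#' @param y numeric response (chronological ages, years).
#' @param lambda regularization constant, `>= 0`.
#' @param alpha lasso fraction in `[0, 1]`.
#' @param standardize center/scale columns before fitting (default `TRUE`).
#' @param tol convergence tolerance on coefficient change (default 1e-6).
#' @param maxit maximum coordinate-descent passes.
#' @param beta_init optional warm-start coefficients (fitting scale).
#' @return An `enet_fit` with elements `mu` (intercept, years), `beta`
#'   (fitting-scale coefficients), `beta_raw`/`mu_raw` (raw-scale
#'   equivalents), `center`, `scale`, `lambda`, `alpha`, `iter`, `converged`.
#' @export
fit_enet <- function(X, y, lambda, alpha, standardize = TRUE,
                     tol = 1e-6, maxit = 100000L, beta_init = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    tc_abort("X and y must be finite", "enet")
  if (lambda < 0 || alpha < 0 || alpha > 1)
    tc_abort("need lambda >= 0 and alpha in [0, 1]", "enet")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n > 0)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (standardize) {
    scl <- sqrt(colMeans(Xc^2))
    zv <- scl == 0
    if (any(zv)) {
      warning(sprintf("%d zero-variance column(s) left unscaled", sum(zv)))
      scl[zv] <- 1
    }
    Xc <- sweep(Xc, 2, scl, "/")
  } else scl <- rep(1, p)
  ybar <- mean(y)
  yc <- y - ybar
  C <- crossprod(Xc) / n
  b <- drop(crossprod(Xc, yc)) / n
  beta0 <- beta_init %||% numeric(p)
  sol <- enet_cd(C, b, lambda, alpha, as.numeric(beta0), tol, as.integer(maxit))
  beta <- drop(sol$beta)
  names(beta) <- colnames(X)
  beta_raw <- beta / scl
  mu_raw <- ybar - sum(beta_raw * ctr)
  structure(list(mu = ybar, beta = beta, beta_raw = beta_raw, mu_raw = mu_raw,
                 center = ctr, scale = scl, lambda = lambda, alpha = alpha,
                 standardize = standardize, iter = sol$iter,
                 converged = sol$converged),
            class = "enet_fit")
}

#' @export
predict.enet_fit <- function(object, newX, ...) {
  newX <- as.matrix(newX)
  drop(newX %*% object$beta_raw) + object$mu_raw
}

#' @exportS3Method base::print
print.enet_fit <- function(x, ...) {
  cat("<enet_fit> lambda=", x$lambda, ", alpha=", x$alpha, "; ",
      sum(x$beta != 0), "/", length(x$beta), " nonzero coefficients\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.enet_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta) %||% paste0("x", seq_along(x$beta)),
                 estimate = as.numeric(x$beta),
                 estimate_raw = as.numeric(x$beta_raw))
}

#' Value of the elastic net objective
#'
#' Computes the penalized objective at given parameters on the data as
#' supplied (no internal standardization); used for convexity and oracle
#' checks.
#'
#' @param X,y data. @param mu intercept. @param beta coefficients.
#' @param lambda,alpha hyperparameters.
#' @return Numeric scalar.
#' @export
enet_objective <- function(X, y, mu, beta, lambda, alpha) {
  r <- y - mu - drop(as.matrix(X) %*% beta)
  sum(r^2) / (2 * length(y)) +
    lambda * ((1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta)))
}
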