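#' Elastic-net regularized logistic regression
#'
#' Fits a logistic regression with the elastic-net penalty by cyclic
#' coordinate descent on an iteratively reweighted least-squares (IRLS)
#' quadratic majorization — the objective minimized is
#'
#' \deqn{\frac{1}{n}\sum_i \log(1 + e^{-\tilde y_i (\beta_0 + x_i \beta)})
#'   + \lambda\left[\alpha \|\beta\|_1 +
#'   \frac{1-\alpha}{2}\|\beta\|_2^2\right]}
#'
#' with an unpenalized intercept, on standardized features; coefficients
#' are reported back on the original scale.  `alpha = 1` is the lasso,
#' `alpha = 0` ridge; the default `alpha = 0.5` mixes the two equally.
#'
#' @param X Numeric matrix (samples x features), no missing values (see
#'   [features_matrix()] for mean-imputation of a feature table).
#' @param y Binary response (0/1 or logical); both classes required.
#' @param lambda Penalty weight (>= 0).
#' @param alpha Elastic-net mixing fraction in `[0, 1]`.
#' @param standardize Standardize columns to zero mean / unit variance
#'   before fitting (default `TRUE`); constant columns keep coefficient 0.
#' @param max_iter Maximum IRLS iterations (divergence guard for perfectly
#'   separable data at `lambda = 0`); a warning is raised if reached.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param init Optional list with `intercept` and `beta` (standardized
#'   scale) used as a warm start.
#' @return Object of class `trg_enet`: list with `intercept`,
#'   `coefficients` (original scale, named), `lambda`, `alpha`,
#'   `standardization` (`center`, `scale`), `converged`, `iterations`.
#' @export
fit_enet_logistic <- function(X, y, lambda, alpha = 0.5, standardize = TRUE,
                              max_iter = 200, tol = 1e-7, init = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), lambda >= 0, alpha >= 0, alpha <= 1)
  if (!all(is.finite(X))) stop("fit_enet_logistic(): X contains non-finite values")
  if (length(unique(y)) < 2) stop("fit_enet_logistic(): y has a single class")
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  center <- if (standardize) colMeans(X) else rep(0, p)
  scl <- if (standardize) sqrt(colMeans(sweep(X, 2, center)^2)) else rep(1, p)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")

  beta <- if (!is.null(init)) init$beta else rep(0, p)
  b0 <- if (!is.null(init)) init$intercept else log(mean(y) / (1 - mean(y)))
  l1 <- lambda * alpha
  l2 <- lambda * (1 - alpha)

  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    beta_old <- beta; b0_old <- b0
    eta <- pmin(pmax(drop(b0 + Xs %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-5)
    z <- eta + (y - mu) / w
    # inner cyclic coordinate descent on the weighted quadratic, with the
    # usual active-set strategy: after a full sweep, iterate only over the
    # nonzero coordinates until stable, then confirm with a full sweep
    res <- z - b0 - drop(Xs %*% beta)
    sweep_coords <- function(coords) {
      delta <- 0
      for (j in coords) {
        r_j <- res + Xs[, j] * beta[j]
        num <- sum(w * Xs[, j] * r_j) / n
        den <- sum(w * Xs[, j]^2) / n + l2
        bj <- soft_threshold(num, l1) / den
        if (bj != beta[j]) {
          res <<- res - Xs[, j] * (bj - beta[j])
          delta <- max(delta, abs(bj - beta[j]))
          beta[j] <<- bj
        }
      }
      b0_new <- sum(w * (res + b0)) / sum(w)
      res <<- res - (b0_new - b0)
      delta <- max(delta, abs(b0_new - b0))
      b0 <<- b0_new
      delta
    }
    repeat {
      delta_full <- sweep_coords(seq_len(p))
      if (delta_full < tol) break
      repeat {
        active <- which(beta != 0)
        if (length(active) == 0) break
        if (sweep_coords(active) < tol) break
      }
    }
    if (max(abs(c(beta - beta_old, b0 - b0_old))) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("fit_enet_logistic() reached max_iter = ", max_iter,
            " without converging (possible separation at small lambda)")
  }
  eta_final <- drop(b0 + Xs %*% beta)
  if (l1 == 0 && l2 == 0 && max(abs(eta_final)) >= 30 - 1e-6) {
    warning("fit_enet_logistic(): fitted probabilities saturated at ",
            "lambda = 0 (perfect or quasi-perfect separation); the linear ",
            "predictor is capped and coefficients are not maximum likelihood")
  }
  coef_orig <- beta / scl
  structure(list(
    intercept = b0 - sum(coef_orig * center),
    coefficients = stats::setNames(coef_orig, colnames(X)),
    beta_standardized = stats::setNames(beta, colnames(X)),
    intercept_standardized = b0,
    lambda = lambda, alpha = alpha,
    standardization = list(center = center, scale = scl),
    converged = converged, iterations = iter, n = n
  ), class = "trg_enet")
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Penalized elastic-net logistic objective
#'
#' Average logistic deviance plus the elastic-net penalty, as minimized by
#' [fit_enet_logistic()].  Evaluated on whatever scale `X` and `beta`
#' share, so tests can compare solutions in standardized space.
#'
#' @param X Feature matrix.
#' @param y Binary response.
#' @param intercept,beta Parameters at which to evaluate.
#' @param lambda,alpha Penalty parameters.
#' @return Scalar objective value.
#' @export
enet_objective <- function(X, y, intercept, beta, lambda, alpha) {
  eta <- drop(intercept + as.matrix(X) %*% beta)
  yt <- ifelse(y == 1, 1, -1)
  mean(log1p(exp(-yt * eta))) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' @export
predict.trg_enet <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- drop(object$intercept + as.matrix(newdata) %*% object$coefficients)
  if (type == "response") 1 / (1 + exp(-eta)) else eta
}

#' @export
print.trg_enet <- function(x, ...) {
  nz <- sum(x$beta_standardized != 0)
  cat("Elastic-net logistic regression (alpha =", x$alpha,
      ", lambda =", format(x$lambda, digits = 4), ")\n",
      nz, "of", length(x$coefficients), "coefficients nonzero;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "IRLS iterations\n")
  invisible(x)
}

#' Default log-spaced lambda grid
#'
#' 50 values descending from the smallest lambda that shrinks every
#' coefficient to zero (`lambda_max = max |<x_j, y - mean(y)>| / (n alpha)`
#' on standardized features, with `alpha` floored at 0.001 so ridge-like
#' mixes still get a finite grid) down four decades.
#'
#' @inheritParams fit_enet_logistic
#' @param n_lambda Grid length (default 50).
#' @param decades How far below `lambda_max` to extend (default 4).
#' @return Decreasing numeric vector.
#' @export
enet_lambda_grid <- function(X, y, alpha = 0.5, n_lambda = 50, decades = 4) {
  X <- as.matrix(X); y <- as.numeric(y)
  center <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, center)^2))
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) /
    (nrow(X) * max(alpha, 0.001))
  10^seq(log10(lambda_max), log10(lambda_max) - decades,
         length.out = n_lambda)
}

# fit a decreasing lambda path with warm starts
fit_enet_path <- function(X, y, lambdas, alpha = 0.5, ...) {
  fits <- vector("list", length(lambdas))
  init <- NULL
  for (i in seq_along(lambdas)) {
    fits[[i]] <- fit_enet_logistic(X, y, lambdas[i], alpha, init = init, ...)
    init <- list(intercept = fits[[i]]$intercept_standardized,
                 beta = fits[[i]]$beta_standardized)
  }
  fits
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.trg_enet <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @export
glance.trg_enet <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, alpha = x$alpha,
                 n_nonzero = sum(x$beta_standardized != 0),
                 converged = x$converged, iterations = x$iterations,
                 nobs = x$n)
}
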