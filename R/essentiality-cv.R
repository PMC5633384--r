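#' Cross-validated ROC AUC for the essentiality classifier
#'
#' Stratified k-fold cross-validation of the elastic-net logistic
#' classifier over a lambda grid.  For each lambda the out-of-fold scores
#' from all folds are pooled into a single ROC and one AUC computed;
#' `chosen_lambda` maximizes this pooled AUC (ties resolved toward the
#' larger, i.e. more regularized, lambda).  A final model is refit on the
#' full data at the chosen lambda.
#'
#' @inheritParams fit_enet_logistic
#' @param k_folds Number of stratified folds (default 5); each class must
#'   have at least `k_folds` members.
#' @param lambda_grid Decreasing lambda grid; [enet_lambda_grid()] on the
#'   full data when `NULL`.
#' @param seed Integer seed controlling the fold shuffle; identical seeds
#'   give identical reports.
#' @return Object of class `trg_cv`: list with `grid` (tibble `lambda`,
#'   `auc`), `chosen_lambda`, `cv_auc`, `fold_assignments` (tibble `row`,
#'   `fold`), `oof_scores` (matrix rows x lambdas), `model` (the refit
#'   `trg_enet`), `alpha`, `k_folds`, `seed`.
#' @export
cross_validated_auc <- function(X, y, k_folds = 5, lambda_grid = NULL,
                                alpha = 0.5, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (min(table(y)) < k_folds) {
    stop("cross_validated_auc(): each class needs at least k_folds = ",
         k_folds, " members to stratify")
  }
  if (is.null(lambda_grid)) lambda_grid <- enet_lambda_grid(X, y, alpha)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  folds <- stratified_folds(y, k_folds, seed)
  oof <- matrix(NA_real_, nrow(X), length(lambda_grid))
  for (f in seq_len(k_folds)) {
    test <- folds == f
    fits <- fit_enet_path(X[!test, , drop = FALSE], y[!test],
                          lambda_grid, alpha)
    for (i in seq_along(fits)) {
      oof[test, i] <- predict(fits[[i]], X[test, , drop = FALSE])
    }
  }
  aucs <- apply(oof, 2, roc_auc, labels = y)
  best <- which(aucs >= max(aucs) - 1e-12)[1]  # first = largest lambda
  structure(list(
    grid = tibble::tibble(lambda = lambda_grid, auc = aucs),
    chosen_lambda = lambda_grid[best],
    cv_auc = aucs[best],
    fold_assignments = tibble::tibble(row = seq_along(y), fold = folds),
    oof_scores = oof,
    model = fit_enet_logistic(X, y, lambda_grid[best], alpha),
    alpha = alpha, k_folds = k_folds, seed = seed
  ), class = "trg_cv")
}

# deterministic stratified fold assignment from a seeded shuffle
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' @export
print.trg_cv <- function(x, ...) {
  cat("Cross-validated elastic-net classifier (alpha =", x$alpha,
      ",", x$k_folds, "folds, seed", x$seed, ")\n",
      "chosen lambda =", format(x$chosen_lambda, digits = 4),
      "; pooled out-of-fold AUC =", round(x$cv_auc, 4), "\n")
  invisible(x)
}

#' @export
tidy.trg_cv <- function(x, ...) x$grid

#' @export
glance.trg_cv <- function(x, ...) {
  tibble::tibble(cv_auc = x$cv_auc, chosen_lambda = x$chosen_lambda,
                 alpha = x$alpha, k_folds = x$k_folds, seed = x$seed,
                 n_lambda = nrow(x$grid))
}

#' Single-feature cross-validated AUC ranking
#'
#' Fits a univariate (unpenalized) logistic regression per feature under
#' the same stratified folds and reports the pooled out-of-fold AUC for
#' each, sorted descending (ties kept in column-name order).  This ranks
#' how informative each pathway feature is on its own.
#'
#' @inheritParams cross_validated_auc
#' @return Tibble with columns `feature`, `cv_auc`, `rank`.
#' @export
single_feature_auc <- function(X, y, k_folds = 5, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (min(table(y)) < k_folds) {
    stop("single_feature_auc(): each class needs at least k_folds members")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  folds <- stratified_folds(y, k_folds, seed)
  aucs <- vapply(seq_len(ncol(X)), function(j) {
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(k_folds)) {
      test <- folds == f
      # separation warnings are irrelevant here: only the rank order of
      # the out-of-fold scores enters the AUC
      fit <- suppressWarnings(
        fit_enet_logistic(X[!test, j, drop = FALSE], y[!test], lambda = 0))
      oof[test] <- predict(fit, X[test, j, drop = FALSE])
    }
    roc_auc(oof, y)
  }, numeric(1))
  ord <- order(-aucs, colnames(X), method = "radix")
  tibble::tibble(feature = colnames(X)[ord], cv_auc = aucs[ord],
                 rank = seq_along(ord))
}
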