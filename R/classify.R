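# Standardization to mean 0, population sd 1 (divisor n). Constant columns
# are mapped to all-zero so their coefficients are pinned at zero.
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  list(mean = mu, sd = sd)
}

standardize_apply <- function(X, std) {
  sd <- ifelse(std$sd > 0, std$sd, 1)
  Xs <- sweep(sweep(X, 2L, std$mean), 2L, sd, "/")
  if (any(std$sd == 0)) Xs[, std$sd == 0] <- 0
  Xs
}

#' Smallest lambda with an all-zero lasso solution
#'
#' The KKT threshold `max_j |<x_j, y - mean(y)>| / n` on standardized
#' columns: at or above it, the penalized logistic fit keeps every
#' coefficient at zero and the intercept at the log-odds of the prevalence.
#'
#' @param X raw feature matrix (standardized internally).
#' @param y binary 0/1 labels.
#' @return The threshold lambda.
#' @export
lambda_max <- function(X, y) {
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  max(abs(crossprod(Xs, y - mean(y)))) / nrow(X)
}

lambda_grid_default <- function(lmax, n_lambda = 50L, min_ratio = 1e-3) {
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Fit a lasso-penalized logistic regression
#'
#' Minimizes the mean negative log-likelihood plus `lambda` times the L1
#' norm of the coefficients, over standardized features with an unpenalized
#' intercept, by IRLS + coordinate descent to objective tolerance 1e-8.
#' Coefficients are reported on the standardized scale. The solver is
#' deterministic: identical inputs give bit-identical fits.
#'
#' @param X rows x features numeric matrix (raw scale).
#' @param y binary labels: 0/1 vector, or a factor/character vector whose
#'   `"RA"` level codes 1.
#' @param lambda non-negative penalty.
#' @return An object of class `lasso_fit` with `lambda`, `intercept`,
#'   `coefficients` (named, standardized scale), `standardization`.
#' @export
fit_lasso_logistic <- function(X, y, lambda) {
  X <- as.matrix(X)
  y <- binarize_labels(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  if (lambda < 0) stop("lambda must be non-negative")
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  fit <- lasso_logit_path_cpp(Xs, y, lambda, tol = 1e-8)
  beta <- fit$beta[, 1L]
  names(beta) <- colnames(X)
  structure(list(lambda = lambda, intercept = fit$intercept[1L],
                 coefficients = beta, standardization = std),
            class = "lasso_fit")
}

binarize_labels <- function(y) {
  if (is.numeric(y)) {
    stopifnot(all(y %in% c(0, 1)))
    as.numeric(y)
  } else {
    as.numeric(as.character(y) == "RA")
  }
}

#' Predicted class-1 probabilities from a lasso fit
#'
#' @param fit a `lasso_fit`.
#' @param X new data on the raw feature scale.
#' @return Numeric vector of probabilities.
#' @export
predict_lasso <- function(fit, X) {
  Xs <- standardize_apply(as.matrix(X), fit$standardization)
  eta <- drop(fit$intercept + Xs %*% fit$coefficients)
  1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * (y * log(p) + (1 - y) * log(1 - p))
}

# Fit the path on (X[rows,], y[rows]) and return held-out probabilities of
# each row in `predict_rows` at every lambda.
path_heldout_probs <- function(Xs, y, lambdas, predict_Xs) {
  fit <- lasso_logit_path_cpp(Xs, y, lambdas, tol = 1e-8)
  eta <- sweep(predict_Xs %*% fit$beta, 2L, fit$intercept, "+")
  1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
}

impute_train_median <- function(Xna, train_rows) {
  med <- apply(Xna[train_rows, , drop = FALSE], 2L, stats::median,
               na.rm = TRUE)
  med[is.na(med)] <- 0
  X <- Xna
  for (j in which(colSums(is.na(X)) > 0))
    X[is.na(X[, j]), j] <- med[j]
  X
}

#' Rank-based AUC
#'
#' Mann-Whitney formulation: ties between a class-1 and a class-0 score
#' count one half.
#'
#' @param y binary 0/1 labels.
#' @param p scores.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(y, p) {
  y <- binarize_labels(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Double leave-one-out cross-validation of the lasso classifier
#'
#' Outer loop: each individual is held out in turn. Inner loop: on the
#' remaining n-1 individuals, leave-one-out binomial deviance selects the
#' penalty from a 50-value log-spaced grid computed from that outer
#' training set (ties toward the larger penalty). Standardization,
#' median-imputation references, penalty selection and the final fold model
#' are all computed strictly without the held-out row, which is then scored.
#'
#' @param table a `feature_table`.
#' @param lambda_grid optional fixed penalty grid (decreasing); by default
#'   a per-fold grid of `n_lambda` values down to
#'   `lambda_min_ratio * lambda_max`.
#' @param n_lambda,lambda_min_ratio grid shape parameters.
#' @return An object of class `cv_report`: per-individual held-out
#'   probabilities, predicted labels (threshold 0.5, ties to HD),
#'   per-group confusion counts, `cv_accuracy`, `auc`,
#'   `selected_lambda_per_fold`, and per-fold coefficient vectors.
#' @export
double_loocv <- function(table, lambda_grid = NULL, n_lambda = 50L,
                         lambda_min_ratio = 1e-3) {
  y <- binarize_labels(table$labels)
  if (sum(y == 1) < 3L || sum(y == 0) < 3L)
    stop("need at least 3 individuals per class")
  Xna <- table$matrix
  Xna[table$missing] <- NA_real_
  n <- nrow(Xna)

  probs <- numeric(n)
  sel_lambda <- numeric(n)
  fold_coefs <- vector("list", n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    Ximp <- impute_train_median(Xna, train)
    Xtr <- Ximp[train, , drop = FALSE]
    ytr <- y[train]
    grid <- if (is.null(lambda_grid)) {
      lambda_grid_default(lambda_max(Xtr, ytr), n_lambda, lambda_min_ratio)
    } else sort(lambda_grid, decreasing = TRUE)

    dev <- loocv_deviance_cpp(Xtr, ytr, grid, tol = 1e-6)
    mean_dev <- colMeans(dev)
    best <- which(mean_dev <= min(mean_dev) + 1e-12)[1L]  # ties: larger lambda
    sel_lambda[i] <- grid[best]

    std <- standardize_fit(Xtr)
    Xs <- standardize_apply(Xtr, std)
    fit <- lasso_logit_path_cpp(Xs, ytr, grid[seq_len(best)], tol = 1e-8)
    beta <- fit$beta[, best]
    names(beta) <- colnames(Xna)
    fold_coefs[[i]] <- beta
    Xs_te <- standardize_apply(Ximp[i, , drop = FALSE], std)
    eta <- fit$intercept[best] + drop(Xs_te %*% beta)
    probs[i] <- 1 / (1 + exp(-min(max(eta, -30), 30)))
  }

  predicted <- ifelse(probs > 0.5, "RA", "HD")  # exact 0.5 -> HD
  truth <- ifelse(y == 1, "RA", "HD")
  confusion <- table(truth = factor(truth, c("HD", "RA")),
                     predicted = factor(predicted, c("HD", "RA")))
  report <- structure(list(
    individuals = table$individuals, truth = truth,
    probabilities = probs, predicted = predicted, confusion = confusion,
    cv_accuracy = mean(predicted == truth),
    auc = rank_auc(y, probs),
    selected_lambda_per_fold = sel_lambda,
    fold_coefficients = fold_coefs,
    model = table$model), class = "cv_report")
  if (all(vapply(fold_coefs, function(b) all(b == 0), TRUE)))
    warning("all folds selected an all-zero (intercept-only) model")
  report
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%s model): accuracy %.3f, AUC %.3f\n",
              x$model, x$cv_accuracy, x$auc))
  print(x$confusion)
  invisible(x)
}

#' Final non-zero coefficients
#'
#' Selects the penalty by full-cohort leave-one-out deviance, refits on all
#' individuals, and returns the non-zero coefficients (standardized scale)
#' in descending absolute value, joined to their feature descriptors.
#'
#' @inheritParams double_loocv
#' @return list with `lambda`, `fit` (the full-cohort `lasso_fit`), and
#'   `nonzero` (data.frame of descriptors plus `coefficient`).
#' @export
final_nonzero_coefficients <- function(table, lambda_grid = NULL,
                                       n_lambda = 50L,
                                       lambda_min_ratio = 1e-3) {
  y <- binarize_labels(table$labels)
  Xna <- table$matrix
  Xna[table$missing] <- NA_real_
  n <- nrow(Xna)
  Ximp <- impute_train_median(Xna, seq_len(n))
  grid <- if (is.null(lambda_grid)) {
    lambda_grid_default(lambda_max(Ximp, y), n_lambda, lambda_min_ratio)
  } else sort(lambda_grid, decreasing = TRUE)

  if (any(is.na(Xna))) {
    dev <- matrix(NA_real_, n, length(grid))
    for (jj in seq_len(n)) {
      train <- setdiff(seq_len(n), jj)
      Xi <- impute_train_median(Xna, train)
      std <- standardize_fit(Xi[train, , drop = FALSE])
      Xs <- standardize_apply(Xi[train, , drop = FALSE], std)
      Xs_out <- standardize_apply(Xi[jj, , drop = FALSE], std)
      p <- path_heldout_probs(Xs, y[train], grid, Xs_out)
      dev[jj, ] <- binomial_deviance(y[jj], p)
    }
  } else {
    dev <- loocv_deviance_cpp(Ximp, y, grid, tol = 1e-6)
  }
  mean_dev <- colMeans(dev)
  best <- which(mean_dev <= min(mean_dev) + 1e-12)[1L]
  lambda <- grid[best]

  std <- standardize_fit(Ximp)
  Xs <- standardize_apply(Ximp, std)
  fit <- lasso_logit_path_cpp(Xs, y, grid[seq_len(best)], tol = 1e-8)
  beta <- fit$beta[, best]
  names(beta) <- colnames(Ximp)
  nz <- which(beta != 0)
  nz <- nz[order(-abs(beta[nz]))]
  nonzero <- cbind(table$descriptors[nz, , drop = FALSE],
                   coefficient = unname(beta[nz]))
  rownames(nonzero) <- NULL
  lasso <- structure(list(lambda = lambda, intercept = fit$intercept[best],
                          coefficients = beta, standardization = std),
                     class = "lasso_fit")
  list(lambda = lambda, fit = lasso, nonzero = nonzero)
}

#' PCA of selected features
#'
#' Principal component analysis of the standardized selected feature
#' columns; the first two component scores separate the groups when the
#' selected features carry group signal.
#'
#' @param table a `feature_table`.
#' @param selected feature column names (or indices); at least 2.
#' @return list with `scores` (individuals x 2, with group labels as
#'   attribute), `explained_variance` (fractions for PC1 and PC2).
#' @export
pca_selected <- function(table, selected) {
  if (length(selected) < 2L) stop("need at least 2 selected features")
  X <- table$matrix[, selected, drop = FALSE]
  keep <- apply(X, 2L, stats::sd) > 0
  if (sum(keep) < 2L) stop("fewer than 2 non-constant selected features")
  pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, 1:2, drop = FALSE]
  rownames(scores) <- table$individuals
  attr(scores, "group") <- table$labels
  list(scores = scores, explained_variance = ev[1:2])
}
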