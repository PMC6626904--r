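test_that("at lambda_max and beyond, all coefficients are exactly zero", {
  set.seed(51)
  X <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c(0, 1), c(12, 18))
  lmax <- lambda_max(X, y)
  for (lam in c(lmax, 2 * lmax)) {
    fit <- fit_lasso_logistic(X, y, lam)
    expect_true(all(fit$coefficients == 0))
    expect_equal(fit$intercept, log(0.6 / 0.4), tolerance = 1e-8)
  }
  # just below lambda_max, at least one coefficient activates
  fit2 <- fit_lasso_logistic(X, y, lmax * 0.95)
  expect_gt(sum(fit2$coefficients != 0), 0)
})

test_that("the 6x2 fixture matches an independent optimizer oracle", {
  # printed fixture
  X <- matrix(c(0.2, -1.1, 0.8, 1.7, -0.4, 0.6,
                -0.9, 0.3, 1.2, -0.5, 0.1, 1.4), 6, 2,
              dimnames = list(NULL, c("a", "b")))
  y <- c(0, 0, 0, 1, 1, 1)
  lambda <- 0.1
  fit <- fit_lasso_logistic(X, y, lambda)

  std <- cytofps:::standardize_fit(X)
  Xs <- cytofps:::standardize_apply(X, std)
  obj <- function(par) {
    eta <- par[1] + Xs %*% par[2:3]
    mean(log1p(exp(eta)) - y * eta) + lambda * sum(abs(par[2:3]))
  }
  mine <- obj(c(fit$intercept, fit$coefficients))
  orac <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                       control = list(maxit = 50000, reltol = 1e-14))$value
  expect_lte(mine, orac + 1e-5)
  expect_equal(mine, orac, tolerance = 1e-5)
})

test_that("our path solver attains glmnet's objective values", {
  set.seed(52)
  X <- matrix(rnorm(40 * 25), 40, 25)
  y <- rep(c(0, 1), each = 20)
  std <- cytofps:::standardize_fit(X)
  Xs <- cytofps:::standardize_apply(X, std)
  lmax <- lambda_max(X, y)
  grid <- cytofps:::lambda_grid_default(lmax, 30, 1e-2)
  fit <- cytofps:::lasso_logit_path_cpp(Xs, y, grid, tol = 1e-8)
  gn <- glmnet::glmnet(Xs, y, family = "binomial", lambda = grid,
                       standardize = FALSE, thresh = 1e-12)
  obj <- function(b0, b, lam) {
    eta <- b0 + Xs %*% b
    mean(log1p(exp(eta)) - y * eta) + lam * sum(abs(b))
  }
  for (l in c(5, 15, 25)) {
    mine <- obj(fit$intercept[l], fit$beta[, l], grid[l])
    theirs <- obj(gn$a0[l], as.numeric(gn$beta[, l]), grid[l])
    expect_equal(mine, theirs, tolerance = 1e-6)
    expect_lte(mine, theirs + 1e-7)
  }
})

test_that("duplicating a feature column leaves predictions unchanged", {
  set.seed(53)
  X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c(0, 1), each = 15)
  Xdup <- cbind(X, f1b = X[, 1])
  lam <- 0.5 * lambda_max(X, y)
  p1 <- predict_lasso(fit_lasso_logistic(X, y, lam), X)
  p2 <- predict_lasso(fit_lasso_logistic(Xdup, y, lam), Xdup)
  expect_equal(p1, p2, tolerance = 1e-5)
})

test_that("deterministic solver: identical inputs, bit-identical fits", {
  set.seed(54)
  X <- matrix(rnorm(24 * 10), 24, 10)
  y <- rep(c(0, 1), each = 12)
  f1 <- fit_lasso_logistic(X, y, 0.05)
  f2 <- fit_lasso_logistic(X, y, 0.05)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$intercept, f2$intercept)
})

test_that("degenerate inputs error as specified", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_lasso_logistic(X, rep(1, 10), 0.1), "both classes")
  expect_error(fit_lasso_logistic(X, rep(c(0, 1), 5), -1), "non-negative")
})

test_that("rank AUC counts ties one half", {
  y <- c(0, 0, 1, 1)
  expect_equal(rank_auc(y, c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(rank_auc(y, c(0.9, 0.8, 0.2, 0.1)), 0)
  expect_equal(rank_auc(y, c(0.5, 0.5, 0.5, 0.5)), 0.5)
  expect_equal(rank_auc(c(0, 1), c(0.3, 0.3)), 0.5)
})

test_that("a perfectly separating feature yields accuracy and AUC 1", {
  set.seed(55)
  n <- 12
  X <- cbind(sep = rep(c(-2, 2), each = n / 2) + rnorm(n, 0, 0.1),
             noise = rnorm(n))
  rownames(X) <- sprintf("I%02d", 1:n)
  ft <- wrap_feature_table(X, rep(c("HD", "RA"), each = n / 2))
  cv <- double_loocv(ft)
  expect_equal(cv$cv_accuracy, 1)
  expect_equal(cv$auc, 1)
  expect_equal(sum(cv$confusion), n)
})

test_that("cv report is self-consistent with its stored probabilities", {
  set.seed(56)
  n <- 12
  X <- cbind(a = rnorm(n, rep(c(0, 1.2), each = n / 2)),
             b = rnorm(n), c = rnorm(n))
  rownames(X) <- sprintf("I%02d", 1:n)
  ft <- wrap_feature_table(X, rep(c("HD", "RA"), each = n / 2))
  cv <- double_loocv(ft)
  expect_equal(cv$cv_accuracy,
               mean(ifelse(cv$probabilities > 0.5, "RA", "HD") == cv$truth))
  expect_equal(cv$auc,
               rank_auc(as.numeric(cv$truth == "RA"), cv$probabilities))
  expect_equal(sum(cv$confusion), n)
})

test_that("outer folds are leakage-free: perturbing one row leaves the rest", {
  set.seed(57)
  n <- 10
  X <- cbind(a = rnorm(n, rep(c(0, 1.5), each = n / 2)),
             b = rnorm(n), c = rnorm(n))
  rownames(X) <- sprintf("I%02d", 1:n)
  ft <- wrap_feature_table(X, rep(c("HD", "RA"), each = n / 2))
  cv1 <- double_loocv(ft)
  ft2 <- ft
  ft2$matrix[3, ] <- ft2$matrix[3, ] + 100
  cv2 <- double_loocv(ft2)
  # fold 3's model is fitted strictly without row 3: bit-identical model,
  # changed prediction
  expect_identical(cv1$selected_lambda_per_fold[3],
                   cv2$selected_lambda_per_fold[3])
  expect_identical(cv1$fold_coefficients[[3]], cv2$fold_coefficients[[3]])
  expect_false(identical(cv1$probabilities[3], cv2$probabilities[3]))
})

test_that("final refit returns nonzero coefficients in |coef| order", {
  set.seed(58)
  n <- 16
  X <- cbind(sig = rep(c(0, 2), each = n / 2) + rnorm(n, 0, 0.3),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  rownames(X) <- sprintf("I%02d", 1:n)
  ft <- wrap_feature_table(X, rep(c("HD", "RA"), each = n / 2))
  fin <- final_nonzero_coefficients(ft)
  expect_true("sig" %in% fin$nonzero$name)
  expect_equal(fin$nonzero$coefficient,
               fin$nonzero$coefficient[order(-abs(fin$nonzero$coefficient))])
  expect_true(all(fin$nonzero$coefficient != 0))
  expect_equal(fin$fit$coefficients[fin$nonzero$name[1]],
               stats::setNames(fin$nonzero$coefficient[1],
                               fin$nonzero$name[1]))
})

test_that("pca of selected features behaves per contract", {
  set.seed(59)
  n <- 10
  base <- rnorm(n)
  X <- cbind(a = base, b = 2 * base + 3, c = rnorm(n))
  rownames(X) <- sprintf("I%02d", 1:n)
  ft <- wrap_feature_table(X, rep(c("HD", "RA"), each = n / 2))
  # two perfectly correlated features: PC1 explains everything
  pc <- pca_selected(ft, c("a", "b"))
  expect_equal(pc$explained_variance[1], 1, tolerance = 1e-12)
  # order invariance up to sign
  pc2 <- pca_selected(ft, c("b", "a"))
  expect_equal(abs(pc$scores[, 1]), abs(pc2$scores[, 1]), tolerance = 1e-9)
  expect_error(pca_selected(ft, "a"), "at least 2")
})
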