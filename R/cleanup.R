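#' Mean-variance scale the QC channels
#'
#' Standardizes each of the seven QC channels to mean 0 and population
#' standard deviation 1 (divisor n, not n-1), recording the scaling so it
#' can be re-applied.
#'
#' @param table an `event_table` containing all QC channels.
#' @return list with `matrix` (events x q standardized values) and
#'   `scaling` (data.frame of per-channel mean and sd).
#' @export
scale_qc <- function(table) {
  qc_ch <- panel_channels(table$panel, "qc")
  m <- table$values[, qc_ch, drop = FALSE]
  mu <- colMeans(m)
  sd <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  zero <- qc_ch[sd == 0]
  if (length(zero))
    stop("ZeroVariance: qc channel(s) with zero variance: ",
         paste(zero, collapse = ", "))
  scaled <- sweep(sweep(m, 2L, mu), 2L, sd, "/")
  list(matrix = scaled,
       scaling = data.frame(channel = qc_ch, mean = mu, sd = sd,
                            row.names = NULL))
}

mvn_logdens <- function(X, mu, sigma) {
  q <- ncol(X)
  R <- chol(sigma)
  Y <- sweep(X, 2L, mu)
  Z <- Y %*% backsolve(R, diag(q))
  -0.5 * q * log(2 * pi) - sum(log(diag(R))) - 0.5 * rowSums(Z^2)
}

#' Fit a two-component Gaussian mixture
#'
#' EM with full covariance matrices on mean-variance scaled QC data.
#' Initialization is a seeded k-means split; each M-step covariance gets a
#' diagonal ridge of 1e-6 so the fit never degenerates. The log-likelihood
#' trace is recorded and is non-decreasing.
#'
#' @param scaled standardized events x q matrix (from [scale_qc()]).
#' @param seed integer seed for the k-means initialization.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood change below which EM stops.
#' @return An object of class `gmm_fit` with `weights`, `means`,
#'   `covariances`, `converged`, `loglik_trace`.
#' @export
fit_gmm2 <- function(scaled, seed = 1L, max_iter = 200L, tol = 1e-8) {
  scaled <- as.matrix(scaled)
  if (!all(is.finite(scaled))) stop("non-finite values in scaled qc matrix")
  n <- nrow(scaled); q <- ncol(scaled)
  if (n < 2 * q + 2)
    stop("need at least ", 2 * q + 2, " events to fit a 2-component mixture")
  ridge <- 1e-6 * diag(q)

  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(scaled, centers = 2L, nstart = 3L,
                                       iter.max = 50L))
  resp <- cbind(as.numeric(km$cluster == 1L), as.numeric(km$cluster == 2L))

  weights <- numeric(2); means <- matrix(0, 2, q)
  covs <- vector("list", 2)
  loglik_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    nk <- colSums(resp)
    weights <- nk / n
    for (k in 1:2) {
      means[k, ] <- colSums(scaled * resp[, k]) / nk[k]
      Y <- sweep(scaled, 2L, means[k, ])
      covs[[k]] <- crossprod(Y * resp[, k], Y) / nk[k] + ridge
    }
    ld <- cbind(log(weights[1]) + mvn_logdens(scaled, means[1, ], covs[[1]]),
                log(weights[2]) + mvn_logdens(scaled, means[2, ], covs[[2]]))
    mx <- pmax(ld[, 1], ld[, 2])
    lse <- mx + log(exp(ld[, 1] - mx) + exp(ld[, 2] - mx))
    loglik <- sum(lse)
    resp <- exp(ld - lse)
    loglik_trace <- c(loglik_trace, loglik)
    if (iter > 1L) {
      prev <- loglik_trace[iter - 1L]
      if (abs(loglik - prev) < tol * (abs(prev) + tol)) {
        converged <- TRUE
        break
      }
    }
  }
  structure(list(weights = weights, means = means, covariances = covs,
                 converged = converged, loglik_trace = loglik_trace,
                 scaling = NULL),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: weights %.3f/%.3f, %d EM iterations, %s\n",
              x$weights[1], x$weights[2], length(x$loglik_trace),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

gmm_posteriors <- function(fit, scaled) {
  ld <- cbind(log(fit$weights[1]) +
                mvn_logdens(scaled, fit$means[1, ], fit$covariances[[1]]),
              log(fit$weights[2]) +
                mvn_logdens(scaled, fit$means[2, ], fit$covariances[[2]]))
  mx <- pmax(ld[, 1], ld[, 2])
  lse <- mx + log(exp(ld[, 1] - mx) + exp(ld[, 2] - mx))
  exp(ld - lse)
}

#' Remove the smaller mixture component
#'
#' Assigns every event to a component by maximum posterior and removes all
#' events of the component with the smaller mixing weight (doublets and
#' debris). If the weights tie exactly, the component with the larger total
#' posterior mass is the one kept.
#'
#' @param table the `event_table` the fit was computed from.
#' @param fit a `gmm_fit` on this table's scaled QC matrix.
#' @return list with `kept` (filtered `event_table`), `kept_index` (row
#'   indices kept) and `report` (kept/discarded counts, weights,
#'   convergence flag).
#' @export
filter_events <- function(table, fit) {
  sc <- scale_qc(table)
  post <- gmm_posteriors(fit, sc$matrix)
  assign <- max.col(post, ties.method = "first")
  if (fit$weights[1] != fit$weights[2]) {
    smaller <- which.min(fit$weights)
  } else {
    smaller <- which.min(colSums(post))
  }
  keep <- assign != smaller
  if (fit$weights[smaller] < 0.001)
    message(sprintf(
      "cleanup [%s %s]: smaller component weight %.5f (<0.1%%); removed anyway",
      table$individual_id, table$condition, fit$weights[smaller]))
  kept <- table
  kept$values <- table$values[keep, , drop = FALSE]
  report <- data.frame(
    individual_id = table$individual_id, group = table$group,
    condition = table$condition, n_total = nrow(table$values),
    n_kept = sum(keep), n_discarded = sum(!keep),
    weight_kept = fit$weights[3L - smaller],
    weight_discarded = fit$weights[smaller],
    converged = fit$converged, stringsAsFactors = FALSE)
  list(kept = kept, kept_index = which(keep), report = report)
}

#' Clean every sample of a cohort
#'
#' Fits the two-component QC mixture per sample (per individual and
#' condition) and removes each sample's smaller component independently.
#'
#' @param tables list of raw `event_table`.
#' @param seed integer seed (per-sample seeds are derived deterministically).
#' @return list with `tables` (cleaned), `kept_index` (per table), and
#'   `report` (one row per sample).
#' @export
clean_cohort <- function(tables, seed = 1L) {
  out <- vector("list", length(tables))
  kept_index <- vector("list", length(tables))
  reports <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    sc <- scale_qc(tables[[i]])
    fit <- fit_gmm2(sc$matrix, seed = seed + i - 1L)
    res <- filter_events(tables[[i]], fit)
    out[[i]] <- res$kept
    kept_index[[i]] <- res$kept_index
    reports[[i]] <- res$report
  }
  list(tables = out, kept_index = kept_index,
       report = do.call(rbind, reports))
}
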