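# L1-regularized logistic regression by coordinate descent on the
# penalized iteratively-reweighted least squares (IRLS) quadratic
# approximation, with an unpenalized intercept and internally standardized
# predictors. Used to estimate odds ratios of driver mutations for binary
# phenotype / outcome contrasts.

soft_threshold <- function(x, g) sign(x) * pmax(abs(x) - g, 0)

# objective: mean logistic deviance/2 ( = mean negative log-likelihood )
# + lambda * ||beta||_1 on the standardized scale
logistic_objective <- function(y, eta, beta_std, lambda) {
  # numerically stable -loglik: log(1 + exp(eta)) - y * eta
  nll <- mean(ifelse(eta > 30, eta, log1p(exp(eta))) - y * eta)
  nll + lambda * sum(abs(beta_std))
}

fit_l1_logistic_single <- function(Xs, y, lambda, beta0 = NULL, b0 = NULL,
                                   tol = 1e-9, max_outer = 100) {
  n <- nrow(Xs); p <- ncol(Xs)
  beta <- beta0 %||% numeric(p)
  intercept <- b0 %||% log(mean(y) / (1 - mean(y) + 1e-12) + 1e-12)
  xsq <- numeric(p)
  for (outer in seq_len(max_outer)) {
    eta <- intercept + drop(Xs %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-5)
    zr <- eta + (y - mu) / w          # working response
    # coordinate descent on the weighted penalized least squares
    for (inner in seq_len(1000)) {
      max_delta <- 0
      r <- zr - intercept - drop(Xs %*% beta)
      # intercept (unpenalized)
      new_int <- intercept + sum(w * r) / sum(w)
      r <- r - (new_int - intercept)
      intercept <- new_int
      for (j in seq_len(p)) {
        r_j <- r + Xs[, j] * beta[j]
        num <- mean(w * Xs[, j] * r_j)
        den <- mean(w * Xs[, j]^2)
        bj <- soft_threshold(num, lambda) / den
        delta <- bj - beta[j]
        if (delta != 0) {
          r <- r - Xs[, j] * delta
          max_delta <- max(max_delta, abs(delta))
          beta[j] <- bj
        }
      }
      if (max_delta < tol) break
    }
    new_eta <- intercept + drop(Xs %*% beta)
    if (max(abs(new_eta - eta)) < 1e-8) break
  }
  list(beta = beta, intercept = intercept)
}

#' L1-regularized logistic regression with cross-validated penalty
#'
#' Minimizes the mean logistic negative log-likelihood plus
#' `lambda * sum(|beta|)` (intercept unpenalized; predictors standardized
#' internally, coefficients reported on the original scale). When `lambda`
#' is `NULL` the penalty is chosen by k-fold cross-validated deviance with
#' the one-standard-error rule over a log-spaced path from the smallest
#' all-zero penalty downward. Odds ratios are `exp(beta)` for the selected
#' (nonzero) coefficients.
#'
#' @param x numeric matrix / data.frame of predictors (e.g. binary mutation
#'   indicators plus clinical covariates).
#' @param y binary outcome (0/1 or logical).
#' @param lambda a fixed penalty (possibly 0 for the unpenalized fit), a
#'   vector of penalties to use as the path, or `NULL` to build a default
#'   path and cross-validate.
#' @param nlambda path length when `lambda` is `NULL` (default 50).
#' @param nfolds cross-validation folds (default 10).
#' @param seed seed controlling fold assignment.
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @return list of class `l1_logistic`: `coef` (original scale, at the
#'   chosen lambda), `intercept`, `odds_ratio` (nonzero coefficients),
#'   `lambda`, `path` (lambda, nonzero count, deviance), `cv` (lambda, mean
#'   and SE of held-out deviance) or NULL for fixed lambda.
#' @export
l1_logistic <- function(x, y, lambda = NULL, nlambda = 50, nfolds = 10,
                        seed = 1, lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2) stop("outcome is constant", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  sds <- apply(X, 2, function(col) sqrt(mean((col - mean(col))^2)))
  if (any(sds == 0)) {
    stop("constant column: ", paste(colnames(X)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  ctr <- colMeans(X)
  Xs <- sweep(sweep(X, 2, ctr), 2, sds, "/")

  fixed_lambda <- !is.null(lambda) && length(lambda) == 1
  if (is.null(lambda)) {
    lambda_max <- max(abs(crossprod(Xs, y - mean(y)) / n))
    lambda <- exp(seq(log(lambda_max), log(lambda_max * 1e-4),
                      length.out = nlambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)

  fit_path <- function(Xs, y, lambdas) {
    fits <- vector("list", length(lambdas))
    beta <- NULL; b0 <- NULL
    for (i in seq_along(lambdas)) {
      fits[[i]] <- fit_l1_logistic_single(Xs, y, lambdas[i], beta, b0)
      beta <- fits[[i]]$beta; b0 <- fits[[i]]$intercept
    }
    fits
  }

  deviance_of <- function(fit, Xs, y) {
    eta <- fit$intercept + drop(Xs %*% fit$beta)
    2 * mean(ifelse(eta > 30, eta, log1p(exp(eta))) - y * eta)
  }

  cv <- NULL
  if (!fixed_lambda && length(lambda) > 1) {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(nfolds), n))
    dev_fold <- matrix(NA_real_, nfolds, length(lambda))
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      fits <- fit_path(Xs[tr, , drop = FALSE], y[tr], lambda)
      dev_fold[f, ] <- vapply(fits, deviance_of,
                              numeric(1), Xs[!tr, , drop = FALSE], y[!tr])
    }
    cvm <- colMeans(dev_fold)
    cvse <- apply(dev_fold, 2, stats::sd) / sqrt(nfolds)
    i_min <- which.min(cvm)
    chosen <- if (lambda_rule == "min") lambda[i_min] else {
      ok <- which(cvm <= cvm[i_min] + cvse[i_min])
      lambda[min(ok)]   # largest lambda within one SE (lambdas descend)
    }
    cv <- data.frame(lambda = lambda, cvm = cvm, cvse = cvse)
  } else {
    chosen <- if (fixed_lambda) lambda else lambda[length(lambda)]
  }

  full_fits <- fit_path(Xs, y, lambda)
  path <- data.frame(
    lambda = lambda,
    nonzero = vapply(full_fits, function(f) sum(f$beta != 0), integer(1)),
    deviance = vapply(full_fits, deviance_of, numeric(1), Xs, y)
  )
  sel <- which.min(abs(lambda - chosen))
  fit <- full_fits[[sel]]

  if (chosen == 0 && max(abs(fit$beta)) > 15) {
    warning("large coefficients at lambda = 0: possible perfect separation; ",
            "rely on a positive penalty", call. = FALSE)
  }

  beta_orig <- fit$beta / sds
  intercept_orig <- fit$intercept - sum(beta_orig * ctr)
  nz <- beta_orig != 0
  structure(list(
    coef = stats::setNames(beta_orig, colnames(X)),
    intercept = intercept_orig,
    odds_ratio = stats::setNames(exp(beta_orig[nz]), colnames(X)[nz]),
    lambda = chosen, lambda_rule = if (fixed_lambda) "fixed" else lambda_rule,
    path = path, cv = cv
  ), class = "l1_logistic")
}

#' @export
print.l1_logistic <- function(x, ...) {
  cat(sprintf("L1 logistic: lambda = %.4g (%s), %d nonzero of %d\n",
              x$lambda, x$lambda_rule, sum(x$coef != 0), length(x$coef)))
  if (length(x$odds_ratio)) {
    print(data.frame(coef = x$coef[x$coef != 0], OR = x$odds_ratio))
  }
  invisible(x)
}
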