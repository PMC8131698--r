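#' Cox proportional hazards model (Breslow ties)
#'
#' Maximizes the Cox partial likelihood by Newton iteration with step
#' halving, handling tied event times with the Breslow approximation.
#' Convergence is declared when the gradient norm drops below `tol` (default
#' 1e-8); failure to converge within `max_iter` iterations is an error that
#' reports the iteration log. A monotone likelihood (separation, e.g. a
#' covariate that perfectly orders events) is detected from diverging
#' coefficients and raised as a warning, as is a fit attempted with a single
#' event.
#'
#' @param time follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param covariates numeric matrix or data.frame of covariates (no constant
#'   column).
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return list of class `cox_fit`: `coef`, `se`, `hr` (exp(coef)),
#'   `ci_lower`, `ci_upper` (Wald 95%), `loglik` (initial, final),
#'   `score_chisq` (score test at beta = 0, equals the log-rank statistic for
#'   a single binary covariate), `iter`, `converged`.
#' @export
cox_fit <- function(time, event, covariates, tol = 1e-8, max_iter = 100) {
  z <- check_survival_input(time, event)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(z$time)) stop("covariate rows must match times", call. = FALSE)
  const <- apply(X, 2, function(col) length(unique(col)) == 1)
  if (any(const)) {
    stop("constant covariate: ", paste(colnames(X)[const], collapse = ", "),
         call. = FALSE)
  }
  n_events <- sum(z$event)
  if (n_events < 2) {
    if (n_events == 1) {
      warning("single event: estimates are unstable (possible separation)",
              call. = FALSE)
    } else stop("need at least one event", call. = FALSE)
  }

  # center covariates for numerical stability (does not change beta)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  p <- ncol(Xc)

  # Breslow partial log-likelihood, gradient, information
  ll_parts <- function(beta) {
    eta <- drop(Xc %*% beta)
    w <- exp(eta)
    ev_times <- sort(unique(z$time[z$event == 1]))
    ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
    for (t in ev_times) {
      risk <- z$time >= t
      d_idx <- which(z$time == t & z$event == 1)
      d <- length(d_idx)
      sw <- sum(w[risk])
      swx <- colSums(w[risk] * Xc[risk, , drop = FALSE])
      xbar <- swx / sw
      swxx <- crossprod(Xc[risk, , drop = FALSE] * sqrt(w[risk]))
      ll <- ll + sum(eta[d_idx]) - d * log(sw)
      grad <- grad + colSums(Xc[d_idx, , drop = FALSE]) - d * xbar
      info <- info + d * (swxx / sw - tcrossprod(xbar))
    }
    list(ll = ll, grad = grad, info = info)
  }

  beta <- numeric(p)
  parts <- ll_parts(beta)
  ll0 <- parts$ll
  score_chisq <- tryCatch(
    drop(t(parts$grad) %*% solve(parts$info, parts$grad)),
    error = function(e) NA_real_)

  iter_log <- data.frame(iter = integer(), loglik = numeric(),
                         grad_norm = numeric())
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gnorm <- sqrt(sum(parts$grad^2))
    iter_log <- rbind(iter_log,
                      data.frame(iter = it, loglik = parts$ll, grad_norm = gnorm))
    if (gnorm < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(parts$info, parts$grad), error = function(e) {
      stop("singular information matrix at iteration ", it, call. = FALSE)
    })
    # step halving if the likelihood does not improve
    for (h in 0:20) {
      beta_new <- beta + step / 2^h
      parts_new <- ll_parts(beta_new)
      if (parts_new$ll >= parts$ll - 1e-12) break
    }
    beta <- beta_new
    parts <- parts_new
    if (any(abs(beta) > 15)) {
      warning("coefficients diverging: monotone likelihood (separation) suspected",
              call. = FALSE)
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("Cox Newton iteration failed to converge; iteration log:\n",
         paste(utils::capture.output(print(iter_log)), collapse = "\n"),
         call. = FALSE)
  }

  se <- sqrt(diag(solve(parts$info)))
  zq <- stats::qnorm(0.975)
  structure(list(
    coef = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    hr = stats::setNames(exp(beta), colnames(X)),
    ci_lower = stats::setNames(exp(beta - zq * se), colnames(X)),
    ci_upper = stats::setNames(exp(beta + zq * se), colnames(X)),
    loglik = c(initial = ll0, final = parts$ll),
    score_chisq = score_chisq,
    iter = nrow(iter_log), converged = converged, n = length(z$time),
    n_events = n_events
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH (Breslow): n = %d, events = %d, %d iterations\n",
              x$n, x$n_events, x$iter))
  print(data.frame(coef = x$coef, se = x$se, HR = x$hr,
                   `95% lower` = x$ci_lower, `95% upper` = x$ci_upper,
                   check.names = FALSE))
  invisible(x)
}
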