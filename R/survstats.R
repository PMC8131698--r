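# Natively implemented survival statistics: Kaplan-Meier product-limit
# estimator and the log-rank test with hypergeometric variance. Overall
# survival runs from diagnosis to death or last follow-up; AML-free survival
# from diagnosis to transformation or death. Event coding: 1 = event,
# 0 = censored.

check_survival_input <- function(time, event) {
  if (anyNA(time) || anyNA(event)) stop("missing time or event", call. = FALSE)
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  event <- as.integer(as.logical(event))
  list(time = time, event = event)
}

#' Kaplan-Meier product-limit estimator
#'
#' S(0) = 1 and the curve steps down only at event times, by the product of
#' (1 - d_i / n_i) over event times up to t. The median is the smallest time
#' at which S(t) falls to 0.5 or below, and is undefined (NA) when the curve
#' never reaches 0.5.
#'
#' @param time follow-up times (months).
#' @param event 1 = event (death / transformation), 0 = censored.
#' @return list of class `km_fit`: `time` (distinct times), `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `median`.
#' @export
km_estimate <- function(time, event) {
  z <- check_survival_input(time, event)
  if (length(z$time) < 1) stop("need at least one sample", call. = FALSE)
  tt <- sort(unique(z$time))
  n_risk <- vapply(tt, function(t) sum(z$time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(z$time == t & z$event == 1), numeric(1))
  n_censor <- vapply(tt, function(t) sum(z$time == t & z$event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  med_idx <- which(surv <= 0.5 + 1e-12)
  median <- if (length(med_idx)) tt[min(med_idx)] else NA_real_
  structure(list(time = tt, n_risk = n_risk, n_event = n_event,
                 n_censor = n_censor, surv = surv, median = median,
                 n = length(z$time)),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param fit a `km_fit`.
#' @param t times at which to evaluate S(t) (right-continuous step function).
#' @return numeric vector of survival probabilities.
#' @export
km_surv <- function(fit, t) {
  vapply(t, function(ti) {
    idx <- which(fit$time <= ti)
    if (!length(idx)) 1 else fit$surv[max(idx)]
  }, numeric(1))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: n = %d, events = %d, median = %s\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank statistic. At each distinct
#' event time the per-group expected event counts and the hypergeometric
#' (co)variance are accumulated; the statistic is the quadratic form over the
#' first k-1 groups and is referred to a chi-square distribution with
#' (groups - 1) degrees of freedom.
#'
#' @param time follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group group labels (at least two groups).
#' @return list of class `logrank_test`: `chisq`, `df`, `p_value`,
#'   `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  z <- check_survival_input(time, event)
  group <- as.factor(as.character(group))
  k <- nlevels(group)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (sum(z$event) < 1) stop("need at least one event", call. = FALSE)

  ev_times <- sort(unique(z$time[z$event == 1]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  V <- matrix(0, k - 1, k - 1)
  for (t in ev_times) {
    at_risk <- z$time >= t
    n_j <- sum(at_risk)
    d_j <- sum(z$time == t & z$event == 1)
    n_ij <- vapply(levels(group), function(g) sum(at_risk & group == g),
                   numeric(1))
    d_ij <- vapply(levels(group), function(g)
      sum(z$time == t & z$event == 1 & group == g), numeric(1))
    O <- O + d_ij
    E <- E + d_j * n_ij / n_j
    if (n_j > 1) {
      p <- n_ij / n_j
      mult <- d_j * (n_j - d_j) / (n_j - 1)
      Vt <- mult * (diag(p[-k], k - 1) - outer(p[-k], p[-k]))
      V <- V + Vt
    }
  }
  u <- (O - E)[-k]
  chisq <- tryCatch(drop(t(u) %*% solve(V, u)), error = function(e) {
    # singular variance (e.g. a group exhausted before any event): use
    # a generalized inverse via the eigendecomposition
    eg <- eigen(V, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-10
    drop(t(u) %*% eg$vectors[, pos, drop = FALSE] %*%
           diag(1 / eg$values[pos], sum(pos)) %*%
           t(eg$vectors[, pos, drop = FALSE]) %*% u)
  })
  df <- as.integer(k - 1)
  structure(list(chisq = chisq, df = df,
                 p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.4f on %d df, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = x$expected), row.names = FALSE)
  invisible(x)
}
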