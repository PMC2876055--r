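#' Kaplan-Meier product-limit estimator
#'
#' Right-continuous step estimate of the survivor function with Greenwood
#' variance. Censorings at an event time count as at risk for the events at
#' that time (the usual convention). Time is in months throughout the
#' package.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators: 1 = death observed, 0 = censored.
#' @return Object of class `KMFit`: list with `time` (distinct event times),
#'   `surv`, `var` (Greenwood), `n_risk`, `n_event`, `n`.
#' @export
km_fit <- function(times, events) {
  if (!length(times)) stop("empty input")
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(times < 0)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  tev <- sort(unique(times[events == 1]))
  n_risk <- vapply(tev, function(t) sum(times >= t), numeric(1L))
  n_event <- vapply(tev, function(t) sum(times == t & events == 1), numeric(1L))
  surv <- cumprod(1 - n_event / n_risk)
  gw_terms <- ifelse(n_risk > n_event,
                     n_event / (n_risk * (n_risk - n_event)), NA_real_)
  var <- surv^2 * cumsum(gw_terms)
  var[surv == 0] <- 0
  structure(list(time = tev, surv = surv, var = var,
                 n_risk = n_risk, n_event = n_event, n = length(times)),
            class = "KMFit")
}

#' @export
print.KMFit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: n = %d, %d event time(s), S(last) = %.3f\n",
              x$n, length(x$time), if (length(x$surv)) min(x$surv) else 1))
  invisible(x)
}

#' Survival probability at a time point
#'
#' Evaluates the right-continuous Kaplan-Meier step function; queries beyond
#' the last observed event time return the last estimate with a warning.
#'
#' @param fit A [km_fit()].
#' @param t_months Non-negative time(s) in months (5 years = 60).
#' @return Survival probabilities.
#' @export
survival_at <- function(fit, t_months) {
  stopifnot(inherits(fit, "KMFit"))
  if (any(t_months < 0)) stop("t_months must be >= 0")
  if (!length(fit$time)) return(rep(1, length(t_months)))
  if (any(t_months > max(fit$time)))
    warning("query beyond the last event time; returning the last estimate")
  f <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  f(t_months)
}

#' Export a Kaplan-Meier curve as a plain table
#'
#' @param fit A [km_fit()].
#' @return Data frame `time`, `survival`, `variance`, `at_risk`, `events`,
#'   beginning with the `t = 0, S = 1` anchor row.
#' @export
km_table <- function(fit) {
  stopifnot(inherits(fit, "KMFit"))
  data.frame(time = c(0, fit$time),
             survival = c(1, fit$surv),
             variance = c(0, fit$var),
             at_risk = c(fit$n, fit$n_risk),
             events = c(0, fit$n_event))
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' At every distinct event time the 2x2 table of deaths by group is compared
#' to its hypergeometric expectation; the squared standardized sum is referred
#' to a chi-square with 1 df.
#'
#' @param times,events As in [km_fit()].
#' @param groups Length-2-level grouping vector, both groups non-empty.
#' @return Object of class `LogRankResult`: `chi_square`, `df`, `p`,
#'   `observed` and `expected` events per group.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly 2 groups are required")
  if (any(table(groups) == 0L)) stop("both groups must be non-empty")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  g1 <- groups == levels(groups)[1L]
  tev <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in tev) {
    at <- times >= t
    n_t <- sum(at); n1_t <- sum(at & g1)
    d_t <- sum(times == t & events == 1)
    d1_t <- sum(times == t & events == 1 & g1)
    o1 <- o1 + d1_t
    e1 <- e1 + d_t * n1_t / n_t
    if (n_t > 1)
      v <- v + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
  }
  total <- sum(events)
  chi <- if (v > 0) (o1 - e1)^2 / v else 0
  structure(list(chi_square = chi, df = 1L,
                 p = stats::pchisq(chi, 1L, lower.tail = FALSE),
                 observed = stats::setNames(c(o1, total - o1), levels(groups)),
                 expected = stats::setNames(c(e1, total - e1), levels(groups))),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f (1 df), p = %.4g\n",
              x$chi_square, x$p))
  invisible(x)
}

#' Cox proportional hazards by Newton-Raphson on the partial likelihood
#'
#' Efron tie correction by default (Breslow available). Standard errors come
#' from the inverse observed information; p-values are Wald. Rows with
#' missing covariates are dropped complete-case with a message. Non-converged
#' fits, constant covariates and monotone likelihoods (complete separation)
#' raise errors rather than returning unreliable estimates.
#'
#' @param times,events As in [km_fit()].
#' @param covariates Numeric matrix or data frame, one column per covariate.
#' @param ties `"efron"` (default) or `"breslow"`. The two coincide exactly
#'   when all event times are distinct.
#' @param max_iter,tol Newton iteration controls.
#' @return Object of class `CoxFit`: data frame `coefficients` with `beta`,
#'   `hr`, `se`, `z`, `p` per covariate, plus `loglik`, `iter`, `converged`,
#'   `ties`, `n`, `n_event`, `n_dropped`.
#' @export
cox_fit <- function(times, events, covariates, ties = c("efron", "breslow"),
                    max_iter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  x <- as.matrix(as.data.frame(covariates))
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  keep <- stats::complete.cases(x) & !is.na(times) & !is.na(events)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " subject(s) dropped for missing covariates")
  x <- x[keep, , drop = FALSE]
  times <- times[keep]; events <- events[keep]
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (sum(events) < 1) stop("at least one event is required")
  if (any(apply(x, 2L, function(col) stats::sd(col) == 0)))
    stop("constant covariate")

  ord <- order(times)
  x <- x[ord, , drop = FALSE]
  times <- times[ord]; events <- events[ord]
  n <- length(times); p <- ncol(x)
  tev <- unique(times[events == 1])
  # risk set at t is a suffix of the time-sorted subjects
  risk_start <- vapply(tev, function(t)
    match(TRUE, times >= t), integer(1L))
  dead_idx <- lapply(tev, function(t) which(times == t & events == 1))
  # x_i x_i' flattened to the p(p+1)/2 lower-triangle entries per subject
  lt <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  xx <- x[, lt[, 1L], drop = FALSE] * x[, lt[, 2L], drop = FALSE]
  unflatten <- function(v) {
    s2 <- matrix(0, p, p)
    s2[lower.tri(s2, diag = TRUE)] <- v
    s2[upper.tri(s2)] <- t(s2)[upper.tri(s2)]
    s2
  }
  rev_cumsum <- function(v) rev(cumsum(rev(v)))

  neg_quantities <- function(beta) {
    eta <- drop(x %*% beta)
    w <- exp(eta)
    cs0 <- rev_cumsum(w)
    cs1 <- apply(x * w, 2L, rev_cumsum)
    cs2 <- apply(xx * w, 2L, rev_cumsum)
    if (p == 1L) cs1 <- matrix(cs1, ncol = 1L)
    if (ncol(xx) == 1L) cs2 <- matrix(cs2, ncol = 1L)
    ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
    for (k in seq_along(tev)) {
      at <- risk_start[k]
      dead <- dead_idx[[k]]
      d <- length(dead)
      s0 <- cs0[at]
      s1 <- cs1[at, ]
      s2 <- unflatten(cs2[at, ])
      if (ties == "efron" && d > 1L) {
        s0d <- sum(w[dead])
        s1d <- colSums(x[dead, , drop = FALSE] * w[dead])
        s2d <- unflatten(colSums(xx[dead, , drop = FALSE] * w[dead]))
      } else {
        s0d <- 0; s1d <- numeric(p); s2d <- matrix(0, p, p)
      }
      ll <- ll + sum(eta[dead])
      grad <- grad + colSums(x[dead, , drop = FALSE])
      for (j in seq_len(d) - 1L) {
        f <- if (ties == "efron") j / d else 0
        phi <- s0 - f * s0d
        psi1 <- s1 - f * s1d
        psi2 <- s2 - f * s2d
        ll <- ll - log(phi)
        grad <- grad - psi1 / phi
        info <- info + psi2 / phi - tcrossprod(psi1 / phi)
      }
    }
    list(ll = ll, grad = grad, info = info)
  }

  beta <- numeric(p)
  q <- neg_quantities(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(q$info, q$grad), error = function(e)
      stop("singular information matrix (possible complete separation)"))
    new_beta <- beta + step
    q_new <- neg_quantities(new_beta)
    halves <- 0L
    while (q_new$ll < q$ll && halves < 20L) {
      halves <- halves + 1L
      new_beta <- beta + step / 2^halves
      q_new <- neg_quantities(new_beta)
    }
    if (any(abs(new_beta) > 20))
      stop("monotone partial likelihood (complete separation)")
    done <- abs(q_new$ll - q$ll) < tol && max(abs(q_new$grad)) < 1e-6
    beta <- new_beta; q <- q_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) stop("Cox fit did not converge in ", max_iter, " iterations")
  cov_beta <- solve(q$info)
  se <- sqrt(diag(cov_beta))
  z <- beta / se
  structure(list(coefficients = data.frame(
    term = colnames(x), beta = beta, hr = exp(beta), se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)), row.names = NULL),
    loglik = q$ll, iter = iter, converged = converged, ties = ties,
    n = n, n_event = sum(events), n_dropped = n_dropped),
    class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_event))
  print(format(x$coefficients, digits = 4L), row.names = FALSE)
  invisible(x)
}
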