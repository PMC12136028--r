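# Survival machinery: Kaplan-Meier product-limit estimation, two-group
# log-rank test, restricted mean survival time at a fixed horizon with a
# Greenwood-based variance, Cox proportional hazards by Newton-Raphson on
# the partial likelihood (Efron or Breslow tie handling), likelihood-ratio
# p-values, and the Grambsch-Therneau scaled-Schoenfeld test of the
# proportional hazards assumption.

#' Kaplan-Meier product-limit estimator
#'
#' At tied times, events precede censorings (the usual convention: a subject
#' censored at t is still at risk for an event at t).
#'
#' @param times Nonnegative follow-up times (days).
#' @param events Binary event indicator (1 = death observed).
#' @return A `survival_curve` list: `event_times` (unique times with at
#'   least one event, ascending), `n_at_risk`, `n_events`, `survival`
#'   (product-limit estimate just after each event time), `max_time`.
#' @export
#' @examples
#' kaplan_meier(c(2, 4, 4, 6), c(1, 1, 0, 1))$survival  # 0.75 0.50 0.00
kaplan_meier <- function(times, events) {
  events <- as_binary(events, "events")
  stopifnot(length(times) == length(events))
  if (length(times) == 0) stop("kaplan_meier requires nonempty input", call. = FALSE)
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)
  ut <- sort(unique(times[events == 1]))
  n_at_risk <- vapply(ut, function(t) sum(times >= t), 0L)
  n_events <- vapply(ut, function(t) sum(times == t & events == 1), 0L)
  surv <- cumprod(1 - n_events / n_at_risk)
  structure(list(event_times = ut, n_at_risk = n_at_risk,
                 n_events = n_events, survival = surv,
                 max_time = max(times)),
            class = "survival_curve")
}

# Evaluate a survival_curve at arbitrary times (right-continuous step).
km_eval <- function(km, t) {
  vapply(t, function(tt) {
    i <- sum(km$event_times <= tt)
    if (i == 0) 1 else km$survival[i]
  }, 0)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square from the observed-minus-expected event
#' counts with hypergeometric variance at each event time.
#'
#' @param times,events As in [kaplan_meier()].
#' @param group Binary group indicator.
#' @return List with `chi2`, `p`, `observed` and `expected` (per group).
#' @export
log_rank <- function(times, events, group) {
  events <- as_binary(events, "events")
  group <- as_binary(group, "group")
  stopifnot(length(times) == length(events), length(times) == length(group))
  if (!any(group == 0) || !any(group == 1)) {
    stop("log_rank requires both groups nonempty", call. = FALSE)
  }
  ut <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  d_tot <- sum(events)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = c(group0 = d_tot - o1, group1 = o1),
       expected = c(group0 = d_tot - e1, group1 = e1))
}

# RMST (area under KM up to tau) and its Greenwood-based variance for one
# sample. Variance term at each event time: (area beyond t)^2 * d/(n(n-d)).
rmst_one <- function(times, events, tau) {
  km <- kaplan_meier(times, events)
  et <- km$event_times[km$event_times <= tau]
  s <- km$survival[km$event_times <= tau]
  grid <- c(0, et, tau)
  sv <- c(1, s)
  widths <- diff(grid)
  rmst <- sum(sv * widths)
  # area under the curve from each event time to tau
  if (length(et)) {
    area_after <- rev(cumsum(rev(sv[-1] * widths[-1])))
    n <- km$n_at_risk[km$event_times <= tau]
    d <- km$n_events[km$event_times <= tau]
    terms <- ifelse(n - d == 0, 0, area_after^2 * d / (n * (n - d)))
    v <- sum(terms)
  } else {
    v <- 0
  }
  list(rmst = rmst, var = v)
}

#' Restricted mean survival time difference
#'
#' Per-group RMST is the area under the Kaplan-Meier curve on `[0, tau]`;
#' the difference (group 1 minus group 0) is tested with an asymptotic
#' normal test using Greenwood-based variances.
#'
#' @param times,events As in [kaplan_meier()].
#' @param group Binary group indicator.
#' @param tau Restriction horizon in days (default 30). If `tau` exceeds the
#'   maximum follow-up of either group it is truncated with a warning.
#' @return An `rmst_result` list: `tau`, `rmst_per_group` (named group0,
#'   group1), `se_per_group`, `diff`, `diff_se`, `diff_p`.
#' @export
rmst_diff <- function(times, events, group, tau = 30) {
  events <- as_binary(events, "events")
  group <- as_binary(group, "group")
  if (!any(group == 0) || !any(group == 1)) {
    stop("rmst_diff requires both groups nonempty", call. = FALSE)
  }
  max_fu <- min(max(times[group == 0]), max(times[group == 1]))
  if (tau > max_fu) {
    warning(sprintf("tau = %g exceeds shortest group max follow-up; truncated to %g",
                    tau, max_fu), call. = FALSE)
    tau <- max_fu
  }
  g0 <- rmst_one(times[group == 0], events[group == 0], tau)
  g1 <- rmst_one(times[group == 1], events[group == 1], tau)
  diff <- g1$rmst - g0$rmst
  se <- sqrt(g0$var + g1$var)
  p <- if (se > 0) 2 * pnorm(-abs(diff) / se) else as.numeric(diff == 0)
  structure(list(tau = tau,
                 rmst_per_group = c(group0 = g0$rmst, group1 = g1$rmst),
                 se_per_group = c(group0 = sqrt(g0$var), group1 = sqrt(g1$var)),
                 diff = diff, diff_se = se, diff_p = p),
            class = "rmst_result")
}

# Cox partial log-likelihood, gradient and information for coefficient beta.
# X: n x p matrix; handles Efron ("efron") and Breslow ("breslow") ties.
cox_loglik <- function(beta, X, times, events, ties = "efron",
                      want_derivs = TRUE) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ut <- sort(unique(times[events == 1]))
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (t in ut) {
    R <- which(times >= t)
    D <- which(times == t & events == 1)
    d <- length(D)
    S0 <- sum(w[R])
    S1 <- drop(crossprod(X[R, , drop = FALSE], w[R]))
    T0 <- sum(w[D])
    T1 <- drop(crossprod(X[D, , drop = FALSE], w[D]))
    if (want_derivs) {
      Xr <- X[R, , drop = FALSE]
      S2 <- crossprod(Xr, Xr * w[R])
      Xd <- X[D, , drop = FALSE]
      T2 <- crossprod(Xd, Xd * w[D])
    }
    cl <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
    ll <- ll + sum(eta[D])
    for (l in seq_len(d)) {
      phi0 <- S0 - cl[l] * T0
      ll <- ll - log(phi0)
      if (want_derivs) {
        phi1 <- S1 - cl[l] * T1
        phi2 <- S2 - cl[l] * T2
        grad <- grad - phi1 / phi0
        info <- info + phi2 / phi0 - tcrossprod(phi1 / phi0)
      }
    }
    if (want_derivs) grad <- grad + colSums(X[D, , drop = FALSE])
  }
  list(loglik = ll, grad = grad, info = info)
}

cox_newton <- function(X, times, events, ties, max_iter = 100, tol = 1e-9) {
  p <- ncol(X)
  beta <- numeric(p)
  ll_old <- cox_loglik(beta, X, times, events, ties)$loglik
  for (it in seq_len(max_iter)) {
    pl <- cox_loglik(beta, X, times, events, ties)
    if (max(abs(pl$grad)) < tol) {
      return(list(beta = beta, loglik = pl$loglik, info = pl$info,
                  iter = it, converged = TRUE))
    }
    step <- tryCatch(solve(pl$info, pl$grad),
                     error = function(e) stop("Cox information matrix singular",
                                              call. = FALSE))
    # step-halving to guarantee ascent
    for (h in 0:20) {
      cand <- beta + step / 2^h
      ll_new <- cox_loglik(cand, X, times, events, ties,
                           want_derivs = FALSE)$loglik
      if (is.finite(ll_new) && ll_new >= pl$loglik - 1e-12) break
    }
    beta <- cand
    ll_old <- ll_new
  }
  pl <- cox_loglik(beta, X, times, events, ties)
  if (max(abs(pl$grad)) < 1e-5) {
    return(list(beta = beta, loglik = pl$loglik, info = pl$info,
                iter = max_iter, converged = TRUE))
  }
  stop(sprintf("Cox fit did not converge in %d iterations (max |grad| = %.3g, max |beta| = %.3g)",
               max_iter, max(abs(pl$grad)), max(abs(beta))), call. = FALSE)
}

#' Cox proportional hazards fit
#'
#' Maximizes the partial likelihood by Newton-Raphson (iterated until the
#' gradient norm drops below 1e-9, with step-halving). Per-covariate
#' p-values come from likelihood-ratio refits dropping one covariate at a
#' time; the 95% CI comes from the observed information.
#'
#' @param covariates Numeric matrix or data frame (n x p), no constant
#'   columns.
#' @param times,events As in [kaplan_meier()].
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit` list: `coef`, `hr` (`exp(coef)`), `se`, `ci95`
#'   (matrix with `lower`/`upper` columns on the HR scale), `p_lrt`
#'   (per-covariate likelihood-ratio p), `global_lrt_p`, `loglik`,
#'   `loglik_null`, `var` (covariance of `coef`), `n`, `n_events`,
#'   `separation` flag.
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  events <- as_binary(events, "events")
  stopifnot(nrow(X) == length(times), length(times) == length(events))
  if (sum(events) < 1) stop("cox_fit requires at least one event", call. = FALSE)
  const <- apply(X, 2, function(v) length(unique(v)) == 1)
  if (any(const)) {
    stop(sprintf("constant covariate(s): %s",
                 paste(colnames(X)[const], collapse = ", ")), call. = FALSE)
  }
  # centre covariates for numerical stability (invariant for the Cox model)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  fit <- cox_newton(Xc, times, events, ties)
  vcov <- solve(fit$info)
  se <- sqrt(diag(vcov))
  ll_null <- cox_loglik(numeric(ncol(Xc)), Xc, times, events, ties,
                        want_derivs = FALSE)$loglik
  p_lrt <- vapply(seq_len(ncol(Xc)), function(j) {
    if (ncol(Xc) == 1) {
      ll_red <- ll_null
    } else {
      ll_red <- cox_newton(Xc[, -j, drop = FALSE], times, events, ties)$loglik
    }
    pchisq(2 * (fit$loglik - ll_red), df = 1, lower.tail = FALSE)
  }, 0)
  z <- qnorm(0.975)
  ci <- cbind(lower = exp(fit$beta - z * se), upper = exp(fit$beta + z * se))
  rownames(ci) <- colnames(X)
  structure(list(
    covariates = colnames(X),
    coef = setNames(fit$beta, colnames(X)),
    hr = setNames(exp(fit$beta), colnames(X)),
    se = setNames(se, colnames(X)),
    ci95 = ci,
    p_lrt = setNames(p_lrt, colnames(X)),
    global_lrt_p = pchisq(2 * (fit$loglik - ll_null), df = ncol(Xc),
                          lower.tail = FALSE),
    loglik = fit$loglik, loglik_null = ll_null,
    var = vcov, n = nrow(X), n_events = sum(events),
    ties = ties, iter = fit$iter,
    separation = any(abs(fit$beta) > 15),
    centre = ctr
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  tab <- data.frame(HR = x$hr, `lower95` = x$ci95[, "lower"],
                    `upper95` = x$ci95[, "upper"], p = x$p_lrt)
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d\n", x$ties, x$n,
              x$n_events))
  print(round(tab, 4))
  cat(sprintf("Global LRT p = %.4g\n", x$global_lrt_p))
  invisible(x)
}

# Efron-adjusted Schoenfeld residuals: one p-vector per event, ordered by
# event time (ties in original data order).
schoenfeld_residuals <- function(fit, covariates, times, events) {
  X <- sweep(as.matrix(covariates), 2, fit$centre)
  storage.mode(X) <- "double"
  events <- as_binary(events, "events")
  eta <- drop(X %*% fit$coef)
  w <- exp(eta)
  ut <- sort(unique(times[events == 1]))
  res <- NULL
  etimes <- numeric(0)
  for (t in ut) {
    R <- which(times >= t)
    D <- which(times == t & events == 1)
    d <- length(D)
    S0 <- sum(w[R]); S1 <- drop(crossprod(X[R, , drop = FALSE], w[R]))
    T0 <- sum(w[D]); T1 <- drop(crossprod(X[D, , drop = FALSE], w[D]))
    cl <- (seq_len(d) - 1) / d
    xbar <- colMeans(do.call(rbind, lapply(seq_len(d), function(l) {
      (S1 - cl[l] * T1) / (S0 - cl[l] * T0)
    })))
    for (i in D) {
      res <- rbind(res, X[i, ] - xbar)
      etimes <- c(etimes, t)
    }
  }
  list(resid = res, times = etimes)
}

#' Schoenfeld proportional-hazards test
#'
#' Grambsch-Therneau score-type test: Schoenfeld residuals are correlated
#' with the Kaplan-Meier-transformed event times (the left-continuous KM
#' estimate of the censoring-ignored survival at each event time), scaled
#' by the fit's covariance. Returns a per-covariate chi-square p-value and
#' a global test; with one covariate the global test equals the
#' per-covariate test.
#'
#' @param fit A [cox_fit()] on the same data.
#' @param covariates,times,events The data the fit was produced from.
#' @return List with `table` (data frame: covariate, chisq, df, p) and
#'   `global` (chisq, df, p).
#' @export
schoenfeld_ph_test <- function(fit, covariates, times, events) {
  stopifnot(inherits(fit, "cox_fit"))
  events <- as_binary(events, "events")
  d <- sum(events)
  if (d < 3) stop("schoenfeld_ph_test requires at least 3 events", call. = FALSE)
  sr <- schoenfeld_residuals(fit, covariates, times, events)
  # KM transform: left-continuous overall KM at each death's event time
  km <- kaplan_meier(times, events)
  gvals <- vapply(sr$times, function(t) {
    i <- sum(km$event_times < t)
    if (i == 0) 1 else km$survival[i]
  }, 0)
  g <- gvals - mean(gvals)
  V <- fit$var
  p <- ncol(sr$resid)
  # scaled residuals: d * s V; per-covariate GT statistic
  r2 <- sr$resid %*% V * d
  num <- drop(crossprod(g, r2))
  denom <- d * diag(V) * sum(g^2)
  chisq <- num^2 / denom
  pvals <- pchisq(chisq, df = 1, lower.tail = FALSE)
  u <- drop(crossprod(g, sr$resid))
  global_chisq <- drop(t(u) %*% (d * V) %*% u) / sum(g^2)
  list(
    table = data.frame(covariate = fit$covariates, chisq = chisq, df = 1,
                       p = pvals, stringsAsFactors = FALSE),
    global = list(chisq = global_chisq, df = p,
                  p = pchisq(global_chisq, df = p, lower.tail = FALSE))
  )
}
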