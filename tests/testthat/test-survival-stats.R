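test_that("Kaplan-Meier matches hand computation and edge cases", {
  km <- kaplan_meier(c(2, 4, 4, 6), c(1, 1, 0, 1))
  expect_equal(km$event_times, c(2, 4, 6))
  expect_equal(km$survival, c(0.75, 0.5, 0))
  # no events: survival identically 1
  none <- kaplan_meier(c(5, 10, 30), c(0, 0, 0))
  expect_length(none$event_times, 0)
  expect_equal(mdscore:::km_eval(none, c(0, 10, 30)), c(1, 1, 1))
  # no censoring: complement of the ECDF
  t <- c(1, 3, 3, 7, 9)
  all_ev <- kaplan_meier(t, rep(1, 5))
  for (tt in c(0.5, 1, 3, 7, 8, 9)) {
    expect_equal(mdscore:::km_eval(all_ev, tt), mean(t > tt))
  }
  expect_error(kaplan_meier(numeric(0), integer(0)), "nonempty")
})

test_that("log-rank: null, separated, and oracle-checked cases", {
  # duplicated data relabeled: no difference
  t <- c(3, 8, 12, 30, 30); e <- c(1, 1, 1, 0, 0)
  lr <- log_rank(c(t, t), c(e, e), rep(c(0, 1), each = 5))
  expect_lt(lr$chi2, 1e-10)
  expect_gt(lr$p, 0.999)
  # strong separation
  set.seed(1)
  t0 <- rexp(250, 0.05); t1 <- rexp(250, 0.25)
  tt <- c(pmin(t0, 30), pmin(t1, 30))
  ee <- as.integer(c(t0 <= 30, t1 <= 30))
  expect_lt(log_rank(tt, ee, rep(0:1, each = 250))$p, 1e-6)
  expect_error(log_rank(t, e, rep(1, 5)), "both groups")
})

test_that("log-rank is invariant to monotone time relabeling", {
  set.seed(2)
  t <- sample(1:30, 60, replace = TRUE)
  e <- rbinom(60, 1, 0.6); g <- rbinom(60, 1, 0.5)
  g[1] <- 0; g[2] <- 1; e[1:2] <- 1
  a <- log_rank(t, e, g)
  b <- log_rank(t^2 + 3, e, g)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
})

test_that("RMST matches rectangle integration and trivial geometry", {
  # no deaths: flat curve, RMST = tau in both groups
  res <- rmst_diff(rep(30, 20), rep(0, 20), rep(0:1, 10), tau = 30)
  expect_equal(unname(res$rmst_per_group), c(30, 30))
  expect_equal(res$diff, 0)
  # everyone dies at day 10: RMST = 10
  one <- mdscore:::rmst_one(rep(10, 8), rep(1, 8), 30)
  expect_equal(one$rmst, 10)
  # independent step integration on random data
  set.seed(3)
  for (r in 1:20) {
    t <- sample(1:30, 40, replace = TRUE)
    e <- rbinom(40, 1, 0.6)
    if (sum(e) == 0) e[1] <- 1
    got <- mdscore:::rmst_one(t, e, 25)$rmst
    km <- kaplan_meier(t, e)
    grid <- seq(0, 25, by = 1 / 64)   # event times are integers: exact on this grid
    area <- sum(mdscore:::km_eval(km, grid[-length(grid)]) * diff(grid))
    expect_equal(got, area, tolerance = 1e-12)
  }
})

test_that("RMST is nondecreasing in tau and truncates with a warning", {
  set.seed(4)
  t <- sample(1:30, 50, replace = TRUE); e <- rbinom(50, 1, 0.5); e[1] <- 1
  taus <- c(5, 10, 20, 30)
  r <- vapply(taus, function(x) mdscore:::rmst_one(t, e, x)$rmst, 0)
  expect_true(all(diff(r) >= 0))
  expect_warning(
    rmst_diff(c(5, 8, 10, 4, 6, 9), c(1, 0, 1, 1, 0, 1), c(0, 0, 0, 1, 1, 1),
              tau = 30),
    "truncated")
})

test_that("Cox fit recovers a null and a planted hazard ratio", {
  set.seed(5)
  n <- 1000
  g <- rep(0:1, each = n / 2)
  t0 <- rexp(n, 0.08)
  tt <- pmin(t0, 30); ee <- as.integer(t0 <= 30)
  fit <- cox_fit(matrix(g, ncol = 1, dimnames = list(NULL, "g")), tt, ee)
  expect_lt(abs(fit$coef), 3 * fit$se)          # null: hr ~ 1
  # planted hr = 2
  t1 <- rexp(n, 0.05 * 2^g)
  tt1 <- pmin(t1, 30); ee1 <- as.integer(t1 <= 30)
  fit2 <- cox_fit(matrix(g, ncol = 1, dimnames = list(NULL, "g")), tt1, ee1)
  expect_lt(abs(fit2$coef - log(2)), 3 * fit2$se)
  expect_equal(unname(fit2$hr), exp(unname(fit2$coef)))
  expect_true(fit2$ci95[, "lower"] < fit2$hr && fit2$hr < fit2$ci95[, "upper"])
})

test_that("three-subject toy fit matches the closed-form partial likelihood optimum", {
  # times 1 < 2 < 3, events at 1 and 2, x = (1, 0, 1):
  # logL(b) = b - log(2 e^b + 1) - log(1 + e^b)
  X <- matrix(c(1, 0, 1), 3, 1, dimnames = list(NULL, "x"))
  fit <- cox_fit(X, c(1, 2, 3), c(1, 1, 0))
  oracle <- optimize(function(b) b - log(2 * exp(b) + 1) - log(1 + exp(b)),
                     c(-10, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fit$coef), oracle$maximum, tolerance = 1e-6)
})

test_that("Cox estimates agree with the survival-package oracle", {
  skip_if_not_installed("survival")
  set.seed(6)
  for (r in 1:25) {
    d <- random_surv(n = sample(30:80, 1), seed = r, p_covar = 2)
    fit <- cox_fit(d$X, d$times, d$events)
    oracle <- survival::coxph(
      survival::Surv(d$times, d$events) ~ d$X, ties = "efron",
      control = survival::coxph.control(eps = 1e-12, iter.max = 50, toler.chol = 1e-13))
    expect_equal(unname(fit$coef), unname(coef(oracle)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(oracle$var))),
                 tolerance = 1e-6)
    # per-covariate LRT against oracle refits
    for (j in 1:2) {
      red <- survival::coxph(
        survival::Surv(d$times, d$events) ~ d$X[, -j],
        ties = "efron",
        control = survival::coxph.control(eps = 1e-12, iter.max = 50, toler.chol = 1e-13))
      p_or <- pchisq(2 * (oracle$loglik[2] - red$loglik[2]), 1,
                     lower.tail = FALSE)
      expect_equal(unname(fit$p_lrt[j]), p_or, tolerance = 1e-6)
    }
  }
})

test_that("Breslow ties match the survival-package oracle too", {
  skip_if_not_installed("survival")
  set.seed(7)
  d <- random_surv(60, seed = 99, p_covar = 1)
  fit <- cox_fit(d$X, d$times, d$events, ties = "breslow")
  oracle <- survival::coxph(
    survival::Surv(d$times, d$events) ~ d$X, ties = "breslow",
    control = survival::coxph.control(eps = 1e-12, iter.max = 50, toler.chol = 1e-13))
  expect_equal(unname(fit$coef), unname(coef(oracle)), tolerance = 1e-6)
})

test_that("cox_fit rejects degenerate inputs", {
  expect_error(cox_fit(matrix(1, 5, 1), 1:5, c(1, 1, 0, 0, 1)), "constant")
  expect_error(cox_fit(matrix(rnorm(5), 5, 1), 1:5, rep(0, 5)), "event")
})

test_that("Schoenfeld test: identity, violation, and null calibration", {
  set.seed(8)
  # single covariate: global equals per-covariate
  d <- random_surv(120, seed = 1, p_covar = 1)
  fit <- cox_fit(d$X, d$times, d$events)
  ph <- schoenfeld_ph_test(fit, d$X, d$times, d$events)
  expect_equal(ph$global$p, ph$table$p[1], tolerance = 1e-12)
  # constructed violation: effect reverses at t = 15 (rates chosen so both
  # groups contribute many events on each side of the changepoint)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t1 <- rexp(n, 0.04 * exp(1.2 * x))          # early: x harmful
  t2 <- 15 + rexp(n, 0.25 * exp(-1.2 * x))    # late: x protective
  tt <- ifelse(t1 <= 15, t1, t2)
  ee <- as.integer(tt <= 40); tt <- pmin(tt, 40)
  fitv <- cox_fit(matrix(x, ncol = 1, dimnames = list(NULL, "x")), tt, ee)
  phv <- schoenfeld_ph_test(fitv, matrix(x, ncol = 1), tt, ee)
  expect_lt(phv$table$p[1], 0.01)
  expect_error(schoenfeld_ph_test(fit, d$X, d$times, rep(0, 120)), "3 events")
})

test_that("Schoenfeld p-values are uniform under proportional hazards", {
  set.seed(9)
  ps <- vapply(1:200, function(r) {
    n <- 100
    x <- rnorm(n)
    t0 <- rexp(n, 0.1 * exp(0.5 * x))
    tt <- pmin(t0, 20); ee <- as.integer(t0 <= 20)
    if (sum(ee) < 10) return(NA_real_)
    fit <- cox_fit(matrix(x, ncol = 1, dimnames = list(NULL, "x")), tt, ee)
    schoenfeld_ph_test(fit, matrix(x, ncol = 1), tt, ee)$table$p[1]
  }, 0)
  ps <- ps[!is.na(ps)]
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Greenwood-based RMST variance matches the survival-package oracle", {
  skip_if_not_installed("survival")
  set.seed(10)
  for (r in 1:15) {
    t <- sample(1:30, 60, replace = TRUE)
    e <- rbinom(60, 1, 0.6)
    if (sum(e) == 0) e[1] <- 1
    sf <- survival::survfit(survival::Surv(t, e) ~ 1)
    tab <- summary(sf, rmean = 25)$table
    ours <- mdscore:::rmst_one(t, e, 25)
    expect_equal(ours$rmst, unname(tab["rmean"]), tolerance = 1e-9)
    expect_equal(sqrt(ours$var), unname(tab["se(rmean)"]), tolerance = 1e-9)
  }
})

test_that("KM and log-rank agree with the survival-package oracle", {
  skip_if_not_installed("survival")
  set.seed(11)
  for (r in 1:15) {
    d <- random_surv(50, seed = 100 + r)
    km <- kaplan_meier(d$times, d$events)
    sf <- survival::survfit(survival::Surv(d$times, d$events) ~ 1)
    sf_ev <- sf$n.event > 0
    expect_equal(km$event_times, sf$time[sf_ev], tolerance = 1e-12)
    expect_equal(km$survival, sf$surv[sf_ev], tolerance = 1e-12)
    g <- rbinom(50, 1, 0.5); g[1] <- 0; g[2] <- 1
    lr <- log_rank(d$times, d$events, g)
    or <- survival::survdiff(survival::Surv(d$times, d$events) ~ g)
    expect_equal(lr$chi2, or$chisq, tolerance = 1e-9)
  }
})
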