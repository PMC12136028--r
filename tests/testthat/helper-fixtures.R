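# Shared fixtures built in code.

# Small cohort with known structure: n patients, mortality by label vector.
toy_cohort <- function(labels, days = NULL, cci = NULL, sofa = NULL,
                       horizon = 30L) {
  n <- length(labels)
  if (is.null(days)) days <- ifelse(labels == 1, pmax(1L, n %% 29 + 1L), horizon)
  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    survival_days = as.integer(days),
    event = as.integer(labels),
    mortality_label = as.integer(labels),
    cci = if (is.null(cci)) rep(4L, n) else cci,
    sofa = if (is.null(sofa)) rep(8L, n) else sofa,
    stringsAsFactors = FALSE
  )
}

# Random survival data for oracle comparisons.
random_surv <- function(n, seed, p_covar = 0, max_t = 20) {
  set.seed(seed)
  times <- sample.int(max_t, n, replace = TRUE)
  events <- rbinom(n, 1, 0.6)
  if (sum(events) == 0) events[1] <- 1L
  X <- if (p_covar > 0) matrix(rnorm(n * p_covar), n, p_covar) else NULL
  list(times = times, events = events, X = X)
}

# Brute-force Youden maximization over all midpoints x both directions.
brute_youden <- function(values, labels) {
  sv <- sort(unique(values))
  if (length(sv) < 2) return(list(j = 0, threshold = NA, direction = NA))
  mids <- (sv[-1] + sv[-length(sv)]) / 2
  pos <- values[labels == 1]; neg <- values[labels == 0]
  best <- list(j = -Inf)
  for (dir in c("high_in_nonsurvivors", "low_in_nonsurvivors")) {
    for (t in mids) {
      if (dir == "high_in_nonsurvivors") {
        se <- mean(pos >= t); sp <- mean(neg < t)
      } else {
        se <- mean(pos <= t); sp <- mean(neg > t)
      }
      j <- se + sp - 1
      if (j > best$j + 1e-12) best <- list(j = j, threshold = t, direction = dir,
                                           sens = se, spec = sp)
    }
  }
  best
}
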