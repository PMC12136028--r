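# Per-metabolite ROC analysis and Youden-optimal cutpoint estimation.
#
# Candidate thresholds are midpoints between consecutive distinct observed
# values (with sentinels beyond the range), which keeps thresholds
# scale-respecting and yields half-integer thresholds on integer scores.

#' Empirical ROC curve
#'
#' Curve over midpoint thresholds with the higher-value-predicts-positive
#' orientation. The AUC equals the Mann-Whitney U statistic divided by
#' `n1 * n0`, counting tied pairs as 1/2.
#'
#' @param values Numeric predictor (no missing values).
#' @param labels Binary outcome (1 = positive class, here nonsurvivor).
#' @return A `roc_curve` list: `thresholds` (decreasing, with `Inf`/`-Inf`
#'   sentinels), `sens`, `spec`, `auc`, `n1`, `n0`.
#' @export
roc_curve <- function(values, labels) {
  labels <- as_binary(labels)
  stopifnot(length(values) == length(labels), !any(is.na(values)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("roc_curve requires both classes present", call. = FALSE)
  }
  sv <- sort(unique(values))
  mids <- if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2 else numeric(0)
  thr <- c(Inf, rev(mids), -Inf)     # decreasing: from predict-none to predict-all
  # positive call: value >= threshold; cumulative counts over sorted values
  f <- findInterval(values, sv)
  cpos <- cumsum(tabulate(f[labels == 1], nbins = length(sv)))
  cneg <- cumsum(tabulate(f[labels == 0], nbins = length(sv)))
  # at mid i (between sv[i], sv[i+1]): #pos >= t = n1 - cpos[i]
  i_of_thr <- c(length(sv), rev(seq_len(length(sv) - 1)), 0)
  inside <- i_of_thr > 0
  sens <- spec <- numeric(length(thr))
  sens[!inside] <- 1                      # t = -Inf: everyone called positive
  sens[inside] <- (n1 - cpos[i_of_thr[inside]]) / n1
  spec[inside] <- cneg[i_of_thr[inside]] / n0
  r <- rank(values)
  u <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  structure(list(thresholds = thr, sens = sens, spec = spec,
                 auc = u / (n1 * n0), n1 = n1, n0 = n0),
            class = "roc_curve")
}

# Youden maximization over midpoint candidates for a fixed direction.
# direction "high": point side is value >= threshold; "low": value <= threshold.
youden_scan <- function(values, labels, direction) {
  sv <- sort(unique(values))
  if (length(sv) < 2) {
    return(list(threshold = NA_real_, j = 0, sens = NA_real_, spec = NA_real_,
                degenerate = TRUE))
  }
  mids <- (sv[-1] + sv[-length(sv)]) / 2
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  f <- findInterval(values, sv)           # exact: sv = sorted unique(values)
  # cumulative class counts at each distinct value (values <= sv[i])
  cpos <- cumsum(tabulate(f[labels == 1], nbins = length(sv)))
  cneg <- cumsum(tabulate(f[labels == 0], nbins = length(sv)))
  i <- seq_len(length(sv) - 1)            # mid i lies in (sv[i], sv[i+1])
  if (direction == "high_in_nonsurvivors") {
    sens <- (n1 - cpos[i]) / n1
    spec <- cneg[i] / n0
  } else {
    sens <- cpos[i] / n1
    spec <- (n0 - cneg[i]) / n0
  }
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  # ties: higher specificity, then lower threshold
  best <- best[order(-spec[best], mids[best])][1]
  list(threshold = mids[best], j = j[best], sens = sens[best],
       spec = spec[best], degenerate = FALSE)
}

#' Youden-optimal cutpoint with stratified bootstrap stability
#'
#' Orients the metabolite so that nonsurvivors are enriched on the point
#' side (oriented AUC >= 0.5), then maximizes the Youden index
#' J = sensitivity + specificity - 1 over midpoint candidate thresholds on
#' the full sample. Ties in J are broken toward higher specificity, then
#' the lower threshold. A stratified bootstrap (resampling within each
#' outcome class) re-estimates the threshold `n_boot` times for stability
#' reporting only; the deployed threshold is always the full-sample optimum.
#'
#' @param values Numeric predictor (no missing values).
#' @param labels Binary outcome (1 = nonsurvivor).
#' @param n_boot Number of stratified bootstrap replicates (default 10).
#' @param seed Integer seed for the bootstrap.
#' @param metabolite Optional id carried into the result.
#' @return A `cutpoint` list: `metabolite`, `threshold`, `direction`
#'   (`"high_in_nonsurvivors"` or `"low_in_nonsurvivors"`), `youden_j`,
#'   `sens`, `spec`, `auc` (oriented), `bootstrap_mean_threshold`,
#'   `bootstrap_sd_threshold`, `n_boot`, `degenerate`.
#' @export
#' @examples
#' youden_cutpoint(c(1, 2, 3), c(0, 0, 1), n_boot = 0)
youden_cutpoint <- function(values, labels, n_boot = 10L, seed = 1L,
                            metabolite = NA_character_) {
  labels <- as_binary(labels)
  stopifnot(length(values) == length(labels), n_boot >= 0)
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("youden_cutpoint requires both classes present", call. = FALSE)
  }
  rc <- roc_curve(values, labels)
  auc_dir <- if (rc$auc >= 0.5) "high_in_nonsurvivors" else "low_in_nonsurvivors"
  auc_oriented <- max(rc$auc, 1 - rc$auc)
  # maximize J over both directions; the AUC-oriented direction (nonsurvivors
  # enriched on the point side) breaks exact ties
  sc_hi <- youden_scan(values, labels, "high_in_nonsurvivors")
  sc_lo <- youden_scan(values, labels, "low_in_nonsurvivors")
  if (abs(sc_hi$j - sc_lo$j) <= 1e-12) {
    direction <- auc_dir
    sc <- if (auc_dir == "high_in_nonsurvivors") sc_hi else sc_lo
  } else if (sc_hi$j > sc_lo$j) {
    direction <- "high_in_nonsurvivors"; sc <- sc_hi
  } else {
    direction <- "low_in_nonsurvivors"; sc <- sc_lo
  }
  boot_mean <- NA_real_; boot_sd <- NA_real_
  if (n_boot > 0 && !sc$degenerate) {
    thr <- with_seed(derive_seed(seed, paste0("boot:", metabolite)), {
      i1 <- which(labels == 1); i0 <- which(labels == 0)
      vapply(seq_len(n_boot), function(b) {
        idx <- c(sample(i1, length(i1), replace = TRUE),
                 sample(i0, length(i0), replace = TRUE))
        vb <- values[idx]; lb <- labels[idx]
        if (length(unique(vb)) < 2 || !any(lb == 1) || !any(lb == 0)) {
          return(NA_real_)
        }
        bh <- youden_scan(vb, lb, "high_in_nonsurvivors")
        bl <- youden_scan(vb, lb, "low_in_nonsurvivors")
        if (bh$j >= bl$j) bh$threshold else bl$threshold
      }, 0)
    })
    thr <- thr[!is.na(thr)]
    if (length(thr)) {
      boot_mean <- mean(thr)
      boot_sd <- if (length(thr) > 1) sd(thr) else 0
    }
  }
  structure(list(metabolite = metabolite, threshold = sc$threshold,
                 direction = direction, youden_j = sc$j,
                 sens = sc$sens, spec = sc$spec, auc = auc_oriented,
                 bootstrap_mean_threshold = boot_mean,
                 bootstrap_sd_threshold = boot_sd,
                 n_boot = as.integer(n_boot), degenerate = sc$degenerate),
            class = "cutpoint")
}

#' @export
print.cutpoint <- function(x, ...) {
  cat(sprintf("Cutpoint%s: threshold %.4g (%s), J = %.3f (sens %.3f, spec %.3f, AUC %.3f)%s\n",
              if (is.na(x$metabolite)) "" else paste0(" [", x$metabolite, "]"),
              x$threshold, x$direction, x$youden_j, x$sens, x$spec, x$auc,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Fit cutpoints for every metabolite in a matrix
#'
#' @param m A [metabolite_matrix()] without missing values.
#' @param labels Binary outcome aligned to the matrix rows.
#' @inheritParams youden_cutpoint
#' @return Named list of `cutpoint` objects, one per metabolite.
#' @export
fit_cutpoints <- function(m, labels, n_boot = 10L, seed = 1L) {
  stopifnot(inherits(m, "metabolite_matrix"))
  setNames(lapply(colnames(m$values), function(id) {
    youden_cutpoint(m$values[, id], labels, n_boot = n_boot, seed = seed,
                    metabolite = id)
  }), colnames(m$values))
}

#' Cutpoint list as a table
#'
#' @param cuts List of `cutpoint` objects.
#' @return Data frame mirroring a per-metabolite threshold table
#'   (metabolite, threshold, direction, J, sens, spec, AUC, bootstrap
#'   summaries).
#' @export
cutpoint_table <- function(cuts) {
  do.call(rbind, lapply(cuts, function(cp) {
    data.frame(metabolite = cp$metabolite, threshold = cp$threshold,
               direction = cp$direction, youden_j = cp$youden_j,
               sens = cp$sens, spec = cp$spec, auc = cp$auc,
               bootstrap_mean_threshold = cp$bootstrap_mean_threshold,
               bootstrap_sd_threshold = cp$bootstrap_sd_threshold,
               n_boot = cp$n_boot, stringsAsFactors = FALSE)
  }))
}

#' Binarize a metabolite matrix into a point matrix
#'
#' Entry is 1 iff the concentration lies on the nonsurvivor side of the
#' column's cutpoint: `value >= threshold` when the direction is
#' `high_in_nonsurvivors`, `value <= threshold` when low (exact equality,
#' possible only for user-supplied thresholds, lands on the point side).
#'
#' @param m A [metabolite_matrix()] with no missing values (impute first).
#' @param cuts Named list of `cutpoint` objects covering every column.
#' @return Integer 0/1 matrix (patients x metabolites) of class
#'   `point_matrix`, with the cutpoints attached as attribute `cutpoints`.
#' @export
binarize <- function(m, cuts) {
  stopifnot(inherits(m, "metabolite_matrix"))
  if (any(is.na(m$values))) {
    stop("binarize requires a fully observed matrix; impute first", call. = FALSE)
  }
  missing_cp <- setdiff(colnames(m$values), names(cuts))
  if (length(missing_cp)) {
    stop(sprintf("no cutpoint for metabolite(s): %s",
                 paste(missing_cp, collapse = ", ")), call. = FALSE)
  }
  pts <- vapply(colnames(m$values), function(id) {
    cp <- cuts[[id]]
    if (is.na(cp$threshold)) {
      return(rep(0L, nrow(m$values)))   # degenerate column scores nothing
    }
    if (cp$direction == "high_in_nonsurvivors") {
      as.integer(m$values[, id] >= cp$threshold)
    } else {
      as.integer(m$values[, id] <= cp$threshold)
    }
  }, integer(nrow(m$values)))
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = nrow(m$values))
  dimnames(pts) <- dimnames(m$values)
  structure(pts, class = c("point_matrix", "matrix"), cutpoints = cuts)
}
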