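# Score assembly: ridge-based metabolite importance ranking on the binary
# point matrix, iterative score construction (adding metabolites in
# importance order, re-optimizing the score threshold per iteration),
# parsimony model selection, and score application.

# Penalized IRLS for logistic (or closed-form for linear) ridge with an
# unpenalized intercept. X is assumed standardized by the caller.
ridge_solve <- function(X, y, lambda, family = "binomial", max_iter = 200,
                        tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  if (family == "gaussian") {
    yc <- y - mean(y)
    beta <- solve(crossprod(X) + diag(lambda, p), crossprod(X, yc))
    return(list(intercept = mean(y), beta = drop(beta)))
  }
  Xt <- cbind(1, X)
  pen <- diag(c(0, rep(lambda, p)))
  th <- numeric(p + 1)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xt %*% th)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xt, y - mu)) - pen %*% th
    H <- crossprod(Xt, Xt * w) + pen
    step <- solve(H, grad)
    th <- th + step
    if (max(abs(grad)) < tol) break
  }
  list(intercept = th[1], beta = th[-1])
}

ridge_deviance <- function(intercept, beta, X, y, family) {
  eta <- intercept + drop(X %*% beta)
  if (family == "gaussian") {
    sum((y - eta)^2)
  } else {
    mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
}

#' Ridge-based metabolite importance ranking
#'
#' Fits a ridge-penalized (logistic by default) regression of the outcome on
#' the standardized binary point-matrix columns; the penalty strength is
#' chosen by K-fold cross-validated deviance over a logarithmic grid
#' (seed-deterministic fold assignment). Metabolites are ranked by
#' decreasing absolute standardized coefficient; ties break
#' lexicographically by metabolite id. Constant columns are dropped from
#' the fit with a warning and appended with zero importance.
#'
#' @param points A `point_matrix` from [binarize()] (any numeric matrix
#'   works).
#' @param labels Binary outcome (1 = nonsurvivor).
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @param lambda_grid Optional penalty grid (decreasing recommended).
#' @return Data frame (`metabolite`, `beta`, `abs_beta`, `rank`) ordered by
#'   rank, with the chosen `lambda` as an attribute.
#' @export
ridge_importance <- function(points, labels, cv_folds = 10L, seed = 1L,
                             family = c("binomial", "gaussian"),
                             lambda_grid = NULL) {
  family <- match.arg(family)
  X <- unclass(points)
  storage.mode(X) <- "double"
  y <- as_binary(labels)
  stopifnot(nrow(X) == length(y))
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("ridge_importance requires at least 2 patients per class", call. = FALSE)
  }
  sds <- apply(X, 2, sd)
  const <- sds == 0
  if (all(const)) stop("all point-matrix columns are constant", call. = FALSE)
  if (any(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(X)[const], collapse = ", ")), call. = FALSE)
  }
  keep <- colnames(X)[!const]
  Xs <- scale(X[, keep, drop = FALSE])
  lambda_grid <- lambda_grid %||% exp(seq(log(1e4), log(1e-4), length.out = 30))
  k <- min(cv_folds, nrow(Xs))
  foldid <- with_seed(derive_seed(seed, "ridge-cv"),
                      sample(rep_len(seq_len(k), nrow(Xs))))
  cvdev <- numeric(length(lambda_grid))
  for (f in seq_len(k)) {
    tr <- foldid != f
    for (li in seq_along(lambda_grid)) {
      fit <- ridge_solve(Xs[tr, , drop = FALSE], y[tr], lambda_grid[li], family)
      cvdev[li] <- cvdev[li] +
        ridge_deviance(fit$intercept, fit$beta, Xs[!tr, , drop = FALSE],
                       y[!tr], family)
    }
  }
  lambda <- lambda_grid[which.min(cvdev)]
  fit <- ridge_solve(Xs, y, lambda, family)
  beta <- setNames(fit$beta, keep)
  if (any(const)) beta <- c(beta, setNames(rep(0, sum(const)), colnames(X)[const]))
  ord <- order(-abs(beta), names(beta))
  out <- data.frame(metabolite = names(beta)[ord],
                    beta = unname(beta[ord]),
                    abs_beta = unname(abs(beta[ord])),
                    rank = seq_along(beta),
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- lambda
  attr(out, "family") <- family
  out
}

#' Iterative score construction
#'
#' For k = 1..K (metabolites in ranking order) the patient score is the row
#' sum over the first k point-matrix columns. Each iteration re-optimizes a
#' Youden threshold on the integer scores (midpoint candidates, hence
#' half-integer thresholds), records classification metrics at that
#' threshold (nonsurvivor = positive class), and compares the low- vs
#' high-score strata by RMST difference (low minus high, in days) and a
#' log-rank test at the `tau`-day horizon.
#'
#' @param points A `point_matrix`.
#' @param ranking Ranking data frame from [ridge_importance()]; must cover
#'   every point-matrix column.
#' @param cohort Cohort data frame with `patient_id`, `survival_days`,
#'   `event`, `mortality_label` covering the matrix rows.
#' @param tau RMST horizon in days (default 30).
#' @return A `score_iterations` data frame, one row per k: `k`, `added`,
#'   `score_threshold`, `accuracy`, `auc`, `sens`, `spec`,
#'   `rmst_diff_days`, `logrank_p`, `degenerate`. The per-iteration score
#'   matrix is attached as attribute `scores`.
#' @export
build_iterations <- function(points, ranking, cohort, tau = 30) {
  X <- unclass(points)
  if (!setequal(ranking$metabolite, colnames(X))) {
    stop("ranking must cover exactly the point-matrix columns", call. = FALSE)
  }
  idx <- match(cohort$patient_id, rownames(X))
  if (any(is.na(idx))) stop("cohort does not match point-matrix patients", call. = FALSE)
  X <- X[idx, , drop = FALSE]
  lab <- as_binary(cohort$mortality_label)
  ord <- ranking$metabolite[order(ranking$rank)]
  cum <- t(apply(X[, ord, drop = FALSE], 1, cumsum))
  if (length(ord) == 1) cum <- matrix(X[, ord], ncol = 1)
  colnames(cum) <- ord
  rows <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    s <- cum[, k]
    if (length(unique(s)) < 2) {
      warning(sprintf("iteration k=%d: scores constant; metrics degenerate", k),
              call. = FALSE)
      rows[[k]] <- data.frame(k = k, added = ord[k], score_threshold = NA_real_,
                              accuracy = NA_real_, auc = NA_real_,
                              sens = NA_real_, spec = NA_real_,
                              rmst_diff_days = NA_real_, logrank_p = NA_real_,
                              degenerate = TRUE, stringsAsFactors = FALSE)
      next
    }
    cp <- youden_cutpoint(s, lab, n_boot = 0)
    high <- if (cp$direction == "high_in_nonsurvivors") {
      as.integer(s >= cp$threshold)
    } else {
      as.integer(s <= cp$threshold)
    }
    acc <- mean(high == lab)
    if (all(high == high[1])) {
      warning(sprintf("iteration k=%d: all patients on one side of the threshold; survival comparison skipped", k),
              call. = FALSE)
      rmstd <- NA_real_; lrp <- NA_real_; deg <- TRUE
    } else {
      rm <- rmst_diff(cohort$survival_days, cohort$event, high, tau = tau)
      lr <- log_rank(cohort$survival_days, cohort$event, high)
      rmstd <- -rm$diff       # low-score minus high-score group, in days
      lrp <- lr$p
      deg <- FALSE
    }
    rows[[k]] <- data.frame(k = k, added = ord[k],
                            score_threshold = cp$threshold,
                            accuracy = acc, auc = cp$auc,
                            sens = cp$sens, spec = cp$spec,
                            rmst_diff_days = rmstd, logrank_p = lrp,
                            degenerate = deg, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("score_iterations", "data.frame")
  attr(out, "scores") <- cum
  attr(out, "order") <- ord
  out
}

#' Parsimony model selection
#'
#' Chooses the smallest iteration whose objective is within `tolerance` of
#' the best over all iterations ("simplest but best-performing"). The
#' default objective is the iteration AUC: it is threshold-free, so the
#' parsimony comparison is not contaminated by the noise of per-iteration
#' threshold re-optimization, which under class imbalance makes accuracy
#' nearly flat across neighbouring iterations and unreliable for ordering
#' models. Accuracy remains available as an alternative objective.
#'
#' @param iterations A `score_iterations` data frame from
#'   [build_iterations()].
#' @param tolerance Allowed shortfall from the maximum (default 0.01).
#' @param cuts Named list of per-metabolite `cutpoint`s (as used to build
#'   the point matrix); attached to the model for later application.
#' @param objective `"auc"` (default) or `"accuracy"`.
#' @return An `mds_model` list: `metabolites` (ordered), `cutpoints`,
#'   `n_metabolites`, `score_threshold`, `dysbiosis_rule`, `objective`,
#'   `tolerance`, `selected_metrics`.
#' @export
select_model <- function(iterations, tolerance = 0.01, cuts = NULL,
                         objective = c("auc", "accuracy")) {
  objective <- match.arg(objective)
  stopifnot(nrow(iterations) >= 1)
  metric <- iterations[[objective]]
  ok <- which(!is.na(metric))
  if (!length(ok)) stop("no non-degenerate iterations to select from", call. = FALSE)
  best <- max(metric[ok])
  k <- ok[which(metric[ok] >= best - tolerance)[1]]
  ord <- attr(iterations, "order")
  mets <- ord[seq_len(iterations$k[k])]
  structure(list(
    metabolites = mets,
    cutpoints = if (!is.null(cuts)) cuts[mets] else NULL,
    n_metabolites = length(mets),
    score_threshold = iterations$score_threshold[k],
    dysbiosis_rule = "score > threshold",
    objective = objective, tolerance = tolerance,
    selected_metrics = iterations[k, , drop = FALSE]
  ), class = "mds_model")
}

#' @export
print.mds_model <- function(x, ...) {
  cat(sprintf("MDS model: %d metabolites, dysbiosis when score > %.1f\n",
              x$n_metabolites, x$score_threshold))
  cat(sprintf("  selection: %s within %.3g of best (accuracy %.3f, AUC %.3f)\n",
              x$objective, x$tolerance, x$selected_metrics$accuracy,
              x$selected_metrics$auc))
  cat("  metabolites:", paste(x$metabolites, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a fitted MDS model
#'
#' Scores each patient by counting metabolites on the nonsurvivor side of
#' their cutpoints; dysbiosis is declared when the score exceeds the model
#' threshold.
#'
#' @param model An `mds_model` with cutpoints attached.
#' @param m A [metabolite_matrix()] containing all model metabolites, with
#'   no missing values among them.
#' @return List with integer `scores` (named by patient) and binary
#'   `dysbiosis`.
#' @export
apply_score <- function(model, m) {
  stopifnot(inherits(model, "mds_model"), inherits(m, "metabolite_matrix"))
  if (is.null(model$cutpoints)) stop("model carries no cutpoints", call. = FALSE)
  absent <- setdiff(model$metabolites, colnames(m$values))
  if (length(absent)) {
    stop(sprintf("matrix lacks model metabolite(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  sub <- metabolite_matrix(m$values[, model$metabolites, drop = FALSE],
                           panel = unname(m$panel[model$metabolites]))
  if (any(is.na(sub$values))) {
    stop("missing values among model metabolites; impute first", call. = FALSE)
  }
  pts <- binarize(sub, model$cutpoints)
  scores <- as.integer(rowSums(pts))
  names(scores) <- rownames(pts)
  list(scores = scores,
       dysbiosis = as.integer(scores > model$score_threshold))
}

#' Apply a predefined (fixed) score definition
#'
#' Scores patients against a user-supplied metabolite/threshold/direction
#' definition with a configurable flag rule, e.g. a previously published
#' 4-metabolite score flagged at `score >= 2`.
#'
#' @param definition List with `metabolites` (ids), `thresholds` (numeric),
#'   `directions` (`"high_in_nonsurvivors"`/`"low_in_nonsurvivors"`),
#'   `score_cut` (numeric), and `op` (`">="` default, or `">"`).
#' @param m A [metabolite_matrix()].
#' @return List with `scores` and binary `flag`.
#' @export
#' @examples
#' def <- list(metabolites = c("dca", "lca"), thresholds = c(1, 2),
#'             directions = rep("low_in_nonsurvivors", 2), score_cut = 2)
apply_predefined_score <- function(definition, m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  mets <- definition$metabolites
  if (is.null(mets) || length(mets) == 0) {
    stop("predefined score must name at least one metabolite", call. = FALSE)
  }
  stopifnot(length(definition$thresholds) == length(mets),
            length(definition$directions) == length(mets))
  op <- definition$op %||% ">="
  stopifnot(op %in% c(">=", ">"))
  cuts <- setNames(lapply(seq_along(mets), function(i) {
    structure(list(metabolite = mets[i], threshold = definition$thresholds[i],
                   direction = match.arg(definition$directions[i],
                                         c("high_in_nonsurvivors",
                                           "low_in_nonsurvivors")),
                   degenerate = FALSE), class = "cutpoint")
  }), mets)
  absent <- setdiff(mets, colnames(m$values))
  if (length(absent)) {
    stop(sprintf("matrix lacks metabolite(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  sub <- metabolite_matrix(m$values[, mets, drop = FALSE],
                           panel = unname(m$panel[mets]))
  pts <- binarize(sub, cuts)
  scores <- as.integer(rowSums(pts))
  names(scores) <- rownames(pts)
  flag <- if (op == ">=") scores >= definition$score_cut else
    scores > definition$score_cut
  list(scores = scores, flag = as.integer(flag))
}

#' Serialize / restore an MDS model as JSON
#'
#' @param model An `mds_model`.
#' @param path Output (input) JSON path.
#' @return `write_mds_model` invisibly returns `path`; `read_mds_model`
#'   returns the restored `mds_model`.
#' @export
write_mds_model <- function(model, path) {
  stopifnot(inherits(model, "mds_model"))
  obj <- list(
    metabolites = model$metabolites,
    thresholds = vapply(model$cutpoints, `[[`, 0, "threshold"),
    directions = vapply(model$cutpoints, `[[`, "", "direction"),
    n_metabolites = model$n_metabolites,
    score_threshold = model$score_threshold,
    dysbiosis_rule = model$dysbiosis_rule,
    objective = model$objective,
    tolerance = model$tolerance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mds_model
#' @export
read_mds_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cuts <- setNames(lapply(seq_along(obj$metabolites), function(i) {
    structure(list(metabolite = obj$metabolites[i],
                   threshold = obj$thresholds[i],
                   direction = obj$directions[i],
                   degenerate = FALSE), class = "cutpoint")
  }), obj$metabolites)
  structure(list(
    metabolites = obj$metabolites, cutpoints = cuts,
    n_metabolites = obj$n_metabolites,
    score_threshold = obj$score_threshold,
    dysbiosis_rule = obj$dysbiosis_rule,
    objective = obj$objective, tolerance = obj$tolerance,
    selected_metrics = NULL
  ), class = "mds_model")
}
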