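# End-to-end orchestration: prep -> cutpoints -> score assembly -> survival
# evaluation, with strict train/validation hygiene (no validation patient
# influences cutpoints, importance ranking, iteration metrics, model
# selection, or thresholds).

#' Classification performance with 95% confidence intervals
#'
#' Accuracy, sensitivity and specificity (nonsurvivor = positive class) at
#' the rule `score > threshold`, with Wilson score intervals, plus the ROC
#' AUC of the raw score.
#'
#' @param scores Numeric per-patient scores.
#' @param labels Binary outcome (1 = nonsurvivor).
#' @param threshold Dysbiosis threshold (predict positive when
#'   `score > threshold`).
#' @return One-row data frame: `auc`, `accuracy`, `accuracy_lo/hi`,
#'   `sens`, `sens_lo/hi`, `spec`, `spec_lo/hi`.
#' @export
performance_table <- function(scores, labels, threshold) {
  labels <- as_binary(labels)
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("performance_table requires both classes", call. = FALSE)
  }
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  acc_ci <- wilson_ci(tp + tn, length(labels))
  sens_ci <- wilson_ci(tp, tp + fn)
  spec_ci <- wilson_ci(tn, tn + fp)
  auc <- roc_curve(scores, labels)$auc
  data.frame(auc = auc,
             accuracy = (tp + tn) / length(labels),
             accuracy_lo = acc_ci[1], accuracy_hi = acc_ci[2],
             sens = tp / (tp + fn), sens_lo = sens_ci[1], sens_hi = sens_ci[2],
             spec = tn / (tn + fp), spec_lo = spec_ci[1], spec_hi = spec_ci[2])
}

# Small deterministic content hash for manifests (not cryptographic).
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %% 4294967291)
}

#' Run the full MDS pipeline
#'
#' Splits the cohort (stratified by outcome), filters and imputes the
#' metabolite panel (train and validation imputed separately), fits
#' per-metabolite Youden cutpoints on the training cohort only, ranks
#' metabolites by ridge importance, assembles the score iteratively,
#' selects the simplest near-best model, and evaluates it on both cohorts:
#' performance metrics with Wilson CIs, Cox models (continuous and
#' dichotomous MDS, adjusted for the configured covariates) with
#' Schoenfeld PH tests, Kaplan-Meier curve data, and RMST difference at
#' `tau` days.
#'
#' @param cohort Cohort data frame (`patient_id`, `survival_days`, `event`,
#'   `mortality_label`, covariates).
#' @param metabolites A [metabolite_matrix()] covering the cohort patients.
#' @param train_fraction Training fraction (default 0.75).
#' @param seed Master integer seed (split, imputation, bootstrap and ridge
#'   CV sub-seeds are derived from it).
#' @param max_missing_frac,exclusions Passed to
#'   [filter_sparse_metabolites()].
#' @param impute_exempt Metabolites exempt from imputation.
#' @param n_boot Cutpoint bootstrap replicates (default 10).
#' @param tolerance,objective Passed to [select_model()].
#' @param tau RMST horizon in days (default 30).
#' @param covariates Confounder column names in `cohort` for the Cox
#'   models (default `c("cci", "sofa")`).
#' @param out_dir Optional output directory; when given, writes the
#'   cutpoint table, iteration metrics, model JSON, performance and Cox
#'   tables, KM curve data, and a run manifest (all TSV/JSON).
#' @return A `mds_pipeline` list bundle (split, cutpoints, ranking,
#'   iterations, model, scores, performance, cox, km, rmst, manifest).
#' @export
run_pipeline <- function(cohort, metabolites,
                         train_fraction = 0.75, seed = 1L,
                         max_missing_frac = 0.2, exclusions = character(0),
                         impute_exempt = character(0),
                         n_boot = 10L, tolerance = 0.01,
                         objective = "auc", tau = 30,
                         covariates = c("cci", "sofa"),
                         out_dir = NULL) {
  stopifnot(inherits(metabolites, "metabolite_matrix"))
  missing_cov <- setdiff(covariates, colnames(cohort))
  if (length(missing_cov)) {
    stop(sprintf("pipeline stage 'prep': cohort lacks covariate(s) %s",
                 paste(missing_cov, collapse = ", ")), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  split <- stage("split", stratified_split(cohort, train_fraction, seed))
  tr_ids <- split$patient_id[split$assignment == "train"]
  va_ids <- split$patient_id[split$assignment == "validation"]
  coh_tr <- cohort[match(tr_ids, cohort$patient_id), , drop = FALSE]
  coh_va <- cohort[match(va_ids, cohort$patient_id), , drop = FALSE]

  filt <- stage("filter", filter_sparse_metabolites(metabolites,
                                                    max_missing_frac,
                                                    exclusions))
  sub_mat <- function(ids) {
    metabolite_matrix(filt$values[ids, , drop = FALSE],
                      panel = unname(filt$panel))
  }
  m_tr <- stage("impute", impute_pmm(sub_mat(tr_ids), seed = derive_seed(seed, "imp-train"),
                                     exempt = impute_exempt))
  m_va <- stage("impute", impute_pmm(sub_mat(va_ids), seed = derive_seed(seed, "imp-val"),
                                     exempt = impute_exempt))

  lab_tr <- as_binary(coh_tr$mortality_label)
  cuts <- stage("cutpoints", fit_cutpoints(m_tr, lab_tr, n_boot = n_boot,
                                           seed = seed))
  pts_tr <- stage("cutpoints", binarize(m_tr, cuts))
  ranking <- stage("ridge", ridge_importance(pts_tr, lab_tr, seed = seed))
  iters <- stage("iterations", build_iterations(pts_tr, ranking, coh_tr,
                                                tau = tau))
  model <- stage("select", select_model(iters, tolerance = tolerance,
                                        cuts = cuts, objective = objective))

  sc_tr <- stage("score", apply_score(model, m_tr))
  sc_va <- stage("score", apply_score(model, m_va))

  perf <- rbind(
    cbind(cohort = "train",
          performance_table(sc_tr$scores, lab_tr, model$score_threshold)),
    cbind(cohort = "validation",
          performance_table(sc_va$scores, as_binary(coh_va$mortality_label),
                            model$score_threshold))
  )

  eval_surv <- function(coh, sc, which) {
    covm <- as.matrix(coh[, covariates, drop = FALSE])
    out <- list()
    out$cox_continuous <- tryCatch({
      fit <- cox_fit(cbind(covm, mds = sc$scores), coh$survival_days,
                     coh$event)
      fit$ph <- schoenfeld_ph_test(fit, cbind(covm, mds = sc$scores),
                                   coh$survival_days, coh$event)
      fit
    }, error = function(e) {
      warning(sprintf("%s continuous Cox model failed: %s", which,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    out$cox_dichotomous <- tryCatch({
      fit <- cox_fit(cbind(covm, mds_high = sc$dysbiosis), coh$survival_days,
                     coh$event)
      fit$ph <- schoenfeld_ph_test(fit, cbind(covm, mds_high = sc$dysbiosis),
                                   coh$survival_days, coh$event)
      fit
    }, error = function(e) {
      warning(sprintf("%s dichotomous Cox model failed: %s", which,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    out$km <- list(low = kaplan_meier(coh$survival_days[sc$dysbiosis == 0],
                                      coh$event[sc$dysbiosis == 0]),
                   high = if (any(sc$dysbiosis == 1)) {
                     kaplan_meier(coh$survival_days[sc$dysbiosis == 1],
                                  coh$event[sc$dysbiosis == 1])
                   })
    out$rmst <- tryCatch(rmst_diff(coh$survival_days, coh$event,
                                   sc$dysbiosis, tau = tau),
                         error = function(e) NULL)
    out$logrank <- tryCatch(log_rank(coh$survival_days, coh$event,
                                     sc$dysbiosis),
                            error = function(e) NULL)
    out
  }
  surv_tr <- stage("survival", eval_surv(coh_tr, sc_tr, "train"))
  surv_va <- stage("survival", eval_surv(coh_va, sc_va, "validation"))

  cfg <- list(train_fraction = train_fraction, seed = seed,
              max_missing_frac = max_missing_frac, exclusions = exclusions,
              impute_exempt = impute_exempt, n_boot = n_boot,
              tolerance = tolerance, objective = objective, tau = tau,
              covariates = covariates)
  manifest <- list(
    config = cfg,
    config_hash = config_hash(cfg),
    seeds = list(master = seed,
                 split = derive_seed(seed, "split"),
                 impute_train = derive_seed(seed, "imp-train"),
                 impute_validation = derive_seed(seed, "imp-val"),
                 ridge_cv = derive_seed(seed, "ridge-cv")),
    n_train = length(tr_ids), n_validation = length(va_ids),
    dropped_metabolites = attr(filt, "dropped"),
    selected_k = model$n_metabolites,
    score_threshold = model$score_threshold
  )

  bundle <- structure(list(
    split = split, cutpoints = cuts, ranking = ranking,
    iterations = iters, model = model,
    scores = list(train = sc_tr, validation = sc_va),
    performance = perf,
    survival = list(train = surv_tr, validation = surv_va),
    manifest = manifest
  ), class = "mds_pipeline")

  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir)
  bundle
}

cox_table <- function(fit) {
  if (is.null(fit)) return(NULL)
  df <- data.frame(covariate = fit$covariates, hr = fit$hr,
                   ci_lower = fit$ci95[, "lower"],
                   ci_upper = fit$ci95[, "upper"], p = fit$p_lrt,
                   row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(fit$ph)) {
    df$ph_p <- fit$ph$table$p
    attr(df, "ph_global_p") <- fit$ph$global$p
  }
  df
}

write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    if (!is.null(df)) write.table(df, file.path(out_dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  }
  wt(cutpoint_table(bundle$cutpoints), "cutpoints.tsv")
  wt(as.data.frame(bundle$iterations), "iterations.tsv")
  wt(bundle$performance, "performance.tsv")
  for (coh in c("train", "validation")) {
    wt(cox_table(bundle$survival[[coh]]$cox_continuous),
       sprintf("cox_continuous_%s.tsv", coh))
    wt(cox_table(bundle$survival[[coh]]$cox_dichotomous),
       sprintf("cox_dichotomous_%s.tsv", coh))
    km <- bundle$survival[[coh]]$km
    for (g in names(km)) {
      if (is.null(km[[g]])) next
      wt(data.frame(time = km[[g]]$event_times, n_at_risk = km[[g]]$n_at_risk,
                    n_events = km[[g]]$n_events, survival = km[[g]]$survival),
         sprintf("km_%s_%s.tsv", coh, g))
    }
  }
  write_mds_model(bundle$model, file.path(out_dir, "model.json"))
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' @export
print.mds_pipeline <- function(x, ...) {
  cat("MDS pipeline run\n")
  cat(sprintf("  train/validation: %d/%d patients\n",
              x$manifest$n_train, x$manifest$n_validation))
  print(x$model)
  cat("Performance:\n")
  print(cbind(x$performance[, c("cohort", "auc", "accuracy", "sens", "spec")]),
        digits = 3)
  invisible(x)
}
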