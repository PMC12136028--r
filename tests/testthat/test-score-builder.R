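make_points <- function(mat) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("P%04d", seq_len(nrow(mat)))
  structure(mat, class = c("point_matrix", "matrix"))
}

test_that("ridge importance puts a perfectly predictive column first", {
  set.seed(1)
  n <- 2000
  lab <- rbinom(n, 1, 0.3)
  X <- cbind(signal = lab,
             matrix(rbinom(n * 6, 1, 0.4), n, 6,
                    dimnames = list(NULL, paste0("noise", 1:6))))
  r <- ridge_importance(make_points(X), lab, seed = 1)
  expect_identical(r$metabolite[1], "signal")
  expect_identical(r$rank, seq_len(7L))
  expect_true(all(diff(r$abs_beta) <= 1e-12))
})

test_that("duplicated predictive columns share their coefficient", {
  set.seed(2)
  n <- 400
  z <- rbinom(n, 1, 0.5)
  lab <- rbinom(n, 1, plogis(-1 + 2 * z))
  X <- cbind(a = z, b = z, c = rbinom(n, 1, 0.5))
  r <- ridge_importance(make_points(X), lab, seed = 1)
  expect_equal(r$beta[r$metabolite == "a"], r$beta[r$metabolite == "b"],
               tolerance = 1e-6)
})

test_that("coefficient norm shrinks monotonically toward zero as the penalty grows", {
  set.seed(3)
  n <- 200
  z <- rbinom(n, 1, 0.5)
  lab <- rbinom(n, 1, plogis(-0.5 + 1.5 * z))
  X <- scale(cbind(z, rbinom(n, 1, 0.4)))
  norms <- vapply(c(0.1, 1, 10, 100, 1000, 1e5), function(lam) {
    sqrt(sum(mdscore:::ridge_solve(X, lab, lam)$beta^2))
  }, 0)
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-3)
})

test_that("ridge solutions match the glmnet oracle at matched penalties", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  n <- 300
  X <- matrix(rbinom(n * 5, 1, 0.4), n, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  lab <- rbinom(n, 1, plogis(-1 + X %*% c(1.5, -1, 0.5, 0, 0)))
  Xs <- scale(X)
  for (lam in c(0.5, 5, 50)) {
    ours <- mdscore:::ridge_solve(Xs, lab, lam, "binomial")
    # glmnet minimizes -(1/n) loglik + lambda/2 ||beta||^2 for alpha = 0
    g <- glmnet::glmnet(Xs, lab, family = "binomial", alpha = 0,
                        lambda = lam / n, standardize = FALSE,
                        thresh = 1e-14)
    expect_equal(unname(ours$beta), as.numeric(g$beta), tolerance = 1e-4)
  }
})

test_that("constant columns are dropped with a warning and ranked last", {
  set.seed(5)
  n <- 120
  lab <- rbinom(n, 1, 0.4)
  X <- cbind(good = lab, flat = rep(1L, n), other = rbinom(n, 1, 0.5))
  expect_warning(r <- ridge_importance(make_points(X), lab, seed = 1), "flat")
  expect_identical(r$metabolite[r$rank == 3], "flat")
  expect_equal(r$beta[r$metabolite == "flat"], 0)
  expect_error(ridge_importance(make_points(X), rep(1L, n)), "class")
})

test_that("iterative score assembly is cumulative and propagates separation", {
  labs <- rep(c(0L, 1L), each = 10)
  coh <- toy_cohort(labs, days = ifelse(labs == 1, 5, 30))
  X <- cbind(perfect = labs,
             part = c(rep(0L, 15), rep(1L, 5)),
             noise = rep(c(0L, 1L), 10))
  rownames(X) <- coh$patient_id
  rk <- data.frame(metabolite = c("perfect", "part", "noise"),
                   beta = c(3, 1, 0.1), abs_beta = c(3, 1, 0.1), rank = 1:3)
  it <- build_iterations(make_points(X), rk, coh)
  expect_equal(it$accuracy[1], 1)
  expect_equal(it$auc[1], 1)
  # score increments are 0/1 per patient
  sc <- attr(it, "scores")
  expect_true(all(apply(sc, 1, diff) %in% 0:1))
  # thresholds on integer scores are half-integers
  expect_true(all(it$score_threshold %% 1 == 0.5))
  # AUC at k = K equals independently computed AUC of the full row sum
  full <- roc_curve(rowSums(X), labs)
  expect_equal(it$auc[3], max(full$auc, 1 - full$auc), tolerance = 1e-12)
})

test_that("model selection applies the parsimony rule", {
  fake <- data.frame(k = 1:4, added = letters[1:4],
                     score_threshold = c(0.5, 1.5, 1.5, 2.5),
                     accuracy = c(0.6, 0.8, 0.8, 0.81),
                     auc = c(0.6, 0.8, 0.8, 0.81),
                     sens = 0.5, spec = 0.5, rmst_diff_days = 1,
                     logrank_p = 0.5, degenerate = FALSE)
  class(fake) <- c("score_iterations", "data.frame")
  attr(fake, "order") <- letters[1:4]
  expect_equal(select_model(fake, tolerance = 0.01)$n_metabolites, 2)
  expect_equal(select_model(fake, tolerance = 0)$n_metabolites, 4)
  expect_equal(select_model(fake, tolerance = 0,
                            objective = "accuracy")$n_metabolites, 4)
  one <- fake[1, , drop = FALSE]
  attr(one, "order") <- "a"
  expect_equal(select_model(one, 0.01)$n_metabolites, 1)
})

test_that("apply_score enforces the threshold rule and matches brute force", {
  set.seed(6)
  n <- 50
  vals <- matrix(rexp(n * 4) + 0.1, n, 4,
                 dimnames = list(sprintf("P%04d", 1:n), paste0("m", 1:4)))
  m <- metabolite_matrix(vals)
  cuts <- setNames(lapply(1:4, function(j) {
    structure(list(metabolite = paste0("m", j),
                   threshold = median(vals[, j]),
                   direction = if (j %% 2) "high_in_nonsurvivors"
                               else "low_in_nonsurvivors",
                   degenerate = FALSE), class = "cutpoint")
  }), paste0("m", 1:4))
  model <- structure(list(metabolites = paste0("m", 1:4), cutpoints = cuts,
                          n_metabolites = 4L, score_threshold = 2.5,
                          dysbiosis_rule = "score > threshold",
                          objective = "auc", tolerance = 0.01,
                          selected_metrics = NULL), class = "mds_model")
  res <- apply_score(model, m)
  manual <- rowSums(cbind(vals[, 1] >= cuts$m1$threshold,
                          vals[, 2] <= cuts$m2$threshold,
                          vals[, 3] >= cuts$m3$threshold,
                          vals[, 4] <= cuts$m4$threshold))
  expect_equal(unname(res$scores), unname(as.integer(manual)))
  expect_equal(res$dysbiosis, as.integer(res$scores > 2.5))
  expect_error(apply_score(model, metabolite_matrix(vals[, 1:2])), "m3")
})

test_that("the half-integer dysbiosis rule separates 7 from 8 at threshold 7.5", {
  ids <- paste0("m", 1:13)
  vals <- matrix(0, 2, 13, dimnames = list(c("A", "B"), ids))
  vals["A", 1:8] <- 10   # 8 metabolites on the nonsurvivor side
  vals["B", 1:7] <- 10   # 7 metabolites
  cuts <- setNames(lapply(ids, function(id) {
    structure(list(metabolite = id, threshold = 5,
                   direction = "high_in_nonsurvivors", degenerate = FALSE),
              class = "cutpoint")
  }), ids)
  model <- structure(list(metabolites = ids, cutpoints = cuts,
                          n_metabolites = 13L, score_threshold = 7.5,
                          dysbiosis_rule = "score > threshold",
                          objective = "auc", tolerance = 0.01,
                          selected_metrics = NULL), class = "mds_model")
  res <- apply_score(model, metabolite_matrix(vals))
  expect_equal(unname(res$scores), c(8L, 7L))
  expect_equal(unname(res$dysbiosis), c(1L, 0L))
})

test_that("predefined scores follow the user rule", {
  vals <- matrix(c(0.5, 3, 0.2, 5), 2, 2,
                 dimnames = list(c("A", "B"), c("dca", "lca")))
  m <- metabolite_matrix(vals)
  def <- list(metabolites = c("dca", "lca"), thresholds = c(1, 1),
              directions = rep("low_in_nonsurvivors", 2), score_cut = 2,
              op = ">=")
  res <- apply_predefined_score(def, m)
  expect_equal(unname(res$scores), c(2L, 0L))
  expect_equal(unname(res$flag), c(1L, 0L))
  expect_error(apply_predefined_score(list(metabolites = character(0)), m),
               "at least one")
})

test_that("models serialize to JSON and back without losing scoring behaviour", {
  set.seed(7)
  sc <- generate_cohort(sim_config(150, missing_rate = 0, seed = 10))
  lab <- sc$cohort$mortality_label
  cuts <- fit_cutpoints(sc$metabolites, lab, n_boot = 0)
  pts <- binarize(sc$metabolites, cuts)
  rk <- ridge_importance(pts, lab, seed = 2)
  it <- build_iterations(pts, rk, sc$cohort)
  model <- select_model(it, cuts = cuts)
  path <- withr::local_tempfile(fileext = ".json")
  write_mds_model(model, path)
  back <- read_mds_model(path)
  expect_identical(apply_score(model, sc$metabolites)$scores,
                   apply_score(back, sc$metabolites)$scores)
  expect_equal(back$score_threshold, model$score_threshold)
})

test_that("end-to-end scoring is deterministic for a fixed seed", {
  sc <- generate_cohort(sim_config(150, missing_rate = 0, seed = 12))
  lab <- sc$cohort$mortality_label
  run_once <- function() {
    cuts <- fit_cutpoints(sc$metabolites, lab, n_boot = 5, seed = 3)
    pts <- binarize(sc$metabolites, cuts)
    rk <- ridge_importance(pts, lab, seed = 3)
    select_model(build_iterations(pts, rk, sc$cohort), cuts = cuts)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$score_threshold, b$score_threshold)
})
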