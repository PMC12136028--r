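# Cohort preparation: container for metabolite panels, stratified splitting,
# sparse-metabolite filtering, predictive-mean-matching imputation, and the
# univariate group-comparison statistics used for baseline tables and
# volcano summaries.

#' Patients-by-metabolites concentration matrix
#'
#' Thin container pairing a nonnegative concentration matrix (rows =
#' patients, columns = metabolites; `NA` marks missing values) with a
#' per-metabolite panel tag (`"absolute"` for mM quantification,
#' `"relative"` for arbitrary units).
#'
#' @param values Numeric matrix with patient row names and metabolite
#'   column names; observed entries must be `>= 0`.
#' @param panel Character vector, one of `"absolute"`/`"relative"` per
#'   column (recycled if length 1).
#' @return A `metabolite_matrix` object.
#' @export
metabolite_matrix <- function(values, panel = "absolute") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("met%02d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%04d", seq_len(nrow(values)))
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("metabolite concentrations must be nonnegative", call. = FALSE)
  }
  panel <- rep_len(match.arg(panel, c("absolute", "relative"),
                             several.ok = TRUE), ncol(values))
  structure(list(values = values, panel = setNames(panel, colnames(values))),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("Metabolite matrix: %d patients x %d metabolites (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Stratified train/validation split
#'
#' Assigns patients to train/validation within each outcome stratum using
#' largest-remainder rounding, so a 75% split of 196 patients (136 survivors,
#' 60 nonsurvivors) yields exactly 147 train / 49 validation.
#'
#' @param cohort Cohort data frame with `patient_id` and `mortality_label`.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed (assignment is seed-deterministic).
#' @return A `split_assignment` data frame (`patient_id`, `stratum`,
#'   `assignment`) with attributes `train_fraction` and `seed`.
#' @export
#' @examples
#' coh <- data.frame(patient_id = sprintf("P%03d", 1:196),
#'                   mortality_label = rep(c(0, 1), c(136, 60)))
#' sp <- stratified_split(coh, 0.75, seed = 1)
#' table(sp$assignment)
stratified_split <- function(cohort, train_fraction, seed) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  lab <- as_binary(cohort$mortality_label, "mortality_label")
  for (s in c(0L, 1L)) {
    if (!any(lab == s)) {
      stop(sprintf("outcome stratum '%d' is empty", s), call. = FALSE)
    }
  }
  n_s <- table(factor(lab, levels = c(0L, 1L)))
  target_total <- round(train_fraction * length(lab))
  base <- floor(train_fraction * n_s)
  rem <- train_fraction * n_s - base
  extra <- target_total - sum(base)
  take <- as.numeric(base)
  if (extra > 0) {
    ord <- order(rem, decreasing = TRUE)
    take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
  }
  assignment <- character(length(lab))
  with_seed(derive_seed(seed, "split"), {
    for (i in 1:2) {
      s <- c(0L, 1L)[i]
      idx <- which(lab == s)
      tr <- sample(idx, take[i])
      assignment[tr] <- "train"
      assignment[setdiff(idx, tr)] <- "validation"
    }
  })
  out <- data.frame(patient_id = cohort$patient_id, stratum = lab,
                    assignment = assignment, stringsAsFactors = FALSE)
  attr(out, "train_fraction") <- train_fraction
  attr(out, "seed") <- seed
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Drop metabolites with excessive missingness
#'
#' Removes metabolites whose missing fraction strictly exceeds
#' `max_missing_frac` (a metabolite missing in exactly 20% of patients is
#' retained at the default threshold) plus any explicit exclusions.
#'
#' @param m A [metabolite_matrix()].
#' @param max_missing_frac Maximum tolerated missing fraction (default 0.2).
#' @param exclusions Metabolite ids to drop regardless of missingness.
#' @return The filtered `metabolite_matrix`, with attribute `dropped`
#'   recording the removed ids and reasons.
#' @export
filter_sparse_metabolites <- function(m, max_missing_frac = 0.2,
                                      exclusions = character(0)) {
  stopifnot(inherits(m, "metabolite_matrix"),
            max_missing_frac >= 0, max_missing_frac < 1)
  frac <- colMeans(is.na(m$values))
  drop_sparse <- names(frac)[frac > max_missing_frac]
  drop_excl <- intersect(exclusions, colnames(m$values))
  dropped <- union(drop_sparse, drop_excl)
  keep <- setdiff(colnames(m$values), dropped)
  if (length(keep) == 0) {
    stop("all metabolites dropped by missingness filter/exclusions",
         call. = FALSE)
  }
  out <- metabolite_matrix(m$values[, keep, drop = FALSE],
                           panel = unname(m$panel[keep]))
  attr(out, "dropped") <- data.frame(
    metabolite = dropped,
    reason = ifelse(dropped %in% drop_excl & !(dropped %in% drop_sparse),
                    "excluded", "sparse"),
    missing_frac = frac[dropped],
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Predictive-mean-matching imputation
#'
#' Single-imputation PMM: for each metabolite with missing entries, a linear
#' model of that metabolite on the other metabolites is fit on complete
#' cases; each missing cell is filled with the observed value of one of the
#' `donors` patients whose predicted mean is closest to the missing case's
#' prediction (the donor is drawn uniformly among the `donors` nearest,
#' seed-deterministically). Imputed values therefore always belong to the
#' metabolite's observed support.
#'
#' @param m A [metabolite_matrix()]; every retained metabolite should have
#'   missing fraction at or below 20% (see [filter_sparse_metabolites()]).
#' @param donors Number of candidate donors (default 5).
#' @param seed Integer seed for donor draws.
#' @param exempt Metabolite ids left untouched (their missing cells, if any,
#'   are preserved).
#' @return A `metabolite_matrix` with missing cells filled.
#' @export
impute_pmm <- function(m, donors = 5L, seed = 1L, exempt = character(0)) {
  stopifnot(inherits(m, "metabolite_matrix"), donors >= 1)
  vals <- m$values
  targets <- setdiff(colnames(vals)[colSums(is.na(vals)) > 0], exempt)
  if (length(targets) == 0) return(m)
  # temporary mean-filled design so predictor gaps do not block prediction
  filled <- vals
  for (j in seq_len(ncol(filled))) {
    jj <- is.na(filled[, j])
    if (any(jj)) filled[jj, j] <- mean(vals[, j], na.rm = TRUE)
  }
  with_seed(derive_seed(seed, "pmm"), {
    for (tg in targets) {
      obs <- !is.na(vals[, tg])
      if (sum(obs) < donors) {
        stop(sprintf("metabolite '%s' has fewer observed values (%d) than donors (%d)",
                     tg, sum(obs), donors), call. = FALSE)
      }
      preds <- setdiff(colnames(vals), tg)
      if (length(preds) == 0) {
        # no covariates: predicted mean is constant, donors are random observed
        yhat <- rep(mean(vals[obs, tg]), nrow(vals))
      } else {
        df <- data.frame(.y = vals[, tg], filled[, preds, drop = FALSE],
                         check.names = FALSE)
        fit <- lm(.y ~ ., data = df[obs, , drop = FALSE])
        yhat <- suppressWarnings(predict(fit, newdata = df))
      }
      for (i in which(!obs)) {
        d <- abs(yhat[obs] - yhat[i])
        cand <- order(d)[seq_len(donors)]
        pick <- cand[sample.int(donors, 1L)]
        vals[i, tg] <- vals[obs, tg][pick]
      }
    }
  })
  metabolite_matrix(vals, panel = unname(m$panel))
}

#' Yates-corrected 2x2 chi-square test
#'
#' Two-sided chi-square test with continuity correction on a 2x2 table
#' given as counts `(a, b)` for group 1 and `(c, d)` for group 2.
#'
#' @param a,b,c,d Nonnegative integer cell counts (rows = groups, columns =
#'   yes/no).
#' @return A one-row data frame with `statistic`, `df`, and `p`.
#' @export
#' @examples
#' chi_square_2x2(38, 64, 27, 18)  # p = 0.017
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  n <- sum(counts)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) {
    stop("2x2 chi-square undefined: zero margin", call. = FALSE)
  }
  num <- max(0, abs(a * d - b * c) - n / 2)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  data.frame(statistic = stat, df = 1L,
             p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration (via the Mann-Whitney distribution when there are no
#' ties, full permutation enumeration otherwise when feasible) for small
#' samples; tie-corrected normal approximation with continuity correction
#' for `n >= 50` per group or when enumeration is infeasible.
#'
#' @param x,y Nonempty numeric vectors (missing values dropped).
#' @param exact Force (`TRUE`)/suppress (`FALSE`) exact enumeration;
#'   default `NULL` chooses automatically.
#' @return One-row data frame with `u` (Mann-Whitney U for `x`), `p`, and
#'   `method`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p  # exact 0.1
rank_sum_test <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("rank_sum_test requires nonempty groups", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  use_exact <- exact %||% (nx < 50 && ny < 50)
  if (use_exact && !ties) {
    # exact Mann-Whitney null distribution
    p <- if (u > nx * ny / 2) {
      stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE) * 2
    } else {
      stats::pwilcox(u, nx, ny) * 2
    }
    p <- min(1, p)
    method <- "exact"
  } else if (use_exact && ties && choose(nx + ny, nx) <= 2e5) {
    # enumerate all label assignments; two-sided p by |U - mean| ordering
    combs <- utils::combn(nx + ny, nx)
    rr <- rank(c(x, y))
    us <- colSums(matrix(rr[combs], nrow = nx)) - nx * (nx + 1) / 2
    centre <- nx * ny / 2
    p <- mean(abs(us - centre) >= abs(u - centre) - 1e-9)
    method <- "exact-permutation"
  } else {
    n <- nx + ny
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    z <- u - nx * ny / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approx"
  }
  data.frame(u = u, p = p, method = method, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values (same order as input), each `>=` its p-value
#'   and capped at 1.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Volcano statistics for a relative metabolite panel
#'
#' Per metabolite: log2 fold change of the survivor-group median over the
#' nonsurvivor-group median (when either median is zero, half the smallest
#' positive observed value of that metabolite is added to both), rank-sum p,
#' BH q across metabolites, and a hit flag (`|log2fc| > lfc_cut` and
#' `q < q_cut`). Metabolites entirely missing in one group are skipped with
#' a warning.
#'
#' @param m A [metabolite_matrix()].
#' @param cohort Cohort data frame with `patient_id` and `mortality_label`,
#'   covering the matrix rows.
#' @param lfc_cut,q_cut Hit thresholds (defaults 0.75 and 0.1).
#' @return Data frame with `metabolite`, `log2fc`, `statistic`, `p`, `q`,
#'   `hit`.
#' @export
volcano_stats <- function(m, cohort, lfc_cut = 0.75, q_cut = 0.1) {
  stopifnot(inherits(m, "metabolite_matrix"))
  lab <- setNames(as_binary(cohort$mortality_label), cohort$patient_id)
  lab <- lab[rownames(m$values)]
  if (any(is.na(lab))) stop("cohort does not cover all matrix patients", call. = FALSE)
  if (!any(lab == 0) || !any(lab == 1)) {
    stop("both outcome groups must be nonempty", call. = FALSE)
  }
  rows <- lapply(colnames(m$values), function(id) {
    v <- m$values[, id]
    vs <- v[lab == 0]; vn <- v[lab == 1]
    vs <- vs[!is.na(vs)]; vn <- vn[!is.na(vn)]
    if (length(vs) == 0 || length(vn) == 0) {
      warning(sprintf("metabolite '%s' all-missing in one group; skipped", id),
              call. = FALSE)
      return(NULL)
    }
    ms <- median(vs); mn <- median(vn)
    if (ms == 0 || mn == 0) {
      pos <- v[!is.na(v) & v > 0]
      pc <- if (length(pos)) min(pos) / 2 else 1
      ms <- ms + pc; mn <- mn + pc
    }
    rs <- rank_sum_test(vs, vn)
    data.frame(metabolite = id, log2fc = log2(ms / mn),
               statistic = rs$u, p = rs$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no testable metabolites", call. = FALSE)
  out$q <- bh_adjust(out$p)
  out$hit <- abs(out$log2fc) > lfc_cut & out$q < q_cut
  rownames(out) <- NULL
  out
}
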