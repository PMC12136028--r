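# Synthetic cohort generation.
#
# The generator emulates the statistical structure of a prospective ICU
# cohort: ~30% 30-day mortality, integer comorbidity (CCI) and organ-failure
# (SOFA) scores correlated with outcome, a panel of strictly positive
# log-normal fecal metabolite concentrations of which a planted subset is
# shifted between outcome groups, right-censoring at the 30-day horizon, and
# Dirichlet-type taxonomic relative-abundance profiles with optional
# pathobiont domination.

#' Simulation configuration
#'
#' Validates and assembles the configuration for [generate_cohort()] and
#' [generate_taxa()].
#'
#' @param n_patients Number of patients (positive integer).
#' @param n_metabolites Number of metabolites in the panel (default 30,
#'   matching a typical absolute-quantification panel).
#' @param n_informative Number of planted discriminative metabolites
#'   (`<= n_metabolites`); their log-scale medians differ between outcome
#'   groups by `effect_log2fc` (in log2 units).
#' @param effect_log2fc Log2 shift of informative metabolite medians between
#'   survivors and nonsurvivors. The shift direction alternates per planted
#'   metabolite (some high, some low in nonsurvivors).
#' @param mortality_rate Target marginal 30-day mortality, in (0, 1).
#'   Default 0.306.
#' @param missing_rate Per-cell missing-completely-at-random rate in
#'   \[0, 0.3).
#' @param horizon_days Administrative censoring horizon in days (default 30).
#' @param n_taxa Number of taxa in simulated profiles (>= 2).
#' @param domination_prob Probability that a profile is dominated (> 50%
#'   relative abundance) by the designated pathobiont taxon.
#' @param seed Integer seed; a single user seed from which per-component
#'   sub-streams (outcome, metabolites, taxa) are derived deterministically.
#' @param sdlog Log-scale standard deviation of metabolite concentrations
#'   (default 1.0).
#' @param rho Optional equicorrelation of metabolite log-concentrations in
#'   \[0, 1) (default 0, independence).
#' @param event_time_dist `"uniform"` (death days uniform on
#'   `{1..horizon_days}`) or `"exponential"` (exponential event times driven
#'   by a latent binary risk group with hazard ratio `hazard_ratio`,
#'   censored at the horizon).
#' @param hazard_ratio Planted hazard ratio for `event_time_dist =
#'   "exponential"`; ignored (and recorded as `NA`) otherwise.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 100, seed = 1)
sim_config <- function(n_patients,
                       n_metabolites = 30L,
                       n_informative = 5L,
                       effect_log2fc = 2,
                       mortality_rate = 0.306,
                       missing_rate = 0.05,
                       horizon_days = 30L,
                       n_taxa = 12L,
                       domination_prob = 0.2,
                       seed = 1L,
                       sdlog = 1.0,
                       rho = 0,
                       event_time_dist = c("uniform", "exponential"),
                       hazard_ratio = 2) {
  check_flag(length(n_patients) == 1 && n_patients >= 2 && n_patients == round(n_patients),
             "n_patients", "must be a positive integer >= 2")
  check_flag(n_metabolites >= 1 && n_metabolites == round(n_metabolites),
             "n_metabolites", "must be a positive integer")
  check_flag(n_informative >= 0 && n_informative <= n_metabolites,
             "n_informative", "must be an integer in [0, n_metabolites]")
  check_flag(is.numeric(effect_log2fc) && length(effect_log2fc) == 1,
             "effect_log2fc", "must be a single real")
  check_flag(mortality_rate > 0 && mortality_rate < 1,
             "mortality_rate", "must lie in (0, 1)")
  check_flag(missing_rate >= 0 && missing_rate < 0.3,
             "missing_rate", "must lie in [0, 0.3)")
  check_flag(horizon_days >= 1 && horizon_days == round(horizon_days),
             "horizon_days", "must be a positive integer")
  check_flag(n_taxa >= 2 && n_taxa == round(n_taxa),
             "n_taxa", "must be an integer >= 2")
  check_flag(domination_prob >= 0 && domination_prob <= 1,
             "domination_prob", "must lie in [0, 1]")
  check_flag(length(seed) == 1 && is.finite(seed) && seed == round(seed),
             "seed", "must be a single integer")
  check_flag(sdlog > 0, "sdlog", "must be positive")
  check_flag(rho >= 0 && rho < 1, "rho", "must lie in [0, 1)")
  event_time_dist <- match.arg(event_time_dist)
  check_flag(hazard_ratio > 0, "hazard_ratio", "must be positive")
  structure(list(
    n_patients = as.integer(n_patients),
    n_metabolites = as.integer(n_metabolites),
    n_informative = as.integer(n_informative),
    effect_log2fc = effect_log2fc,
    mortality_rate = mortality_rate,
    missing_rate = missing_rate,
    horizon_days = as.integer(horizon_days),
    n_taxa = as.integer(n_taxa),
    domination_prob = domination_prob,
    seed = as.integer(seed),
    sdlog = sdlog,
    rho = rho,
    event_time_dist = event_time_dist,
    hazard_ratio = if (event_time_dist == "exponential") hazard_ratio else NA_real_
  ), class = "sim_config")
}

# Calibrate the logistic intercept so the mean event probability over the
# realized covariates equals the target rate.
calibrate_intercept <- function(lp, target) {
  uniroot(function(a) mean(plogis(a + lp)) - target,
          interval = c(-20, 20), tol = 1e-10)$root
}

#' Generate a synthetic ICU cohort
#'
#' Draws covariates (CCI, SOFA), a 30-day mortality outcome from a logistic
#' model on those covariates calibrated to `mortality_rate`, survival times
#' (nonsurvivors die uniformly on `{1..horizon}`; survivors are censored at
#' the horizon), and a patients-by-metabolites log-normal concentration
#' matrix with `n_informative` planted discriminative metabolites and
#' missing-completely-at-random gaps. A `truth` record carries the planted
#' metabolite ids, directions, shifts and (for exponential event times) the
#' planted hazard ratio.
#'
#' @param config A [sim_config()] object.
#' @return A `synthetic_cohort` list with elements `cohort` (data frame:
#'   `patient_id`, `survival_days`, `event`, `mortality_label`, `cci`,
#'   `sofa`), `metabolites` (a [metabolite_matrix()]), `taxa` (see
#'   [generate_taxa()]), and `truth`.
#' @export
#' @examples
#' sc <- generate_cohort(sim_config(n_patients = 50, seed = 7))
#' table(sc$cohort$mortality_label)
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  # --- outcome stream: covariates, labels, survival times -----------------
  outc <- with_seed(derive_seed(config$seed, "outcome"), {
    cci <- pmin(rpois_int(n, 4.5), 15L)
    sofa <- pmin(rpois_int(n, 8), 24L)
    lp <- 0.18 * (cci - mean(cci)) + 0.15 * (sofa - mean(sofa))
    a <- calibrate_intercept(lp, config$mortality_rate)
    if (config$event_time_dist == "uniform") {
      label <- rbinom(n, 1L, plogis(a + lp))
      days <- ifelse(label == 1L,
                     sample.int(config$horizon_days, n, replace = TRUE),
                     config$horizon_days)
      risk_group <- rep(NA_integer_, n)
    } else {
      # latent risk group with planted hazard ratio; overall event fraction
      # calibrated to mortality_rate at the horizon
      risk_group <- rbinom(n, 1L, plogis(a + lp))
      h <- config$hazard_ratio
      lam0 <- uniroot(function(l) {
        mean(1 - exp(-l * h^risk_group * config$horizon_days)) - config$mortality_rate
      }, interval = c(1e-8, 10), tol = 1e-12)$root
      t_ev <- rexp(n, rate = lam0 * h^risk_group)
      label <- as.integer(t_ev <= config$horizon_days)
      days <- ifelse(label == 1L, pmax(1L, ceiling(t_ev)), config$horizon_days)
    }
    list(cci = cci, sofa = sofa, label = as.integer(label),
         days = as.integer(days), risk_group = risk_group)
  })

  cohort <- data.frame(
    patient_id = ids,
    survival_days = outc$days,
    event = outc$label,
    mortality_label = outc$label,
    cci = outc$cci,
    sofa = outc$sofa,
    stringsAsFactors = FALSE
  )

  # --- metabolite stream --------------------------------------------------
  k <- config$n_metabolites
  met_names <- sprintf("met%02d", seq_len(k))
  met <- with_seed(derive_seed(config$seed, "metabolites"), {
    base_meanlog <- runif(k, -1, 1.5)          # panel spans ~0.4..4.5 mM medians
    informative <- if (config$n_informative > 0) seq_len(config$n_informative) else integer(0)
    # alternate planted direction: odd planted ids high in nonsurvivors
    dir_sign <- ifelse(seq_along(informative) %% 2 == 1, 1, -1)
    shift <- config$effect_log2fc * log(2)
    z <- matrix(rnorm(n * k), n, k)
    if (config$rho > 0) {
      common <- rnorm(n)
      z <- sqrt(config$rho) * common + sqrt(1 - config$rho) * z
    }
    mu <- matrix(base_meanlog, n, k, byrow = TRUE)
    if (length(informative)) {
      mu[, informative] <- mu[, informative] +
        outer(outc$label, dir_sign * shift)
    }
    vals <- exp(mu + config$sdlog * z)
    miss <- matrix(runif(n * k) < config$missing_rate, n, k)
    vals[miss] <- NA_real_
    list(values = vals, informative = informative, dir_sign = dir_sign,
         base_meanlog = base_meanlog)
  })
  dimnames(met$values) <- list(ids, met_names)

  metabolites <- metabolite_matrix(met$values,
                                   panel = rep("absolute", k))

  taxa <- generate_taxa(config)

  truth <- list(
    informative_ids = met_names[met$informative],
    directions = if (length(met$informative)) {
      ifelse(met$dir_sign > 0, "high_in_nonsurvivors", "low_in_nonsurvivors")
    } else character(0),
    effect_log2fc = config$effect_log2fc,
    # planted threshold: log-scale midpoint between the two group medians
    thresholds = if (length(met$informative)) {
      exp(met$base_meanlog[met$informative] +
            met$dir_sign * config$effect_log2fc * log(2) / 2)
    } else numeric(0),
    hazard_ratio = config$hazard_ratio,
    risk_group = outc$risk_group
  )

  structure(list(cohort = cohort, metabolites = metabolites,
                 taxa = taxa, truth = truth, config = config),
            class = "synthetic_cohort")
}

# Poisson draw coerced to integer (kept separate so the outcome stream is
# easy to reason about).
rpois_int <- function(n, lambda) as.integer(stats::rpois(n, lambda))

#' Generate synthetic taxonomic profiles
#'
#' Per patient, Dirichlet-distributed relative abundances over
#' `config$n_taxa` taxa, summing to 100. With probability
#' `config$domination_prob` the designated pathobiont taxon (the first,
#' labelled as *Enterococcus*) is forced above 50% relative abundance.
#'
#' @param config A [sim_config()] object.
#' @return A `taxa_profiles` object: matrix of taxa (rows, lineage-named) by
#'   patients (columns), percentages summing to 100 per column, with
#'   attribute `pathobiont` naming the designated dominating lineage.
#' @export
generate_taxa <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (config$n_taxa < 2) stop_config("n_taxa", "must be >= 2")
  n <- config$n_patients
  k <- config$n_taxa
  genera <- c("Enterococcus", "Escherichia", "Bacteroides", "Blautia",
              "Faecalibacterium", "Roseburia", "Akkermansia", "Lactobacillus",
              "Klebsiella", "Clostridium", "Prevotella", "Ruminococcus")
  gname <- if (k <= length(genera)) genera[seq_len(k)] else
    c(genera, sprintf("Genus%02d", seq_len(k - length(genera))))
  ords <- c("Lactobacillales", "Enterobacterales", "Bacteroidales",
            "Lachnospirales", "Oscillospirales", "Lachnospirales",
            "Verrucomicrobiales", "Lactobacillales", "Enterobacterales",
            "Eubacteriales", "Bacteroidales", "Oscillospirales")
  oname <- if (k <= length(ords)) ords[seq_len(k)] else
    c(ords, sprintf("Order%02d", seq_len(k - length(ords))))
  lineage <- sprintf("k__Bacteria|o__%s|g__%s|s__%s_species",
                     oname, gname, gname)
  prof <- with_seed(derive_seed(config$seed, "taxa"), {
    alpha <- rep(1, k)
    g <- matrix(rgamma(n * k, shape = alpha, rate = 1), k, n)
    p <- sweep(g, 2, colSums(g), "/") * 100
    dom <- runif(n) < config$domination_prob
    if (any(dom)) {
      u <- runif(sum(dom), 0.55, 0.95) * 100
      for (jj in seq_along(which(dom))) {
        j <- which(dom)[jj]
        rest <- p[-1, j]
        p[1, j] <- u[jj]
        p[-1, j] <- rest / sum(rest) * (100 - u[jj])
      }
    }
    p
  })
  ids <- sprintf("P%04d", seq_len(n))
  dimnames(prof) <- list(lineage, ids)
  structure(prof, class = c("taxa_profiles", "matrix"),
            pathobiont = lineage[1])
}

#' Write a synthetic cohort to plain-text tables
#'
#' Writes the cohort table, the metabolite matrix, a MetaPhlAn-style merged
#' taxa table, and a truth record as TSV/JSON under `dir`.
#'
#' @param sc A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(sc, dir) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cohort = file.path(dir, "cohort.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    taxa = file.path(dir, "taxa.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write.table(sc$cohort, paths["cohort"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  met <- data.frame(patient_id = rownames(sc$metabolites$values),
                    sc$metabolites$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(met, paths["metabolites"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  taxa <- data.frame(clade_name = rownames(sc$taxa),
                     unclass(sc$taxa), check.names = FALSE,
                     stringsAsFactors = FALSE)
  write.table(taxa, paths["taxa"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(sc$truth[c("informative_ids", "directions",
                                  "effect_log2fc", "thresholds",
                                  "hazard_ratio")],
                       paths["truth"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d metabolites (%d informative), %d taxa\n",
              nrow(x$cohort), ncol(x$metabolites$values),
              length(x$truth$informative_ids), nrow(x$taxa)))
  cat(sprintf("  30-day mortality: %.1f%%; seed %d\n",
              100 * mean(x$cohort$mortality_label), x$config$seed))
  invisible(x)
}
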