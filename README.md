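# mdscore

Construction and survival evaluation of a **metabolic dysbiosis score
(MDS)** for critically ill patients, from panels of fecal
microbiome-derived metabolite concentrations (short-chain fatty acids,
primary and secondary bile acids, tryptophan metabolites).

## The problem

Single fecal metabolite concentrations rarely separate ICU survivors from
nonsurvivors, yet the joint state of the fecal metabolome carries
prognostic signal. The MDS aggregates that signal into one interpretable
integer per patient:

1. **Per-metabolite cutpoints.** For each metabolite, a ROC analysis
   against 30-day mortality finds the threshold maximizing the Youden
   index *J* = sensitivity + specificity − 1, over midpoint candidate
   thresholds, with the point side oriented toward nonsurvivors
   (stratified bootstrap reported for stability).
2. **Point matrix.** Each patient earns one point per metabolite whose
   concentration falls on the nonsurvivor side of its cutpoint.
3. **Importance-ordered assembly.** A cross-validated logistic ridge
   regression on the standardized point matrix ranks metabolites by
   |β|; metabolites are added to the score one at a time in that order,
   re-optimizing a Youden threshold on the integer scores (hence
   half-integer thresholds such as 7.5) and recording accuracy, AUC,
   sensitivity, specificity, the restricted-mean-survival-time (RMST)
   difference at 30 days, and a log-rank p per iteration.
4. **Parsimony selection.** The simplest iteration within a tolerance of
   the best objective is kept; *dysbiosis* is declared when
   score > threshold.
5. **Evaluation.** Train/validation performance with Wilson 95% CIs; Cox
   proportional-hazards models (continuous and dichotomous MDS, adjusted
   for the Charlson comorbidity index and SOFA score) with
   likelihood-ratio p-values and Schoenfeld proportional-hazards
   diagnostics; Kaplan-Meier curves and RMST differences.

All statistical machinery (Youden cutpoints, Mann-Whitney/chi-square/BH,
PMM imputation, KM, log-rank, RMST with Greenwood variance, Cox partial
likelihood with Efron ties, Grambsch-Therneau PH test, Shannon/Bray-Curtis)
is implemented natively and verified in the test suite against independent
oracles (`survival`, `glmnet`, `vegan`, brute-force enumeration).

A synthetic-cohort generator (`generate_cohort()`) emulates the assumed
data structure — ~30.6% 30-day mortality, log-normal concentration panels
with a planted discriminative subset, integer CCI/SOFA confounders,
right-censoring at day 30, Dirichlet taxa profiles with optional
pathobiont domination — so the entire pipeline is testable without
patient data.

## Worked example

```r
library(mdscore)

sc <- generate_cohort(sim_config(n_patients = 196, n_informative = 5,
                                 effect_log2fc = 1, seed = 7))
bundle <- run_pipeline(sc$cohort, sc$metabolites, seed = 7)
print(bundle)
#> MDS pipeline run
#>   train/validation: 147/49 patients
#> MDS model: 17 metabolites, dysbiosis when score > 9.5
#>   selection: auc within 0.01 of best (accuracy 0.939, AUC 0.976)
#>   metabolites: met02, met30, met21, met22, met05, met03, met29, ...
#> Performance:
#>       cohort   auc accuracy  sens  spec
#> 1      train 0.976    0.939 0.973 0.927
#> 2 validation 0.687    0.735 0.385 0.861

print(bundle$survival$validation$cox_dichotomous)
#> Cox PH fit (efron ties): n = 49, events = 13
#>              HR lower95 upper95      p
#> cci      1.4686  1.1108  1.9417 0.0069
#> sofa     1.1845  0.9742  1.4403 0.0952
#> mds_high 3.3950  1.0899 10.5751 0.0485
#> Global LRT p = 0.003228
```

Reading the output: the 196 synthetic patients split 147/49 stratified by
outcome; on the training cohort the fitted score separates outcomes
almost perfectly (AUC 0.976 — optimistic, since cutpoints, ordering and
threshold were all fit there), while the held-out validation cohort gives
the honest estimate (AUC 0.687). Metabolites `met01`–`met05` carry the
planted signal; the model keeps all five plus noise columns that the
parsimony rule could not exclude at this sample size. In the validation
Cox model, dysbiosis (score > 9.5) triples the 30-day mortality hazard
(HR 3.40, 95% CI 1.09–10.6) after adjustment for comorbidity (CCI) and
disease severity (SOFA).

Apply a fixed, previously published definition (e.g. a 4-metabolite
score flagged at ≥ 2 points):

```r
def <- list(metabolites = c("dca", "lca", "idca", "dat"),
            thresholds = c(0.5, 0.2, 0.1, 0.3),
            directions = rep("low_in_nonsurvivors", 4),
            score_cut = 2, op = ">=")
apply_predefined_score(def, my_metabolite_matrix)
```

Taxonomic side (MetaPhlAn-style merged profiles):

```r
prof <- read_taxa_profiles("taxa.tsv")
shannon <- apply(prof, 2, shannon_index)
dom <- domination_flag(prof, "Enterococcus", "genus", 19.9)
stratify_by_youden(shannon, cohort)   # Youden split + log-rank
```

## Command line

```sh
Rscript inst/cli/mds.R simulate --n 200 --seed 1 --out simdir
Rscript inst/cli/mds.R run --cohort simdir/cohort.tsv \
    --metabolites simdir/metabolites.tsv --split 0.75 --seed 1 --out outdir
Rscript inst/cli/mds.R score --model outdir/model.json \
    --metabolites simdir/metabolites.tsv --out scores.tsv
Rscript inst/cli/mds.R taxa --profiles simdir/taxa.tsv --out taxa_summary.tsv
```
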