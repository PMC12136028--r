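# Taxonomic-side computations on MetaPhlAn-style relative-abundance
# profiles: parsing, rank aggregation, Shannon diversity, Bray-Curtis
# dissimilarity, pathobiont domination flags, and Youden-threshold survival
# stratification of a continuous marker.

RANK_PREFIX <- c(kingdom = "k__", phylum = "p__", class = "c__",
                 order = "o__", family = "f__", genus = "g__",
                 species = "s__")
UNCLASSIFIED_KEY <- "UNCLASSIFIED"

#' Read MetaPhlAn-style merged abundance profiles
#'
#' Expects a TSV whose first column holds pipe-delimited lineage strings
#' (`k__...|o__...|g__...|s__...`) and remaining columns one sample each.
#' Unclassified rows are retained under the reserved key `"UNCLASSIFIED"`.
#'
#' @param path Path to the TSV.
#' @return A `taxa_profiles` matrix (lineages x samples, percent).
#' @export
read_taxa_profiles <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 2) stop("profile table needs a lineage column plus samples",
                         call. = FALSE)
  lineage <- as.character(df[[1]])
  for (i in seq_along(lineage)) {
    ln <- lineage[i]
    if (ln == UNCLASSIFIED_KEY) next
    parts <- strsplit(ln, "|", fixed = TRUE)[[1]]
    ok <- vapply(parts, function(p) any(startsWith(p, RANK_PREFIX)), TRUE)
    if (!length(parts) || !all(ok)) {
      stop(sprintf("malformed lineage at line %d: '%s'", i + 1L, ln),
           call. = FALSE)
    }
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- lineage
  structure(m, class = c("taxa_profiles", "matrix"))
}

#' Write profiles in the merged-table layout
#'
#' @param profiles A `taxa_profiles` matrix.
#' @param path Output TSV path.
#' @export
write_taxa_profiles <- function(profiles, path) {
  df <- data.frame(clade_name = rownames(profiles), unclass(profiles),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Leaf rows: lineages that are not a strict prefix of any other lineage
# (guards against double counting in tables that carry every rank).
leaf_rows <- function(lineages) {
  !vapply(lineages, function(ln) {
    any(startsWith(setdiff(lineages, ln), paste0(ln, "|")))
  }, TRUE)
}

#' Aggregate profiles to a taxonomic rank
#'
#' Sums descendant (leaf-row) abundances per taxon at the requested rank.
#' Leaf rows lacking the rank (including unclassified) are pooled under the
#' reserved `"UNCLASSIFIED"` key.
#'
#' @param profiles A `taxa_profiles` matrix (or a single named profile
#'   vector).
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return Matrix of taxa-at-rank x samples (or a named vector for vector
#'   input).
#' @export
#' @examples
#' m <- matrix(c(10, 15), 2, 1,
#'             dimnames = list(c("k__B|g__G|s__G_a", "k__B|g__G|s__G_b"), "S1"))
#' aggregate_level(m, "genus")
aggregate_level <- function(profiles, rank) {
  rank <- match.arg(rank, names(RANK_PREFIX))
  vec_in <- is.null(dim(profiles))
  m <- if (vec_in) matrix(profiles, ncol = 1,
                          dimnames = list(names(profiles), "sample")) else
    unclass(profiles)
  pre <- RANK_PREFIX[[rank]]
  leaves <- leaf_rows(rownames(m))
  key <- vapply(rownames(m), function(ln) {
    parts <- strsplit(ln, "|", fixed = TRUE)[[1]]
    hit <- parts[startsWith(parts, pre)]
    if (length(hit)) hit[1] else UNCLASSIFIED_KEY
  }, "")
  if (!any(startsWith(unlist(strsplit(rownames(m)[leaves], "|", fixed = TRUE)),
                      pre))) {
    stop(sprintf("rank '%s' absent from profiles", rank), call. = FALSE)
  }
  out <- rowsum(m[leaves, , drop = FALSE], group = key[leaves])
  if (vec_in) setNames(out[, 1], rownames(out)) else out
}

#' Shannon diversity index
#'
#' `H = -sum p_i log(p_i)` over renormalized proportions; zero-abundance
#' taxa contribute nothing. Natural log by default.
#'
#' @param abundances Nonnegative abundance vector (not all zero).
#' @param base Logarithm base (default `exp(1)`).
#' @return The Shannon index (scalar).
#' @export
#' @examples
#' shannon_index(rep(25, 4))  # log(4)
shannon_index <- function(abundances, base = exp(1)) {
  if (any(abundances < 0)) stop("abundances must be nonnegative", call. = FALSE)
  tot <- sum(abundances)
  if (tot == 0) stop("all-zero abundance vector", call. = FALSE)
  p <- abundances / tot
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity
#'
#' `BC = sum |a_i - b_i| / sum (a_i + b_i)` over the union of taxa keys
#' (absent taxa count as zero).
#'
#' @param a,b Named nonnegative abundance vectors.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  keys <- union(names(a) %||% seq_along(a), names(b) %||% seq_along(b))
  av <- setNames(rep(0, length(keys)), keys)
  bv <- av
  av[names(a) %||% seq_along(a)] <- a
  bv[names(b) %||% seq_along(b)] <- b
  if (any(av < 0) || any(bv < 0)) stop("abundances must be nonnegative",
                                       call. = FALSE)
  denom <- sum(av + bv)
  if (denom == 0) stop("both profiles are all-zero", call. = FALSE)
  sum(abs(av - bv)) / denom
}

#' Pathobiont domination flag
#'
#' Flags samples whose aggregated relative abundance of `taxon` at `rank`
#' strictly exceeds `threshold_pct` (an absent taxon has abundance 0).
#'
#' @param profiles A `taxa_profiles` matrix (or single profile vector).
#' @param taxon Taxon name, with or without the rank prefix (e.g.
#'   `"Enterococcus"` or `"g__Enterococcus"`).
#' @param rank Rank at which to aggregate (e.g. `"genus"`, `"order"`).
#' @param threshold_pct Strict domination threshold in percent, in (0, 100).
#' @return Named integer vector of 0/1 flags per sample (scalar for vector
#'   input).
#' @export
#' @examples
#' m <- matrix(c(25, 75), 2, 1,
#'             dimnames = list(c("k__B|g__Enterococcus|s__E_x",
#'                               "k__B|g__Blautia|s__B_y"), "S1"))
#' domination_flag(m, "Enterococcus", "genus", 19.9)
domination_flag <- function(profiles, taxon, rank, threshold_pct) {
  stopifnot(threshold_pct > 0, threshold_pct < 100)
  agg <- aggregate_level(profiles, rank)
  rank <- match.arg(rank, names(RANK_PREFIX))
  key <- if (startsWith(taxon, RANK_PREFIX[[rank]])) taxon else
    paste0(RANK_PREFIX[[rank]], taxon)
  vec_in <- is.null(dim(agg))
  if (vec_in) {
    ab <- if (key %in% names(agg)) agg[[key]] else 0
    return(as.integer(ab > threshold_pct))
  }
  ab <- if (key %in% rownames(agg)) agg[key, ] else
    setNames(rep(0, ncol(agg)), colnames(agg))
  setNames(as.integer(ab > threshold_pct), colnames(agg))
}

#' Youden-threshold survival stratification of a continuous marker
#'
#' Dichotomizes a continuous per-patient value (e.g. the Shannon index) at
#' its Youden-optimal cutpoint against 30-day mortality, then compares the
#' two strata with a log-rank test.
#'
#' @param values Numeric marker, aligned to `cohort` rows.
#' @param cohort Cohort data frame (`survival_days`, `event`,
#'   `mortality_label`).
#' @param n_boot,seed Passed to [youden_cutpoint()].
#' @return List with `cutpoint`, `group` (1 = nonsurvivor-associated side),
#'   and `logrank` (from [log_rank()]).
#' @export
stratify_by_youden <- function(values, cohort, n_boot = 10L, seed = 1L) {
  stopifnot(length(values) == nrow(cohort))
  cp <- youden_cutpoint(values, cohort$mortality_label, n_boot = n_boot,
                        seed = seed)
  if (cp$degenerate) {
    stop("marker values are constant; stratification refused", call. = FALSE)
  }
  grp <- if (cp$direction == "high_in_nonsurvivors") {
    as.integer(values >= cp$threshold)
  } else {
    as.integer(values <= cp$threshold)
  }
  lr <- log_rank(cohort$survival_days, cohort$event, grp)
  list(cutpoint = cp, group = grp, logrank = lr)
}
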