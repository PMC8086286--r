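#' Counts per million
#'
#' Scales each sample (column) of a raw count matrix to counts per million
#' mapped reads: `cpm(i,j) = counts(i,j) / colsum(j) * 1e6`.
#'
#' @param counts an `ExpressionMatrix` with unit `counts`.
#' @return an `ExpressionMatrix` with unit `cpm`; every column sums to 1e6.
#' @export
cpm_matrix <- function(counts) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (em_unit(counts) != "counts") stop("cpm_matrix expects raw counts")
  ls <- colSums(counts)
  if (any(ls == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[ls == 0], collapse = ", "))
  em_like(sweep(unclass(counts), 2, ls, "/") * 1e6, counts, unit = "cpm")
}

#' Remove features with low expression
#'
#' A feature is retained (default mode `per_condition_mean`) iff its mean CPM
#' reaches `cpm_threshold` in at least one condition, so features expressed
#' in only one of the two groups survive. The stricter `total_sum` mode drops
#' features whose summed CPM over all samples is below the threshold.
#'
#' @param counts an `ExpressionMatrix` with unit `counts`.
#' @param groups named factor from [sample_groups()] covering all samples.
#' @param cpm_threshold CPM cut-off (default 1).
#' @param mode filtering rule, `"per_condition_mean"` or `"total_sum"`.
#' @return list with `counts` (filtered `ExpressionMatrix`) and `removed_ids`.
#' @export
filter_low_expression <- function(counts, groups, cpm_threshold = 1,
                                  mode = c("per_condition_mean", "total_sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (!all(colnames(counts) %in% names(groups)))
    stop("every sample needs a condition label")
  grp <- groups[colnames(counts)]
  if (any(table(grp) == 0)) stop("a condition has no samples in the matrix")
  cp <- cpm_matrix(counts)
  if (mode == "per_condition_mean") {
    means <- vapply(levels(grp),
                    function(g) rowMeans(unclass(cp)[, grp == g, drop = FALSE]),
                    numeric(nrow(cp)))
    keep <- apply(means, 1, max) >= cpm_threshold
  } else {
    keep <- rowSums(unclass(cp)) >= cpm_threshold
  }
  list(counts = em_like(unclass(counts)[keep, , drop = FALSE], counts),
       removed_ids = rownames(counts)[!keep])
}

#' TMM normalization factors
#'
#' Between-sample scaling factors from the weighted trimmed mean of per-feature
#' log2 expression ratios (M-values) against a reference sample, the standard
#' TMM recipe: the reference is the sample whose upper-quartile CPM is closest
#' to the mean upper-quartile; features with a zero count in either sample are
#' excluded; the M-values are trimmed symmetrically (default 30%) along with
#' an absolute-expression trim (default 5%); the surviving M-values are
#' averaged with inverse-asymptotic-variance weights. Factors are rescaled so
#' their geometric mean is 1. Computation is delegated to
#' [edgeR::calcNormFactors()], which implements exactly this rule.
#'
#' @param counts an `ExpressionMatrix` with unit `counts`, >= 2 samples.
#' @param logratio_trim two-sided trim fraction on M-values (default 0.30).
#' @param abs_trim two-sided trim fraction on absolute expression (default 0.05).
#' @return named numeric vector of per-sample composition factors (geometric
#'   mean 1) with attributes `reference_sample_id` and `effective_scale`, the
#'   total per-sample scaling that [normalize_counts()] divides by (library
#'   size times factor), rescaled to geometric mean 1. A sample sequenced
#'   twice as deeply has composition factor 1 but effective scale 2x.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (em_unit(counts) != "counts") stop("tmm_factors expects raw counts")
  if (ncol(counts) < 2) stop(">= 2 samples required")
  m <- unclass(counts)
  # edgeR's reference choice: upper-quartile of CPM closest to the mean
  ls <- colSums(m)
  uq <- apply(sweep(m, 2, ls, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- suppressWarnings(
    edgeR::calcNormFactors(m, method = "TMM", refColumn = ref,
                           logratioTrim = logratio_trim, sumTrim = abs_trim))
  if (any(!is.finite(f))) {
    warning("no co-expressed features with reference for sample(s): ",
            paste(colnames(m)[!is.finite(f)], collapse = ", "),
            "; factor set to 1")
    f[!is.finite(f)] <- 1
    f <- f / exp(mean(log(f)))
  }
  names(f) <- colnames(m)
  eff <- ls * f
  eff <- eff / exp(mean(log(eff)))
  attr(f, "reference_sample_id") <- colnames(m)[ref]
  attr(f, "effective_scale") <- eff
  f
}

#' Normalize counts by effective library size
#'
#' CPM on the TMM-corrected library size:
#' `norm(i,j) = counts(i,j) / (colsum(j) * factor(j)) * 1e6`.
#'
#' @param counts an `ExpressionMatrix` with unit `counts`.
#' @param factors named factor vector from [tmm_factors()]; a factor must be
#'   available for every sample.
#' @return an `ExpressionMatrix` with unit `normalized`.
#' @export
normalize_counts <- function(counts, factors) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (!all(colnames(counts) %in% names(factors)))
    stop("missing normalization factor for sample(s): ",
         paste(setdiff(colnames(counts), names(factors)), collapse = ", "))
  f <- factors[colnames(counts)]
  ls <- colSums(unclass(counts))
  em_like(sweep(unclass(counts), 2, ls * f, "/") * 1e6, counts, unit = "normalized")
}
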