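#' Per-feature M and D statistics
#'
#' For each feature, compares the two condition means on the normalized
#' scale: `M = log2((mean_B + k) / (mean_A + k))` (comparison vs reference)
#' and `D = |mean_B - mean_A|`. The pseudocount `k` guards zero means.
#'
#' @param norm an `ExpressionMatrix` with unit `normalized` (or `cpm`).
#' @param groups named factor from [sample_groups()]; the first level is the
#'   reference condition A, the second the comparison B.
#' @param pseudocount `k` added to both means inside the log ratio (default 0.5).
#' @return data.frame with columns `feature_id`, `M`, `D`.
#' @export
md_statistics <- function(norm, groups, pseudocount = 0.5) {
  stopifnot(inherits(norm, "ExpressionMatrix"))
  m <- unclass(norm)
  if (any(!is.finite(m))) stop("non-finite values in expression matrix")
  grp <- groups[colnames(m)]
  if (any(is.na(grp))) stop("every sample needs a condition label")
  a <- levels(grp)[1]; b <- levels(grp)[2]
  mA <- rowMeans(m[, grp == a, drop = FALSE])
  mB <- rowMeans(m[, grp == b, drop = FALSE])
  data.frame(feature_id = rownames(m),
             M = log2((mB + pseudocount) / (mA + pseudocount)),
             D = abs(mB - mA),
             stringsAsFactors = FALSE)
}

#' Empirical within-condition noise distribution
#'
#' Builds the null reference for the differential-expression test: for every
#' unordered pair of samples within the same condition and every feature, the
#' pairwise statistics `|M*| = |log2((x_t + k)/(x_s + k))|` and
#' `D* = |x_t - x_s|` are computed with the same pseudocount as
#' [md_statistics()] and pooled across the two conditions. When the pooled
#' set exceeds `max_points` it is subsampled without replacement using the
#' current RNG state (set a seed upstream for reproducibility).
#'
#' @inheritParams md_statistics
#' @param max_points cap on retained noise points (default 5e5); the full
#'   features-by-pairs cross is quadratic in sample number.
#' @return an object of class `NoiseDistribution`: list with `m` (|M*|),
#'   `d` (D*), `n_pairs` (number of within-condition sample pairs) and
#'   `n_points`.
#' @export
noise_distribution <- function(norm, groups, pseudocount = 0.5, max_points = 5e5) {
  stopifnot(inherits(norm, "ExpressionMatrix"))
  m <- unclass(norm)
  grp <- groups[colnames(m)]
  sizes <- table(grp)
  if (any(sizes < 2))
    stop("condition(s) with < 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  nm <- list(); nd <- list(); idx <- 0L; n_pairs <- 0L
  for (g in levels(grp)) {
    X <- m[, grp == g, drop = FALSE]
    pr <- utils::combn(ncol(X), 2)
    n_pairs <- n_pairs + ncol(pr)
    for (j in seq_len(ncol(pr))) {
      x <- X[, pr[1, j]]; y <- X[, pr[2, j]]
      idx <- idx + 1L
      nm[[idx]] <- abs(log2((y + pseudocount) / (x + pseudocount)))
      nd[[idx]] <- abs(y - x)
    }
  }
  nm <- unlist(nm, use.names = FALSE)
  nd <- unlist(nd, use.names = FALSE)
  if (length(nm) > max_points) {
    take <- sample.int(length(nm), max_points)
    nm <- nm[take]; nd <- nd[take]
  }
  structure(list(m = nm, d = nd, n_pairs = n_pairs, n_points = length(nm)),
            class = "NoiseDistribution")
}

#' @export
print.NoiseDistribution <- function(x, ...) {
  cat(sprintf("NoiseDistribution: %d points from %d within-condition sample pairs\n",
              x$n_points, x$n_pairs))
  invisible(x)
}

#' Differential-expression probability against the noise
#'
#' A feature's probability of being differential is the fraction of noise
#' points it strictly dominates: `prob_i = mean(|M_i| > m* & D_i > d*)`.
#' Ties count against the feature, so a feature at (0, 0) has probability 0.
#'
#' @param stats data.frame from [md_statistics()].
#' @param noise a `NoiseDistribution`.
#' @return numeric vector of probabilities in `[0, 1]`, one per feature.
#' @export
de_probability <- function(stats, noise) {
  stopifnot(inherits(noise, "NoiseDistribution"))
  if (noise$n_points == 0) stop("empty noise distribution")
  o <- order(noise$m)
  nm <- noise$m[o]; nd <- noise$d[o]
  N <- length(nm)
  absM <- abs(stats$M); D <- stats$D
  vapply(seq_along(absM), function(i) {
    k <- findInterval(absM[i], nm, left.open = TRUE)  # noise points with m* < |M_i|
    if (k == 0) return(0)
    sum(nd[seq_len(k)] < D[i]) / N
  }, numeric(1))
}

#' FDR-controlled selection of differential features
#'
#' Features are ranked by probability (descending); the cumulative FDR at
#' rank r is the mean of (1 - prob) over the top r features, and the selected
#' set is the largest prefix whose cumulative FDR stays at or below `q`.
#'
#' @param stats data.frame from [md_statistics()].
#' @param prob probabilities from [de_probability()], aligned with `stats`.
#' @param q FDR threshold in (0, 1), default 0.05.
#' @return data.frame (the `DEResult` table) with columns `feature_id`, `M`,
#'   `D`, `prob`, `fdr`, `selected`, ordered by decreasing probability.
#' @export
select_by_fdr <- function(stats, prob, q = 0.05) {
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)")
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  o <- order(prob, decreasing = TRUE)
  fdr <- cumsum(1 - prob[o]) / seq_along(o)
  n_sel <- if (fdr[1] <= q) max(which(fdr <= q)) else 0L
  res <- data.frame(feature_id = stats$feature_id[o],
                    M = stats$M[o], D = stats$D[o],
                    prob = prob[o], fdr = fdr,
                    selected = seq_along(o) <= n_sel,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' One-call differential expression test
#'
#' Convenience wrapper chaining [md_statistics()], [noise_distribution()],
#' [de_probability()] and [select_by_fdr()].
#'
#' @inheritParams md_statistics
#' @inheritParams noise_distribution
#' @inheritParams select_by_fdr
#' @return the `DEResult` data.frame from [select_by_fdr()].
#' @export
de_test <- function(norm, groups, q = 0.05, pseudocount = 0.5, max_points = 5e5) {
  stats <- md_statistics(norm, groups, pseudocount)
  noise <- noise_distribution(norm, groups, pseudocount, max_points)
  select_by_fdr(stats, de_probability(stats, noise), q = q)
}

#' Row-standardize an expression matrix
#'
#' Centers and scales each feature (row) to mean 0 and population standard
#' deviation 1 across samples, the heatmap-ready "standard deviations from
#' the mean" representation. Constant rows are emitted as zeros with a
#' warning.
#'
#' @param expr an `ExpressionMatrix` or plain matrix.
#' @param features optional character vector of row ids to standardize.
#' @return a plain numeric matrix of z-scores.
#' @export
standardize_rows <- function(expr, features = NULL) {
  m <- unclass(expr)
  if (!is.null(features)) {
    if (length(features) == 0) stop("empty feature subset")
    missing <- setdiff(features, rownames(m))
    if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "))
    m <- m[features, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("empty feature subset")
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))   # population sd
  const <- sdp == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) emitted as zeros")
    sdp[const] <- 1
  }
  (m - mu) / sdp
}
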