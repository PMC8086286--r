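# rank each row across samples, average ranks for ties
rank_rows <- function(m) {
  t(apply(m, 1, rank))
}

# two-sided p-value for a Spearman rho via the t approximation, n - 2 df
spearman_p <- function(rho, n) {
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of the average-rank vectors; the two-sided
#' p-value uses the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with elements `rho` and `p`. A constant input yields
#'   `rho = NA` with a warning.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need >= 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, p = spearman_p(rho, length(x)))
}

#' Correlation filter between lncRNAs and mRNAs
#'
#' Computes the Spearman correlation between every (lncRNA, mRNA) row pair on
#' the shared samples and retains positively correlated pairs passing both
#' thresholds. Sponge mechanics predict a positive lncRNA--mRNA correlation,
#' so negative correlations are never retained.
#'
#' @param lnc_expr,mrna_expr `ExpressionMatrix` objects over the same samples
#'   in the same order; `lnc_expr` rows are typically the differential lncRNAs.
#' @param rho_min minimum Spearman rho (default 0.5).
#' @param p_max maximum two-sided p-value (default 0.05, unadjusted).
#' @param strict if `TRUE`, require `rho > rho_min` instead of `>=`.
#' @param adjust_p apply Benjamini-Hochberg across all tested pairs before
#'   the `p_max` cut (off by default).
#' @return data.frame with columns `lncRNA`, `mRNA`, `r_xy`, `p_xy`.
#' @export
correlate_pairs <- function(lnc_expr, mrna_expr, rho_min = 0.5, p_max = 0.05,
                            strict = FALSE, adjust_p = FALSE) {
  if (!identical(colnames(lnc_expr), colnames(mrna_expr)))
    stop("lncRNA and mRNA matrices must share the same samples in the same order")
  n <- ncol(lnc_expr)
  if (n < 4) stop("need >= 4 shared samples")
  rl <- rank_rows(unclass(lnc_expr))
  rm_ <- rank_rows(unclass(mrna_expr))
  cl <- apply(rl, 1, stats::sd) == 0
  cm <- apply(rm_, 1, stats::sd) == 0
  if (any(cl) || any(cm))
    warning(sum(cl) + sum(cm), " constant feature(s) skipped in correlation filter")
  rl <- rl[!cl, , drop = FALSE]; rm_ <- rm_[!cm, , drop = FALSE]
  if (nrow(rl) == 0 || nrow(rm_) == 0)
    return(data.frame(lncRNA = character(), mRNA = character(),
                      r_xy = numeric(), p_xy = numeric()))
  rho <- stats::cor(t(rl), t(rm_))
  p <- spearman_p(rho, n)
  if (adjust_p) p[] <- stats::p.adjust(p, method = "BH")
  pass <- if (strict) rho > rho_min else rho >= rho_min
  pass <- pass & rho > 0 & p <= p_max
  idx <- which(pass, arr.ind = TRUE)
  out <- data.frame(lncRNA = rownames(rl)[idx[, 1]],
                    mRNA = rownames(rm_)[idx[, 2]],
                    r_xy = rho[idx], p_xy = p[idx],
                    stringsAsFactors = FALSE)
  out[order(out$lncRNA, out$mRNA), , drop = FALSE]
}

#' Construct candidate sponge triplets
#'
#' One triplet per (correlated pair, shared miRNA): the miRNA must be a
#' predicted targeter of both the lncRNA and the mRNA, and must be present
#' (expressed) in the miRNA matrix.
#'
#' @param pairs data.frame from [correlate_pairs()].
#' @param targets a `TargetMap`.
#' @param mirna_ids character vector of expressed miRNA ids (e.g.
#'   `rownames(mirna_expr)`); `NULL` to skip the expression restriction.
#' @return data.frame with columns `lncRNA`, `miRNA`, `mRNA`, `r_xy`, `p_xy`.
#' @export
build_triplets <- function(pairs, targets, mirna_ids = NULL) {
  stopifnot(inherits(targets, "TargetMap"))
  empty <- data.frame(lncRNA = character(), miRNA = character(),
                      mRNA = character(), r_xy = numeric(), p_xy = numeric())
  if (nrow(pairs) == 0) return(empty)
  rev <- targets$reverse
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    shared <- intersect(rev[[pairs$lncRNA[i]]], rev[[pairs$mRNA[i]]])
    if (!is.null(mirna_ids)) shared <- intersect(shared, mirna_ids)
    if (length(shared) == 0) return(NULL)
    data.frame(lncRNA = pairs$lncRNA[i], miRNA = shared, mRNA = pairs$mRNA[i],
               r_xy = pairs$r_xy[i], p_xy = pairs$p_xy[i],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) empty else res
}

#' First-order Spearman partial correlation
#'
#' The correlation of x and y after removing the (rank-linear) effect of z:
#' all three vectors are rank-transformed and the first-order closed form
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` is applied to their
#' pairwise Pearson correlations.
#'
#' @param x,y,z numeric vectors of equal length >= 5.
#' @return the partial correlation; `NA` with a warning when z is perfectly
#'   rank-correlated with x or y (denominator zero).
#' @export
partial_spearman <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 5) stop("need >= 5 observations")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0 || stats::sd(rz) == 0) {
    warning("constant vector: partial correlation undefined")
    return(NA_real_)
  }
  r_xy <- stats::cor(rx, ry); r_xz <- stats::cor(rx, rz); r_yz <- stats::cor(ry, rz)
  partial_from_cors(r_xy, r_xz, r_yz)
}

#' @rdname partial_spearman
#' @param r_xy,r_xz,r_yz pairwise correlations, when already available.
#' @export
partial_from_cors <- function(r_xy, r_xz, r_yz) {
  den2 <- (1 - r_xz^2) * (1 - r_yz^2)
  out <- (r_xy - r_xz * r_yz) / sqrt(den2)
  bad <- den2 <= .Machine$double.eps
  if (any(bad)) {
    warning("partial correlation undefined where z is perfectly correlated with x or y")
    out[bad] <- NA_real_
  }
  out
}

#' Score triplets with the sponge sensitivity Sz
#'
#' Fills each candidate triplet with the Spearman correlation `r_xy`, the
#' partial correlation `r_xy|z` controlling for the miRNA, and the
#' sensitivity score `Sz = r_xy - r_xy|z`. All three correlations are
#' computed on the samples common to the three matrices (a partial
#' correlation needs complete triples), so `r_xy` is recomputed here on that
#' common set; with identical sample sets it equals the pair-stage value.
#' Triplets whose miRNA row is missing, or whose partial correlation is
#' undefined, are dropped with a warning.
#'
#' @param triplets data.frame from [build_triplets()].
#' @param lnc_expr,mrna_expr,mirna_expr `ExpressionMatrix` objects; sample
#'   ids are intersected across the three.
#' @return data.frame with columns `lncRNA`, `miRNA`, `mRNA`, `r_xy`, `p_xy`,
#'   `r_xy_given_z`, `Sz`.
#' @export
sensitivity_scores <- function(triplets, lnc_expr, mrna_expr, mirna_expr) {
  empty <- data.frame(lncRNA = character(), miRNA = character(),
                      mRNA = character(), r_xy = numeric(), p_xy = numeric(),
                      r_xy_given_z = numeric(), Sz = numeric())
  if (nrow(triplets) == 0) return(empty)
  shared <- Reduce(intersect, list(colnames(lnc_expr), colnames(mrna_expr),
                                   colnames(mirna_expr)))
  if (length(shared) < 5) stop("need >= 5 samples shared by all three matrices")

  has_mir <- triplets$miRNA %in% rownames(mirna_expr)
  if (!all(has_mir)) {
    warning(sum(!has_mir), " triplet(s) dropped: miRNA not in expression matrix")
    triplets <- triplets[has_mir, , drop = FALSE]
    if (nrow(triplets) == 0) return(empty)
  }

  ln <- unique(triplets$lncRNA); mr <- unique(triplets$mRNA); mi <- unique(triplets$miRNA)
  rl <- rank_rows(unclass(lnc_expr)[ln, shared, drop = FALSE])
  rm_ <- rank_rows(unclass(mrna_expr)[mr, shared, drop = FALSE])
  rz <- rank_rows(unclass(mirna_expr)[mi, shared, drop = FALSE])

  c_lm <- stats::cor(t(rl), t(rm_))   # lnc x mrna
  c_lz <- stats::cor(t(rl), t(rz))    # lnc x mir
  c_mz <- stats::cor(t(rm_), t(rz))   # mrna x mir

  il <- match(triplets$lncRNA, ln); im <- match(triplets$mRNA, mr)
  iz <- match(triplets$miRNA, mi)
  r_xy <- c_lm[cbind(il, im)]
  r_xz <- c_lz[cbind(il, iz)]
  r_yz <- c_mz[cbind(im, iz)]
  pc <- suppressWarnings(partial_from_cors(r_xy, r_xz, r_yz))
  undef <- !is.finite(pc)
  if (any(undef))
    warning(sum(undef), " triplet(s) dropped: partial correlation undefined")

  out <- data.frame(lncRNA = triplets$lncRNA, miRNA = triplets$miRNA,
                    mRNA = triplets$mRNA,
                    r_xy = r_xy,
                    p_xy = spearman_p(r_xy, length(shared)),
                    r_xy_given_z = pc,
                    Sz = r_xy - pc,
                    stringsAsFactors = FALSE)
  out <- out[!undef, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sz selection threshold
#'
#' Either the fixed cut (default 0.2, approximately the 99th percentile of
#' the Sz distribution in the glioma study) or the empirical q-quantile of
#' the scored triplets' Sz values (linear interpolation).
#'
#' @param triplets scored data.frame from [sensitivity_scores()], or a
#'   numeric vector of Sz values.
#' @param mode `"fixed"` or `"percentile"`.
#' @param sz_min fixed threshold (default 0.2).
#' @param q quantile for percentile mode (default 0.99).
#' @return a single threshold value.
#' @export
sz_threshold <- function(triplets, mode = c("fixed", "percentile"),
                         sz_min = 0.2, q = 0.99) {
  mode <- match.arg(mode)
  sz <- if (is.data.frame(triplets)) triplets$Sz else triplets
  if (length(sz) == 0) stop("empty triplet set")
  if (mode == "fixed") sz_min
  else unname(stats::quantile(sz, probs = q, type = 7))
}

#' Call sponge lncRNAs
#'
#' Groups triplets passing `Sz > threshold` by lncRNA. A miRNA is flagged
#' when any of its triplets passes, with its maximum Sz reported.
#'
#' @param triplets scored data.frame from [sensitivity_scores()].
#' @param threshold Sz cut from [sz_threshold()].
#' @return an object of class `SpongeCalls`: list with `calls` (per-lncRNA
#'   data.frame: `lncRNA`, `n_miRNA`, `n_mRNA`, `n_triplets_passing`,
#'   `max_Sz`), `mirnas` (per-miRNA data.frame), `mrna_sets` / `mirna_sets`
#'   (named lists of ids per called lncRNA), `n_unique_mrna` (union over all
#'   calls) and `threshold`.
#' @export
call_sponges <- function(triplets, threshold) {
  pass <- triplets[is.finite(triplets$Sz) & triplets$Sz > threshold, , drop = FALSE]
  if (nrow(pass) == 0) {
    calls <- data.frame(lncRNA = character(), n_miRNA = integer(),
                        n_mRNA = integer(), n_triplets_passing = integer(),
                        max_Sz = numeric())
    mirnas <- data.frame(miRNA = character(), n_triplets_passing = integer(),
                         max_Sz = numeric())
    return(structure(list(calls = calls, mirnas = mirnas,
                          mrna_sets = list(), mirna_sets = list(),
                          n_unique_mrna = 0L, threshold = threshold),
                     class = "SpongeCalls"))
  }
  sp <- split(pass, pass$lncRNA)
  calls <- data.frame(
    lncRNA = names(sp),
    n_miRNA = vapply(sp, function(d) length(unique(d$miRNA)), integer(1)),
    n_mRNA = vapply(sp, function(d) length(unique(d$mRNA)), integer(1)),
    n_triplets_passing = vapply(sp, nrow, integer(1)),
    max_Sz = vapply(sp, function(d) max(d$Sz), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  mp <- split(pass, pass$miRNA)
  mirnas <- data.frame(
    miRNA = names(mp),
    n_triplets_passing = vapply(mp, nrow, integer(1)),
    max_Sz = vapply(mp, function(d) max(d$Sz), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(calls = calls, mirnas = mirnas,
                 mrna_sets = lapply(sp, function(d) unique(d$mRNA)),
                 mirna_sets = lapply(sp, function(d) unique(d$miRNA)),
                 n_unique_mrna = length(unique(pass$mRNA)),
                 threshold = threshold),
            class = "SpongeCalls")
}

#' @export
print.SpongeCalls <- function(x, ...) {
  cat(sprintf("SpongeCalls: %d lncRNA(s) called at Sz > %.4g; %d unique mRNA(s)\n",
              nrow(x$calls), x$threshold, x$n_unique_mrna))
  if (nrow(x$calls)) print(x$calls)
  invisible(x)
}
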