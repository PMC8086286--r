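#' Pipeline run configuration
#'
#' All stage parameters with defaults matching the glioma study's stated
#' values: CPM threshold 1, DE FDR 0.05, correlation filter rho >= 0.5 at
#' p <= 0.05 (unadjusted), Sz cut 0.2 (fixed mode) or the 0.99 quantile
#' (percentile mode).
#'
#' @param cpm_threshold low-expression CPM cut-off.
#' @param filter_mode see [filter_low_expression()].
#' @param fdr_q differential-expression FDR threshold.
#' @param pseudocount pseudocount for M statistics.
#' @param max_noise_points cap on the empirical noise distribution.
#' @param rho_min,p_max,strict_rho,adjust_p correlation-filter parameters,
#'   see [correlate_pairs()].
#' @param mrna_mode which mRNAs enter the correlation filter:
#'   `"all_expressed"` (every mRNA surviving preprocessing) or `"de_only"`.
#' @param lnc_selection which lncRNAs enter the correlation filter: `"de"`
#'   (those selected by the DE stage) or `"all"` (every expressed lncRNA).
#' @param sz_mode,sz_min,sz_percentile Sz threshold rule, see [sz_threshold()].
#' @param seed integer seed for the run (noise subsampling).
#' @return a list of class `RunConfig`.
#' @export
run_config <- function(cpm_threshold = 1,
                       filter_mode = "per_condition_mean",
                       fdr_q = 0.05, pseudocount = 0.5, max_noise_points = 5e5,
                       rho_min = 0.5, p_max = 0.05,
                       strict_rho = FALSE, adjust_p = FALSE,
                       mrna_mode = c("all_expressed", "de_only"),
                       lnc_selection = c("de", "all"),
                       sz_mode = c("fixed", "percentile"),
                       sz_min = 0.2, sz_percentile = 0.99,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$mrna_mode <- match.arg(mrna_mode)
  cfg$lnc_selection <- match.arg(lnc_selection)
  cfg$sz_mode <- match.arg(sz_mode)
  structure(cfg, class = "RunConfig")
}

#' Run the full sponge-nomination pipeline
#'
#' Executes, in order: biotype classification, CPM low-expression filtering,
#' TMM normalization, nonparametric differential expression, lncRNA--mRNA
#' correlation filtering, shared-miRNA triplet construction, Sz scoring,
#' thresholding and sponge calling. The returned manifest records every
#' parameter and the feature counts surviving each stage.
#'
#' @param counts gene `ExpressionMatrix` (unit counts; mRNA + lncRNA rows).
#' @param mirna miRNA `ExpressionMatrix` (any monotone scale; correlations
#'   are rank-based).
#' @param annotation annotation source accepted by [classify_biotypes()].
#' @param groups named condition factor from [sample_groups()].
#' @param targets a `TargetMap`.
#' @param config a `RunConfig`.
#' @return list of class `PipelineResult` with elements `de` (DEResult table
#'   with a `class` column), `norm`, `pairs`, `triplets`, `sz_cut`, `calls`,
#'   `annotation` and `manifest`.
#' @export
run_pipeline <- function(counts, mirna, annotation, groups, targets,
                         config = run_config()) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  stage <- "biotype classification"
  res <- tryCatch({
    ann <- classify_biotypes(annotation)
    keep <- intersect(rownames(counts), ann$gene_id)
    cts <- em_like(unclass(counts)[keep, , drop = FALSE], counts)
    n_input <- nrow(counts)

    stage <- "low-expression filter"
    flt <- filter_low_expression(cts, groups, config$cpm_threshold,
                                 mode = config$filter_mode)

    stage <- "TMM normalization"
    f <- tmm_factors(flt$counts)
    norm <- normalize_counts(flt$counts, f)

    stage <- "differential expression"
    de <- de_test(norm, groups, q = config$fdr_q,
                  pseudocount = config$pseudocount,
                  max_points = config$max_noise_points)
    de$class <- ifelse(
      is_lncRNA_class(ann$biotype_class[match(de$feature_id, ann$gene_id)]),
      "lncRNA", "mRNA")

    stage <- "correlation filter"
    lnc_all <- intersect(rownames(norm), ann$gene_id[is_lncRNA_class(ann$biotype_class)])
    mrna_all <- intersect(rownames(norm), ann$gene_id[ann$biotype_class == "mRNA"])
    de_sel <- de$feature_id[de$selected]
    lnc_use <- if (config$lnc_selection == "de") intersect(lnc_all, de_sel) else lnc_all
    mrna_use <- if (config$mrna_mode == "de_only") intersect(mrna_all, de_sel) else mrna_all
    if (length(lnc_use) == 0 || length(mrna_use) == 0) {
      pairs <- data.frame(lncRNA = character(), mRNA = character(),
                          r_xy = numeric(), p_xy = numeric())
    } else {
      pairs <- correlate_pairs(
        em_like(unclass(norm)[lnc_use, , drop = FALSE], norm),
        em_like(unclass(norm)[mrna_use, , drop = FALSE], norm),
        rho_min = config$rho_min, p_max = config$p_max,
        strict = config$strict_rho, adjust_p = config$adjust_p)
    }

    stage <- "triplet construction"
    trip <- build_triplets(pairs, targets, rownames(mirna))

    stage <- "sensitivity scoring"
    scored <- if (nrow(trip) == 0) {
      data.frame(lncRNA = character(), miRNA = character(), mRNA = character(),
                 r_xy = numeric(), p_xy = numeric(),
                 r_xy_given_z = numeric(), Sz = numeric())
    } else {
      sensitivity_scores(trip,
                         em_like(unclass(norm)[lnc_use, , drop = FALSE], norm),
                         em_like(unclass(norm)[mrna_use, , drop = FALSE], norm),
                         mirna)
    }

    stage <- "sponge calling"
    sz_cut <- if (nrow(scored) == 0) config$sz_min
              else sz_threshold(scored, mode = config$sz_mode,
                                sz_min = config$sz_min, q = config$sz_percentile)
    calls <- call_sponges(scored, sz_cut)

    manifest <- list(
      parameters = unclass(config),
      stages = list(
        n_features_input = n_input,
        n_annotated = nrow(cts),
        n_removed_low_expression = length(flt$removed_ids),
        n_after_filter = nrow(flt$counts),
        n_de_selected = sum(de$selected),
        n_de_mrna = sum(de$selected & de$class == "mRNA"),
        n_de_lnc = sum(de$selected & de$class == "lncRNA"),
        n_lnc_for_pairs = length(lnc_use),
        n_mrna_for_pairs = length(mrna_use),
        n_pairs = nrow(pairs),
        n_triplets = nrow(trip),
        n_triplets_scored = nrow(scored),
        sz_threshold = sz_cut,
        n_sponge_calls = nrow(calls$calls),
        n_unique_mrna = calls$n_unique_mrna),
      reference_sample = attr(f, "reference_sample_id"),
      seed = config$seed)

    list(de = de, norm = norm, factors = f, pairs = pairs, triplets = scored,
         sz_cut = sz_cut, calls = calls, annotation = ann, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  class(res) <- "PipelineResult"
  res
}

#' @export
print.PipelineResult <- function(x, ...) {
  s <- x$manifest$stages
  cat("Sponge-nomination pipeline run\n")
  cat(sprintf("  features: %d input, %d annotated, %d after CPM filter\n",
              s$n_features_input, s$n_annotated, s$n_after_filter))
  cat(sprintf("  DE selected: %d (mRNA %d, lncRNA %d)\n",
              s$n_de_selected, s$n_de_mrna, s$n_de_lnc))
  cat(sprintf("  pairs: %d; triplets scored: %d; Sz cut: %.4g\n",
              s$n_pairs, s$n_triplets_scored, s$sz_threshold))
  cat(sprintf("  sponge calls: %d lncRNA(s), %d unique mRNA(s)\n",
              s$n_sponge_calls, s$n_unique_mrna))
  invisible(x)
}

#' Write a run manifest as JSON
#'
#' @param result a `PipelineResult` (or its `manifest` element).
#' @param path output path.
#' @export
write_manifest <- function(result, path) {
  manifest <- if (inherits(result, "PipelineResult")) result$manifest else result
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Summary report of a pipeline run
#'
#' Produces the differential-expression summary by feature class, the
#' row-standardized expression matrix of differential lncRNAs with at least
#' the requested fold change (heatmap-ready, in standard deviations from the
#' row mean), and the sponge-call summary.
#'
#' @param result a `PipelineResult`.
#' @param min_fold_change include DE lncRNAs with `|M| >= log2(min_fold_change)`
#'   in the standardized export (default 2).
#' @return list with `de_summary` (data.frame class/n_selected), `heatmap`
#'   (z-score matrix, possibly 0-row), `sponge_calls` and `mirna_summary`.
#' @export
pipeline_report <- function(result, min_fold_change = 2) {
  stopifnot(inherits(result, "PipelineResult"))
  de <- result$de
  de_summary <- data.frame(class = c("mRNA", "lncRNA"),
                           n_selected = c(sum(de$selected & de$class == "mRNA"),
                                          sum(de$selected & de$class == "lncRNA")))
  ids <- de$feature_id[de$selected & de$class == "lncRNA" &
                         abs(de$M) >= log2(min_fold_change)]
  heatmap <- if (length(ids) == 0) {
    warning("no differential lncRNAs at the requested fold change; empty export")
    matrix(numeric(0), 0, ncol(result$norm),
           dimnames = list(NULL, colnames(result$norm)))
  } else {
    standardize_rows(result$norm, ids)
  }
  list(de_summary = de_summary, heatmap = heatmap,
       sponge_calls = result$calls$calls, mirna_summary = result$calls$mirnas)
}

#' Within-condition percentages for a cohort summary table
#'
#' Given a long-format table of case counts (columns `variable`, `category`,
#' then one count column per condition), computes, for every category, the
#' percentage of that condition's cases --- the usual "n (%)" presentation of
#' a clinical Table 1. By default the denominator is the condition's total
#' within each variable block; pass `totals` (named by count column) to use
#' the cohort's overall case counts instead, which is how such tables are
#' usually reported when some cases are unclassified for a variable.
#'
#' @param counts data.frame with columns `variable`, `category` and one or
#'   more numeric count columns.
#' @param totals optional named numeric vector of per-condition denominators.
#' @return the input with an added `pct_<condition>` column per count column.
#' @export
cohort_percentages <- function(counts, totals = NULL) {
  if (!all(c("variable", "category") %in% names(counts)))
    stop("expected columns: variable, category, <count columns>")
  num <- names(counts)[vapply(counts, is.numeric, logical(1))]
  if (length(num) == 0) stop("no count columns found")
  if (!is.null(totals) && !all(num %in% names(totals)))
    stop("'totals' must name every count column")
  out <- counts
  for (cc in num) {
    tot <- if (is.null(totals)) stats::ave(counts[[cc]], counts$variable, FUN = sum)
           else totals[[cc]]
    out[[paste0("pct_", cc)]] <- 100 * counts[[cc]] / tot
  }
  out
}
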