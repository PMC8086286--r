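#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic two-condition
#' dataset. Counts are negative-binomial with log-normally distributed base
#' means and sample-specific library-size factors; dependence is planted on a
#' latent Gaussian scale and mapped onto the count margins by quantile
#' transform (Gaussian copula), so planted Spearman correlations survive the
#' count mapping. Sponge triplets are fully mediated: the lncRNA and mRNA
#' latents both load negatively on the shared miRNA latent z
#' (`lnc = -b_lnc z + e`, `mrna = -b_mrna z + e'`, unit variance), making
#' them mutually positively correlated with the correlation vanishing given
#' z. Decoy pairs are correlated through a confounder that is not any
#' miRNA's expression, so their Sz is centered at zero. Differential features
#' get their mean raised by `2^lfc` in one randomly chosen condition.
#'
#' @param n_per_condition integer vector of length 2: samples in the
#'   reference and comparison condition.
#' @param n_mrna,n_lnc,n_mirna feature census.
#' @param n_de_mrna,n_de_lnc number of planted differential features per
#'   class (disjoint from sponge/decoy features).
#' @param lfc absolute log2 fold change of planted differential features.
#' @param n_sponge number of planted fully mediated triplets (one lncRNA,
#'   miRNA and mRNA each).
#' @param b_lnc,b_mrna latent loadings of the sponge lncRNA and mRNA on the
#'   miRNA latent, in `[0, 1)` (0 plants a null triplet); the implied latent
#'   Pearson correlation of the pair is `b_lnc * b_mrna`.
#' @param n_decoy number of confounder-driven decoy pairs (each with its own
#'   independent miRNA sharing the pair in the target map).
#' @param b_decoy latent loading of decoy pairs on their confounder.
#' @param meanlog,sdlog log-normal parameters of the NB base means.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param libsize_sdlog log-normal sd of per-sample library-size factors.
#' @param mirna_baseline_mean,mirna_baseline_sd,mirna_slope,mirna_noise_sd
#'   parameters of the miRNA matrix, emitted directly on a log2-RPM-like
#'   scale as `baseline + slope * z + noise`.
#' @param n_extra_edges random additional miRNA-to-gene edges in the target map.
#' @param seed mandatory integer seed.
#' @return a list of class `SimulationConfig`.
#' @export
sim_config <- function(n_per_condition = c(100, 100),
                       n_mrna = 800, n_lnc = 80, n_mirna = 60,
                       n_de_mrna = 50, n_de_lnc = 10, lfc = 2,
                       n_sponge = 10, b_lnc = 0.8, b_mrna = 0.8,
                       n_decoy = 20, b_decoy = 0.8,
                       meanlog = log(100), sdlog = 0.8, dispersion = 0.1,
                       libsize_sdlog = 0.15,
                       mirna_baseline_mean = 6, mirna_baseline_sd = 1,
                       mirna_slope = 1.5, mirna_noise_sd = 0.1,
                       n_extra_edges = 100, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  cfg <- as.list(environment())
  if (any(n_per_condition < 2)) stop("need >= 2 samples per condition")
  if (any(c(b_lnc, b_mrna, b_decoy) < 0) || any(c(b_lnc, b_mrna, b_decoy) >= 1))
    stop("latent loadings must lie in [0, 1)")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (n_sponge + n_decoy + n_de_lnc > n_lnc)
    stop("more planted lncRNAs than lncRNA features")
  if (n_sponge + n_decoy + n_de_mrna > n_mrna)
    stop("more planted mRNAs than mRNA features")
  if (n_sponge + n_decoy > n_mirna)
    stop("more planted miRNAs than miRNA features")
  structure(cfg, class = "SimulationConfig")
}

# Spearman correlation implied by a latent bivariate-normal Pearson rho
latent_spearman <- function(rho) (6 / pi) * asin(rho / 2)

#' Simulate a two-condition dataset with planted structure
#'
#' @param config a `SimulationConfig` from [sim_config()].
#' @return list with elements `counts` (gene `ExpressionMatrix`, unit counts),
#'   `mirna` (`ExpressionMatrix`, unit log2rpm), `annotation` (data.frame
#'   `gene_id`, `symbol`, `biotype`), `groups` (named factor), `targets`
#'   (`TargetMap`) and `truth` (list: `de_features`, `sponge_triplets`,
#'   `decoy_pairs`, id universes, and the seed).
#' @export
simulate_sponge_dataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cf <- config
  set.seed(cf$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  n <- sum(cf$n_per_condition)
  samples <- sprintf("s%03d", seq_len(n))
  cond <- factor(rep(c("groupA", "groupB"), cf$n_per_condition),
                 levels = c("groupA", "groupB"))
  names(cond) <- samples

  mrna_ids <- sprintf("mrna_%04d", seq_len(cf$n_mrna))
  lnc_ids <- sprintf("lnc_%04d", seq_len(cf$n_lnc))
  mir_ids <- sprintf("mir_%03d", seq_len(cf$n_mirna))
  gene_ids <- c(mrna_ids, lnc_ids)

  # feature roles (disjoint)
  sp_lnc <- lnc_ids[seq_len(cf$n_sponge)]
  dc_lnc <- lnc_ids[cf$n_sponge + seq_len(cf$n_decoy)]
  de_lnc <- lnc_ids[cf$n_sponge + cf$n_decoy + seq_len(cf$n_de_lnc)]
  sp_mrna <- mrna_ids[seq_len(cf$n_sponge)]
  dc_mrna <- mrna_ids[cf$n_sponge + seq_len(cf$n_decoy)]
  de_mrna <- mrna_ids[cf$n_sponge + cf$n_decoy + seq_len(cf$n_de_mrna)]
  sp_mir <- mir_ids[seq_len(cf$n_sponge)]
  dc_mir <- mir_ids[cf$n_sponge + seq_len(cf$n_decoy)]

  # latent Gaussian layer (unit variance rows)
  U <- matrix(stats::rnorm(length(gene_ids) * n), length(gene_ids), n,
              dimnames = list(gene_ids, samples))
  Zmir <- matrix(stats::rnorm(cf$n_mirna * n), cf$n_mirna, n,
                 dimnames = list(mir_ids, samples))
  mix <- function(b, z) -b * z + sqrt(1 - b^2) * stats::rnorm(n)
  for (i in seq_len(cf$n_sponge)) {
    z <- Zmir[sp_mir[i], ]
    U[sp_lnc[i], ] <- mix(cf$b_lnc, z)
    U[sp_mrna[i], ] <- mix(cf$b_mrna, z)
  }
  for (j in seq_len(cf$n_decoy)) {
    conf <- stats::rnorm(n)                      # confounder, not any miRNA
    U[dc_lnc[j], ] <- mix(cf$b_decoy, conf)
    U[dc_mrna[j], ] <- mix(cf$b_decoy, conf)
  }

  # per-condition mean multipliers for differential features
  de_ids <- c(de_mrna, de_lnc)
  raised_in_B <- sample(c(TRUE, FALSE), length(de_ids), replace = TRUE)
  mult <- matrix(1, length(gene_ids), 2, dimnames = list(gene_ids, NULL))
  mult[de_ids[raised_in_B], 2] <- 2^cf$lfc
  mult[de_ids[!raised_in_B], 1] <- 2^cf$lfc

  mu <- stats::rlnorm(length(gene_ids), cf$meanlog, cf$sdlog)
  lib <- stats::rlnorm(n, 0, cf$libsize_sdlog)
  size <- 1 / cf$dispersion
  counts <- matrix(0, length(gene_ids), n, dimnames = list(gene_ids, samples))
  for (s in seq_len(n)) {
    mus <- mu * lib[s] * mult[, 1 + (cond[s] == "groupB")]
    counts[, s] <- stats::qnbinom(stats::pnorm(U[, s]), mu = mus, size = size)
  }

  base <- stats::rnorm(cf$n_mirna, cf$mirna_baseline_mean, cf$mirna_baseline_sd)
  mirna <- base + cf$mirna_slope * Zmir +
    matrix(stats::rnorm(cf$n_mirna * n, 0, cf$mirna_noise_sd), cf$n_mirna, n)
  dimnames(mirna) <- list(mir_ids, samples)

  # annotation: mRNAs protein_coding, lncRNAs cycled over the four classes
  lnc_bts <- rep(c("lincRNA", "antisense", "sense_intronic", "sense_overlapping"),
                 length.out = cf$n_lnc)
  annotation <- data.frame(
    gene_id = gene_ids,
    symbol = toupper(gene_ids),
    biotype = c(rep("protein_coding", cf$n_mrna), lnc_bts),
    stringsAsFactors = FALSE)

  edges <- data.frame(miRNA_id = c(rep(sp_mir, each = 2), rep(dc_mir, each = 2)),
                      gene_id = c(rbind(sp_lnc, sp_mrna), rbind(dc_lnc, dc_mrna)),
                      stringsAsFactors = FALSE)
  if (cf$n_extra_edges > 0)
    edges <- rbind(edges,
                   data.frame(miRNA_id = sample(mir_ids, cf$n_extra_edges, TRUE),
                              gene_id = sample(gene_ids, cf$n_extra_edges, TRUE),
                              stringsAsFactors = FALSE))

  implied <- latent_spearman(cf$b_lnc * cf$b_mrna)
  truth <- list(
    de_features = data.frame(
      feature_id = de_ids,
      class = c(rep("mRNA", length(de_mrna)), rep("lncRNA", length(de_lnc))),
      log2fc = ifelse(raised_in_B, cf$lfc, -cf$lfc),
      stringsAsFactors = FALSE),
    sponge_triplets = data.frame(
      lncRNA = sp_lnc, miRNA = sp_mir, mRNA = sp_mrna,
      b_lnc = rep(cf$b_lnc, cf$n_sponge), b_mrna = rep(cf$b_mrna, cf$n_sponge),
      implied_r_xy = rep(implied, cf$n_sponge),
      stringsAsFactors = FALSE),
    decoy_pairs = data.frame(
      lncRNA = dc_lnc, miRNA = dc_mir, mRNA = dc_mrna,
      b = rep(cf$b_decoy, cf$n_decoy), stringsAsFactors = FALSE),
    lnc_ids = lnc_ids, mrna_ids = mrna_ids, mir_ids = mir_ids,
    seed = cf$seed)

  list(counts = expression_matrix(counts, "counts"),
       mirna = expression_matrix(mirna, "log2rpm"),
       annotation = annotation,
       groups = cond,
       targets = target_map(edges),
       truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the five TSV tables consumed by the pipeline (gene counts, miRNA
#' expression, annotation, sample metadata, target map) plus the ground truth
#' as JSON.
#'
#' @param sim output of [simulate_sponge_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(counts = file.path(dir, "counts.tsv"),
         mirna = file.path(dir, "mirna_log2rpm.tsv"),
         annotation = file.path(dir, "annotation.tsv"),
         samples = file.path(dir, "samples.tsv"),
         targets = file.path(dir, "targets.tsv"),
         truth = file.path(dir, "truth.json"))
  write_expression_matrix(sim$counts, p["counts"], id_column = "gene_id")
  write_expression_matrix(sim$mirna, p["mirna"], id_column = "miRNA_id")
  utils::write.table(sim$annotation, p["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(sim$groups),
                                condition = as.character(sim$groups)),
                     p["samples"], sep = "\t", quote = FALSE, row.names = FALSE)
  fw <- sim$targets$forward
  utils::write.table(data.frame(miRNA_id = rep(names(fw), lengths(fw)),
                                gene_id = unlist(fw, use.names = FALSE)),
                     p["targets"], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, p["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(p)
}

#' Score sponge-call recovery against the planted truth
#'
#' @param calls a `SpongeCalls` object.
#' @param truth the `truth` element of [simulate_sponge_dataset()] output.
#' @return list with `sensitivity` (fraction of planted sponge lncRNAs
#'   called) and `false_call_rate` (fraction of decoy lncRNAs called).
#' @export
score_recovery <- function(calls, truth) {
  stopifnot(inherits(calls, "SpongeCalls"))
  called <- calls$calls$lncRNA
  unknown <- setdiff(called, truth$lnc_ids)
  if (length(unknown))
    stop("called lncRNA id(s) not present in the simulated dataset: ",
         paste(unknown, collapse = ", "))
  planted <- truth$sponge_triplets$lncRNA
  decoys <- truth$decoy_pairs$lncRNA
  list(sensitivity = if (length(planted)) mean(planted %in% called) else NA_real_,
       false_call_rate = if (length(decoys)) mean(decoys %in% called) else 0)
}
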