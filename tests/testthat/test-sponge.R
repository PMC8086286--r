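mk_em <- function(m, ids, unit = "normalized") {
  if (min(m) < 0) m <- m - min(m)  # global shift; rank structure unaffected
  dimnames(m) <- list(ids, sprintf("s%03d", seq_len(ncol(m))))
  expression_matrix(m, unit)
}

test_that("spearman correlation matches rank-then-Pearson with ties", {
  expect_equal(spearman_cor(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_cor(1:4, c(40, 30, 20, 10))$rho, -1)

  set.seed(20)
  for (i in 1:5) {
    x <- sample(1:8, 15, replace = TRUE)   # plenty of ties
    y <- sample(1:8, 15, replace = TRUE)
    r <- spearman_cor(x, y)
    expect_equal(r$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(r$rho, suppressWarnings(cor.test(x, y, method = "spearman"))$estimate[[1]],
                 tolerance = 1e-12)
  }
  expect_warning(r0 <- spearman_cor(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(r0$rho))
})

test_that("pair filter keeps positive correlations passing both thresholds", {
  set.seed(21)
  n <- 30
  base <- rnorm(n)
  lnc <- mk_em(rbind(base, rnorm(n), -base + rnorm(n, sd = 0.1)),
               c("L1", "L2", "L3"))
  mrna <- mk_em(rbind(base, base + rnorm(n, sd = 0.3), rnorm(n), -base),
                c("M1", "M2", "M3", "M4"))
  pairs <- correlate_pairs(lnc, mrna)
  # identical profile -> rho 1 retained
  expect_true(any(pairs$lncRNA == "L1" & pairs$mRNA == "M1" & pairs$r_xy == 1))
  # strongly anti-correlated pairs are never retained
  expect_false(any(pairs$lncRNA == "L3" & pairs$mRNA %in% c("M1", "M2")))
  expect_false(any(pairs$lncRNA == "L1" & pairs$mRNA == "M4"))
  expect_true(all(pairs$r_xy >= 0.5 & pairs$p_xy <= 0.05))

  # exhaustive brute force over all 12 pairs
  brute <- do.call(rbind, lapply(c("L1", "L2", "L3"), function(l)
    do.call(rbind, lapply(c("M1", "M2", "M3", "M4"), function(m) {
      r <- spearman_cor(unclass(lnc)[l, ], unclass(mrna)[m, ])
      data.frame(lncRNA = l, mRNA = m, r_xy = r$rho, p_xy = r$p)
    }))))
  brute <- brute[brute$r_xy >= 0.5 & brute$r_xy > 0 & brute$p_xy <= 0.05, ]
  expect_equal(pairs$r_xy, brute$r_xy, tolerance = 1e-12)
  expect_identical(paste(pairs$lncRNA, pairs$mRNA), paste(brute$lncRNA, brute$mRNA))

  expect_error(correlate_pairs(lnc, mk_em(matrix(1, 2, 5), c("a", "b"))),
               "same samples")
})

test_that("triplet construction requires a shared expressed miRNA", {
  tm <- target_map(data.frame(
    miRNA_id = c("miR1", "miR1", "miR2", "miR2", "miR3", "miR3", "miR4", "miR4"),
    gene_id = c("L1", "M1", "L1", "M1", "L1", "M1", "L2", "M9")))
  pairs <- data.frame(lncRNA = c("L1", "L2"), mRNA = c("M1", "M2"),
                      r_xy = c(0.8, 0.7), p_xy = c(1e-4, 1e-3))
  # pair 2 shares no miRNA -> only pair 1 contributes, once per shared miRNA
  tr <- build_triplets(pairs, tm, mirna_ids = c("miR1", "miR2", "miR3"))
  expect_identical(nrow(tr), 3L)
  expect_setequal(tr$miRNA, c("miR1", "miR2", "miR3"))
  expect_true(all(tr$lncRNA == "L1" & tr$mRNA == "M1"))

  # expression restriction: miR3 not expressed
  tr2 <- build_triplets(pairs, tm, mirna_ids = c("miR1", "miR2"))
  expect_identical(nrow(tr2), 2L)

  # two pairs sharing the same three miRNAs -> product count 6
  tm2 <- target_map(data.frame(
    miRNA_id = rep(c("miR1", "miR2", "miR3"), each = 4),
    gene_id = rep(c("L1", "M1", "L2", "M2"), 3)))
  pairs2 <- data.frame(lncRNA = c("L1", "L2"), mRNA = c("M1", "M2"),
                       r_xy = 0.6, p_xy = 0.01)
  expect_identical(nrow(build_triplets(pairs2, tm2, paste0("miR", 1:3))), 6L)

  expect_identical(nrow(build_triplets(pairs[0, ], tm, "miR1")), 0L)
})

test_that("partial spearman matches the closed form and the residual oracle", {
  expect_equal(partial_from_cors(0.6, 0.5, 0.5), (0.6 - 0.25) / 0.75,
               tolerance = 1e-12)

  set.seed(22)
  # x = y: partial correlation is 1 for any non-degenerate z
  x <- rnorm(30)
  expect_equal(partial_spearman(x, x, rnorm(30)), 1, tolerance = 1e-12)

  # independent z leaves the correlation essentially untouched (large n)
  n <- 2000
  z <- rnorm(n); w <- rnorm(n)
  a <- w + rnorm(n); b <- w + rnorm(n)
  r_xy <- cor(rank(a), rank(b))
  expect_equal(partial_spearman(a, b, z), r_xy, tolerance = 0.05)

  # residual-rank brute force agreement on random non-degenerate triples
  for (i in 1:25) {
    x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
    expect_equal(partial_spearman(x, y, z), partial_oracle(x, y, z),
                 tolerance = 1e-10)
  }

  expect_warning(pd <- partial_spearman(x, y, x), "undefined")
  expect_true(is.na(pd))
})

test_that("sensitivity scores fill r_xy|z and Sz, dropping degenerate triplets", {
  expect_equal(0.6 - partial_from_cors(0.6, 0.5, 0.5), 0.6 - 0.4666667,
               tolerance = 1e-6)

  set.seed(23)
  n <- 200
  z <- rnorm(n)
  x <- -0.8 * z + 0.6 * rnorm(n)
  y <- -0.8 * z + 0.6 * rnorm(n)
  lnc <- mk_em(rbind(x), "L1")
  mrna <- mk_em(rbind(y), "M1")
  mir <- mk_em(rbind(z, x), c("miR1", "miR_copy_of_x"), unit = "log2rpm")
  tr <- data.frame(lncRNA = "L1", miRNA = "miR1", mRNA = "M1",
                   r_xy = NA, p_xy = NA)
  sc <- sensitivity_scores(tr, lnc, mrna, mir)
  # full mediation: conditioning on the shared driver removes the correlation
  expect_equal(sc$Sz, sc$r_xy, tolerance = 0.1)
  expect_lt(abs(sc$r_xy_given_z), 0.1)

  # z a deterministic monotone copy of x -> undefined partial -> dropped
  tr2 <- data.frame(lncRNA = "L1", miRNA = "miR_copy_of_x", mRNA = "M1",
                    r_xy = NA, p_xy = NA)
  expect_warning(sc2 <- sensitivity_scores(tr2, lnc, mrna, mir), "undefined")
  expect_identical(nrow(sc2), 0L)

  # missing miRNA row -> dropped with warning
  tr3 <- data.frame(lncRNA = "L1", miRNA = "miR_absent", mRNA = "M1",
                    r_xy = NA, p_xy = NA)
  expect_warning(sc3 <- sensitivity_scores(tr3, lnc, mrna, mir), "not in expression")
  expect_identical(nrow(sc3), 0L)
})

test_that("Sz for an independent miRNA is centered at zero", {
  set.seed(24)
  n <- 200
  sz <- replicate(500, {
    w <- rnorm(n)
    x <- w + rnorm(n); y <- w + rnorm(n); z <- rnorm(n)
    cor(rank(x), rank(y)) - partial_spearman(x, y, z)
  })
  expect_lt(abs(mean(sz)), 0.02)
})

test_that("Sz thresholding supports fixed and percentile modes", {
  sz <- c(rep(0, 99), 0.5)
  expect_identical(sz_threshold(sz, "fixed"), 0.2)
  expect_identical(sz_threshold(data.frame(Sz = sz), "fixed", sz_min = 0.3), 0.3)
  thr <- sz_threshold(sz, "percentile", q = 0.99)
  expect_equal(thr, quantile(sz, 0.99, type = 7)[[1]], tolerance = 1e-12)
  expect_true(thr > 0 && thr < 0.5)
  expect_identical(sz_threshold(rep(0.25, 10), "percentile"), 0.25)
  expect_error(sz_threshold(numeric(0)), "empty")
})

test_that("sponge calls group passing triplets and count unique mRNAs", {
  tr <- data.frame(
    lncRNA = c("L1", "L1", "L1", "L2", "L2", "L3"),
    miRNA = c("miR1", "miR1", "miR2", "miR3", "miR3", "miR4"),
    mRNA = c("A", "B", "C", "D", "E", "F"),
    r_xy = 0.6, p_xy = 1e-4, r_xy_given_z = 0.1,
    Sz = c(0.5, 0.4, 0.3, 0.45, 0.35, 0.1))
  calls <- call_sponges(tr, 0.2)
  expect_identical(calls$calls$lncRNA, c("L1", "L2"))
  expect_identical(calls$calls$n_triplets_passing, c(3L, 2L))
  expect_identical(calls$n_unique_mrna, 5L)
  expect_identical(calls$mirnas$miRNA, c("miR1", "miR2", "miR3"))

  # overlapping mRNA sets union correctly: {A,B,C} and {B,C,D} give 4
  tr2 <- tr
  tr2$mRNA <- c("A", "B", "C", "B", "C", "D")
  tr2$Sz <- 0.3
  expect_identical(call_sponges(tr2, 0.2)$n_unique_mrna, 4L)

  # raising the threshold never adds a call
  thresholds <- seq(0, 0.6, by = 0.05)
  n_calls <- vapply(thresholds, function(t) nrow(call_sponges(tr, t)$calls),
                    integer(1))
  expect_true(all(diff(n_calls) <= 0))

  empty <- call_sponges(tr, 10)
  expect_identical(nrow(empty$calls), 0L)
  expect_identical(empty$n_unique_mrna, 0L)
})
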