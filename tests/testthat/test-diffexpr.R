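mk_norm <- function(m, samples = sprintf("s%03d", seq_len(ncol(m))),
                    features = sprintf("f%03d", seq_len(nrow(m)))) {
  dimnames(m) <- list(features, samples)
  expression_matrix(m, "normalized")
}

test_that("M and D statistics follow the definitions", {
  groups <- two_groups(2, 2)
  norm <- mk_norm(matrix(100, 3, 4))
  st <- md_statistics(norm, groups)
  expect_equal(st$M, rep(0, 3))
  expect_equal(st$D, rep(0, 3))

  norm2 <- mk_norm(matrix(rep(c(50, 50, 200, 200), each = 1), 1, 4))
  st2 <- md_statistics(norm2, groups, pseudocount = 0)
  expect_equal(st2$M, 2)
  expect_equal(st2$D, 150)

  # swapping condition labels negates M and preserves D
  set.seed(10)
  norm3 <- mk_norm(matrix(rexp(6 * 30, rate = 0.01), 6, 30))
  g1 <- two_groups(15, 15)
  g2 <- sample_groups(setNames(rep(c("B", "A"), c(15, 15)), names(g1)))
  s1 <- md_statistics(norm3, g1); s2 <- md_statistics(norm3, g2)
  expect_equal(s1$M, -s2$M, tolerance = 1e-12)
  expect_equal(s1$D, s2$D, tolerance = 1e-12)
})

test_that("noise distribution enumerates within-condition sample pairs", {
  groups <- sample_groups(setNames(rep(c("A", "B"), c(3, 2)),
                                   sprintf("s%03d", 1:5)))
  norm <- mk_norm(matrix(c(1, 2, 4, 8, 16,
                           3, 3, 3, 3, 3), 2, 5, byrow = TRUE))
  nd <- noise_distribution(norm, groups, pseudocount = 0)
  expect_identical(nd$n_pairs, 4L)            # 3C2 + 2C2
  expect_identical(nd$n_points, 8L)           # 2 features x 4 pairs

  # hand enumeration: feature 1 pairs within A: (1,2),(1,4),(2,4); within B: (8,16)
  expect_setequal(round(nd$m[nd$d > 0 | nd$m > 0], 10),
                  round(c(1, 2, 1, 1), 10))
  expect_setequal(nd$d[seq_along(nd$d) %% 2 == 1], c(1, 3, 2, 8))

  same <- mk_norm(matrix(5, 3, 5))
  nds <- noise_distribution(same, groups)
  expect_true(all(nds$m == 0) && all(nds$d == 0))

  g_small <- factor(c("A", "A", "A", "B"), levels = c("A", "B"))
  names(g_small) <- sprintf("s%03d", c(1, 2, 3, 5))
  expect_error(noise_distribution(mk_norm(matrix(1, 2, 4),
                                          samples = names(g_small)), g_small),
               "< 2 samples")
})

test_that("noise subsampling respects the cap and the seed", {
  set.seed(11)
  norm <- mk_norm(matrix(rexp(100 * 10, 0.01), 100, 10))
  groups <- two_groups(5, 5)
  set.seed(99); n1 <- noise_distribution(norm, groups, max_points = 100)
  set.seed(99); n2 <- noise_distribution(norm, groups, max_points = 100)
  expect_identical(n1, n2)
  expect_identical(n1$n_points, 100L)
})

test_that("dominance probability counts strictly dominated noise points", {
  noise <- structure(list(m = c(0.1, 0.5, 1.0, 2.0, 3.0),
                          d = c(5, 1, 3, 2, 0.5),
                          n_pairs = 5L, n_points = 5L),
                     class = "NoiseDistribution")
  st <- data.frame(feature_id = c("a", "b", "c"),
                   M = c(5, 0, 1.5), D = c(100, 0, 6))
  p <- de_probability(st, noise)
  expect_equal(p[1], 1)       # dominates everything
  expect_equal(p[2], 0)       # (0,0) cannot strictly dominate
  expect_equal(p[3], 0.6)     # dominates (0.1,5),(0.5,1),(1.0,3); m too big elsewhere

  # brute-force oracle on random data
  set.seed(12)
  noise2 <- structure(list(m = abs(rnorm(400)), d = rexp(400, 0.1),
                           n_pairs = 400L, n_points = 400L),
                      class = "NoiseDistribution")
  st2 <- data.frame(feature_id = paste0("f", 1:50),
                    M = rnorm(50), D = rexp(50, 0.05))
  expect_equal(de_probability(st2, noise2),
               prob_oracle(st2$M, st2$D, noise2$m, noise2$d), tolerance = 1e-12)

  # ties count against the feature
  tie <- structure(list(m = 1, d = 1, n_pairs = 1L, n_points = 1L),
                   class = "NoiseDistribution")
  expect_equal(de_probability(data.frame(feature_id = "t", M = 1, D = 2), tie), 0)
  expect_equal(de_probability(data.frame(feature_id = "t", M = 2, D = 1), tie), 0)
})

test_that("dominance probability is monotone in |M| and D", {
  set.seed(13)
  noise <- structure(list(m = abs(rnorm(300)), d = rexp(300),
                          n_pairs = 300L, n_points = 300L),
                     class = "NoiseDistribution")
  M0 <- rnorm(1); D0 <- rexp(1)
  grid <- expand.grid(dm = seq(0, 2, by = 0.25), dd = seq(0, 3, by = 0.5))
  p <- de_probability(data.frame(feature_id = seq_len(nrow(grid)),
                                 M = abs(M0) + grid$dm, D = D0 + grid$dd), noise)
  for (i in seq_len(nrow(grid)))
    for (j in seq_len(nrow(grid)))
      if (grid$dm[i] <= grid$dm[j] && grid$dd[i] <= grid$dd[j])
        expect_lte(p[i], p[j])
})

test_that("FDR selection keeps the largest low-FDR prefix", {
  st <- data.frame(feature_id = paste0("f", 1:3), M = 1:3, D = 1:3)
  all1 <- select_by_fdr(st, c(1, 1, 1))
  expect_true(all(all1$selected))
  expect_equal(all1$fdr, rep(0, 3))

  none <- select_by_fdr(st, c(0.5, 0.5, 0.5))
  expect_false(any(none$selected))

  mix <- select_by_fdr(st, c(0.99, 0.98, 0.6))
  expect_identical(mix$selected, c(TRUE, TRUE, FALSE))
  expect_equal(mix$fdr, c(0.01, 0.015, 0.43 / 3), tolerance = 1e-12)
  expect_true(all(mix$fdr[mix$selected] <= 0.05))

  expect_error(select_by_fdr(st, c(0.5, 0.5, 0.5), q = 1.2), "q must")
  expect_error(select_by_fdr(st, c(-0.1, 0.5, 0.5)), "probabilities")
})

test_that("row standardization yields mean 0 and population sd 1", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("r1", paste0("s", 1:3)))
  z <- standardize_rows(m)
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)

  expect_warning(zc <- standardize_rows(matrix(7, 1, 4, dimnames = list("c", 1:4))),
                 "constant")
  expect_true(all(zc == 0))

  set.seed(14)
  mr <- matrix(rnorm(5 * 20), 5, 20, dimnames = list(paste0("r", 1:5), 1:20))
  zr <- standardize_rows(mr)
  expect_equal(unname(rowMeans(zr)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(rowMeans(zr^2)), rep(1, 5), tolerance = 1e-12)

  expect_error(standardize_rows(mr, character(0)), "empty")
  expect_error(standardize_rows(mr, "nope"), "unknown")
})
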