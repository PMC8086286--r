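# shared fixture builders; everything is generated in code at test time

rand_counts <- function(nfeat, nsamp, mu = 50, disp = 0.1, prefix = "g") {
  m <- matrix(rnbinom(nfeat * nsamp, mu = mu, size = 1 / disp), nfeat, nsamp,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(nfeat)),
                              sprintf("s%03d", seq_len(nsamp))))
  expression_matrix(m, "counts")
}

two_groups <- function(n_a, n_b) {
  sample_groups(setNames(rep(c("A", "B"), c(n_a, n_b)),
                         sprintf("s%03d", seq_len(n_a + n_b))))
}

# independent TMM oracle: the published weighted-trimmed-mean recipe,
# coded from scratch (no edgeR)
tmm_oracle <- function(m, logratio_trim = 0.30, abs_trim = 0.05) {
  ls <- colSums(m)
  uq <- apply(sweep(m, 2, ls, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  r <- m[, ref]; nR <- ls[ref]
  f <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]; nO <- ls[j]
    keep <- x > 0 & r > 0
    x <- x[keep]; rr <- r[keep]
    logR <- log2((x / nO) / (rr / nR))
    absE <- (log2(x / nO) + log2(rr / nR)) / 2
    v <- (nO - x) / (nO * x) + (nR - rr) / (nR * rr)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * abs_trim) + 1; hiS <- n + 1 - loS
    k <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[k] / v[k]) / sum(1 / v[k]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# brute-force strict-dominance probability
prob_oracle <- function(M, D, nm, nd) {
  vapply(seq_along(M), function(i) mean(abs(M[i]) > nm & D[i] > nd), numeric(1))
}

# residual-rank partial correlation oracle: regress ranks on rank(z),
# correlate the residuals
partial_oracle <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  cor(resid(lm(rx ~ rz)), resid(lm(ry ~ rz)))
}

write_toy_gtf <- function(path) {
  attr_line <- function(id, name, type)
    sprintf(paste0("chr1\tTEST\tgene\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; ",
                   "gene_name \"%s\"; gene_type \"%s\";"),
            1000 * id, 1000 * id + 500, sprintf("ENSG%011d.%d", id, id), name, type)
  writeLines(c(attr_line(1, "PCG1", "protein_coding"),
               attr_line(2, "PCG2", "protein_coding"),
               attr_line(3, "AS1", "antisense"),
               attr_line(4, "MIR1", "miRNA")), path)
  path
}
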