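# Independent oracles shared across test files.

# Direct-formula TMM oracle, written from the published procedure:
# pairwise M/A statistics against a reference column, double trimming
# (30% on M, 5% on A) by rank, inverse-asymptotic-variance weighting, and
# rescaling of the factors to geometric mean 1.
tmm_oracle <- function(mat, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(mat)
  uq <- apply(mat, 2L, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(mat)), function(k) {
    obs <- mat[, k]; refc <- mat[, ref]
    nO <- lib[k]; nR <- lib[ref]
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
      (rank(absE) >= loS & rank(absE) <= hiS)
    if (!any(keep)) return(1)
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# deterministic stop-free CDS built codon-wise
make_cds <- function(n_codons, seed = 3) {
  set.seed(seed)
  cod <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           c("A", "C", "G", "T")), 1, paste, collapse = "")
  cod <- setdiff(cod, c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(cod, n_codons - 2, replace = TRUE), "TAA"),
        collapse = "")
}
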