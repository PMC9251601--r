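## Shared fixtures and independent oracles. Everything is generated in
## code; oracles are deliberately naive (per-element loops, longhand
## normal equations) and independent of the package's vectorised paths.

## a desk-scale SimConfig that keeps the pure-group sizes of the full
## design (12 vs 19) but shrinks everything else
smallConfig <- function(seed = 1, ...) {
  args <- list(n_accessions = 60, n_pure_a = 12, n_pure_b = 19,
               n_snps = 600, n_genes = 120, n_metabolites = 25,
               n_epav = 6, n_deg = 6, n_cis_eqtl = 5, n_trans_eqtl = 3,
               n_met_links = 4, n_met_snp_links = 2, n_das = 3,
               n_sparse_metabolites = 2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simConfig, args)
}

nullConfig <- function(seed = 1, ...) {
  smallConfig(seed = seed, n_epav = 0, n_deg = 0, n_cis_eqtl = 0,
              n_trans_eqtl = 0, n_met_links = 0, n_met_snp_links = 0,
              n_das = 0, ...)
}

## random genotype matrix with controllable missingness
randomGenotype <- function(n = 30, M = 60, miss = 0.1, seed = 1,
                           nchr = 2) {
  set.seed(seed)
  d <- matrix(sample(0:2, n * M, replace = TRUE), n, M,
              dimnames = list(sprintf("a%02d", 1:n), NULL))
  if (miss > 0) d[runif(n * M) < miss] <- NA
  per <- diff(round(seq(0, M, length.out = nchr + 1)))
  v <- data.frame(id = sprintf("s%03d", 1:M),
                  chrom = rep(paste0("chr", 1:nchr), per),
                  pos = unlist(lapply(per, function(m)
                    sort(sample.int(1e6, m)))),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  GenotypeMatrix(d, v)
}

## longhand OLS of y on cbind(1, covars, x): solves the normal equations
## explicitly and returns the x coefficient, its SE and two-sided p.
olsOracle <- function(y, x, covars) {
  X <- cbind(1, covars, x)
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  j <- ncol(X)
  tt <- b[j] / se[j]
  list(effect = unname(b[j]), se = unname(se[j]),
       p = unname(2 * pt(-abs(tt), df)))
}

## independent Weir-Cockerham theta for one SNP, written directly from
## the two-population variance-component formulas
wcOracle <- function(da, db) {
  n1 <- length(da); n2 <- length(db)
  p1 <- mean(da) / 2; p2 <- mean(db) / 2
  h1 <- mean(da == 1); h2 <- mean(db == 1)
  nbar <- (n1 + n2) / 2
  nc <- (2 * nbar - (n1^2 + n2^2) / (2 * nbar))
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a / (a + b + cc)
}

## mean |allele-frequency difference| between two Balding-Nichols
## populations sampled at sizes n1/n2: brute-force Monte-Carlo oracle
bnDivergenceOracle <- function(F, n1, n2, n_snps = 50000, seed = 99) {
  set.seed(seed)
  p0 <- runif(n_snps, 0.05, 0.95)
  sh <- (1 - F) / F
  pa <- rbeta(n_snps, p0 * sh, (1 - p0) * sh)
  pb <- rbeta(n_snps, p0 * sh, (1 - p0) * sh)
  fa <- rbinom(n_snps, 2 * n1, pa) / (2 * n1)
  fb <- rbinom(n_snps, 2 * n2, pb) / (2 * n2)
  mean(abs(fa - fb))
}

## realised mean |frequency difference| between the pure groups of a
## synthetic dataset
realisedDivergence <- function(ds) {
  pg <- pureGroups(ds@groups)
  d <- dosages(ds@genotype)
  fa <- colMeans(d[pg$A, , drop = FALSE], na.rm = TRUE) / 2
  fb <- colMeans(d[pg$B, , drop = FALSE], na.rm = TRUE) / 2
  mean(abs(fa - fb), na.rm = TRUE)
}

## multivariate-normal draw y ~ N(0, h2 * K + (1 - h2) * I): a
## structured null trait with heritable background and no causal SNP
structuredNullTrait <- function(K, h2 = 0.5, seed = 1) {
  set.seed(seed)
  eig <- eigen(unclass(K), symmetric = TRUE)
  d <- pmax(eig$values, 0)
  n <- nrow(K)
  y <- eig$vectors %*% (sqrt(h2 * d) * rnorm(n)) +
    sqrt(1 - h2) * rnorm(n)
  setNames(as.vector(y), rownames(K))
}
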