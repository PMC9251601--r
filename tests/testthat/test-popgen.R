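test_that("variant filtering keeps at the MAF boundary and drops by missingness", {
  ## 20 accessions: MAF 0.05 is exactly 2 alt alleles out of 40
  d <- matrix(0, 20, 3, dimnames = list(sprintf("a%02d", 1:20), NULL))
  d[1, 1] <- 1               # MAF 1/40 = 0.025 -> removed
  d[1:2, 2] <- 1             # MAF 2/40 = 0.05  -> retained (boundary)
  d[1:10, 3] <- 1            # MAF 0.25 but 35% missing -> removed
  d[11:17, 3] <- NA
  v <- data.frame(id = paste0("s", 1:3), chrom = "chr1", pos = 1:3 * 100,
                  ref = "A", alt = "G")
  g <- filterVariants(GenotypeMatrix(d, v))
  expect_identical(variants(g)$id, "s2")
})

test_that("surviving filter set equals an independent per-SNP loop", {
  g <- randomGenotype(100, 500, miss = 0.25, seed = 8)
  ## make MAF and missingness vary: zero out random SNP tails
  d <- dosages(g)
  set.seed(9)
  for (j in sample(500, 150)) d[sample(100, 92), j] <- 0
  for (j in sample(500, 60)) d[sample(100, 40), j] <- NA
  g <- GenotypeMatrix(d, variants(g))
  got <- variants(filterVariants(g, 0.05, 0.3))$id
  ref <- character(0)
  for (j in seq_len(ncol(d))) {
    x <- d[, j]
    obs <- x[!is.na(x)]
    p <- sum(obs) / (2 * length(obs))
    if (min(p, 1 - p) >= 0.05 && mean(is.na(x)) <= 0.3)
      ref <- c(ref, variants(g)$id[j])
  }
  expect_identical(got, ref)
})

test_that("mean imputation fills missing dosages with the observed column mean", {
  d <- matrix(c(0, 2, NA, 1, 1, 1, NA, NA, NA), 3,
              dimnames = list(c("a", "b", "c"), NULL))
  v <- data.frame(id = paste0("s", 1:3), chrom = "chr1",
                  pos = c(10, 20, 30), ref = "A", alt = "G")
  expect_warning(gi <- imputeMean(GenotypeMatrix(d, v)), "all values missing")
  expect_equal(unname(dosages(gi)[, 1]), c(0, 2, 1))
  expect_equal(unname(dosages(gi)[, 2]), c(1, 1, 1))
  expect_equal(ncol(dosages(gi)), 2)

  gc <- randomGenotype(12, 30, miss = 0)
  expect_identical(dosages(imputeMean(gc)), dosages(gc))

  gm <- randomGenotype(25, 40, miss = 0.2, seed = 4)
  di <- dosages(imputeMean(gm))
  dm <- dosages(gm)
  for (j in seq_len(ncol(dm))) {
    ref <- dm[, j]
    ref[is.na(ref)] <- mean(dm[, j], na.rm = TRUE)
    expect_equal(unname(di[, j]), unname(ref))
  }
})

test_that("LD pruning removes one of a perfect pair, keeps independent SNPs, and passes exhaustive verification", {
  set.seed(21)
  base <- sample(0:2, 200, replace = TRUE)
  d <- cbind(base, base, sample(0:2, 200, replace = TRUE))
  rownames(d) <- sprintf("a%03d", 1:200)
  v <- data.frame(id = paste0("s", 1:3), chrom = "chr1",
                  pos = c(100, 200, 300), ref = "A", alt = "G")
  kept <- ldPrune(GenotypeMatrix(d, v))
  expect_length(intersect(kept, c("s1", "s2")), 1)
  expect_true("s3" %in% kept)

  ## mutually independent SNPs (large n keeps sample r2 far below 0.2)
  gi <- randomGenotype(400, 60, miss = 0, seed = 31, nchr = 1)
  r2 <- suppressWarnings(cor(dosages(gi)))^2
  diag(r2) <- 0
  stopifnot(max(r2) < 0.2) # fixture precondition
  expect_identical(ldPrune(gi), variants(gi)$id)

  ## 300-SNP single-chromosome fixture with planted correlated blocks
  set.seed(77)
  n <- 150
  d <- matrix(sample(0:2, n * 300, replace = TRUE), n, 300)
  for (b in seq(1, 300, by = 30)) { # plant near-duplicates
    for (k in 1:4) {
      col <- d[, b]
      flip <- sample(n, 5)
      col[flip] <- sample(0:2, 5, replace = TRUE)
      d[, b + k] <- col
    }
  }
  rownames(d) <- sprintf("a%03d", 1:n)
  v <- data.frame(id = sprintf("s%03d", 1:300), chrom = "chr1",
                  pos = sort(sample.int(3e6, 300)), ref = "A", alt = "G")
  g <- GenotypeMatrix(d, v)
  kept <- ldPrune(g)
  expect_true(verifyLdPrune(g, kept))
  expect_lt(length(kept), 300)
  expect_error(ldPrune(g, window_snps = 1), "window_snps")
})

test_that("genotype PCA recovers rank-1 structure and separates subpopulations", {
  ## identical columns -> standardised matrix has rank 1
  set.seed(5)
  base <- sample(0:2, 30, replace = TRUE)
  d <- matrix(rep(base, 10), 30, 10,
              dimnames = list(sprintf("a%02d", 1:30), NULL))
  v <- data.frame(id = paste0("s", 1:10), chrom = "chr1",
                  pos = 1:10 * 50, ref = "A", alt = "G")
  pca <- genotypePca(GenotypeMatrix(d, v), 1)
  expect_equal(pca$explained_variance[1], 1)

  ds <- simulatePopulation(smallConfig(seed = 12, fst_divergence = 0.3))
  g <- imputeMean(ds@genotype)
  pca <- genotypePca(g, 3)
  pg <- pureGroups(ds@groups)
  sA <- pca$scores[pg$A, 1]
  sB <- pca$scores[pg$B, 1]
  expect_true(max(sA) < min(sB) || max(sB) < min(sA)) # zero overlap

  ## decomposition identity: scores = standardised matrix x loadings
  X <- dosages(g)
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  Xs <- sweep(sweep(X[, keep], 2, 2 * p[keep]), 2,
              sqrt(2 * p[keep] * (1 - p[keep])), "/")
  expect_equal(unname(pca$scores), unname(Xs %*% pca$loadings),
               tolerance = 1e-8)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  expect_error(genotypePca(g, nrow(X)), "smaller")
})

test_that("VanRaden kinship matches a brute-force double loop and is PSD", {
  g <- randomGenotype(10, 50, miss = 0, seed = 14)
  K <- kinshipMatrix(g)
  X <- dosages(g)
  p <- colMeans(X) / 2
  denom <- 2 * sum(p * (1 - p))
  ref <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    ref[i, j] <- sum((X[i, ] - 2 * p) * (X[j, ] - 2 * p)) / denom
  expect_equal(unname(unclass(K)), ref, tolerance = 1e-10)
  expect_equal(unclass(K), t(unclass(K)))
  ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * sum(diag(unclass(K))))

  ## duplicated accessions give equal rows and the largest diagonals
  d2 <- X[c(1, 1, 2:6), ]
  rownames(d2) <- paste0("b", 1:7)
  K2 <- unclass(kinshipMatrix(GenotypeMatrix(d2, variants(g))))
  expect_equal(K2[1, ], K2[2, ], ignore_attr = TRUE)
  expect_equal(K2[1, 2], K2[1, 1])

  ## unrelated accessions: off-diagonal mean ~ 0
  set.seed(3)
  M <- 800; n <- 40
  p <- runif(M, 0.1, 0.9)
  du <- matrix(rbinom(n * M, 2, rep(p, each = n)), n, M,
               dimnames = list(paste0("u", 1:n), NULL))
  vu <- data.frame(id = paste0("s", 1:M), chrom = "chr1",
                   pos = sort(sample.int(1e7, M)), ref = "A", alt = "G")
  Ku <- unclass(kinshipMatrix(GenotypeMatrix(du, vu)))
  expect_lt(abs(mean(Ku[upper.tri(Ku)])), 0.05)
})

test_that("Weir-Cockerham Fst is exact for fixed differences, ~0 without differentiation, and matches the oracle", {
  ## fixed difference, 12 vs 19 accessions
  d <- matrix(c(rep(0, 12), rep(2, 19)), ncol = 1,
              dimnames = list(sprintf("a%02d", 1:31), NULL))
  v <- data.frame(id = "s1", chrom = "chr1", pos = 100, ref = "A",
                  alt = "G")
  fst <- fstScan(GenotypeMatrix(d, v), sprintf("a%02d", 1:12),
                 sprintf("a%02d", 13:31))
  expect_equal(fst$fst, 1)
  expect_true(fst$defined)

  ## same allele frequencies in both groups, large n
  set.seed(6)
  n <- 400
  dd <- matrix(rbinom(2 * n * 20, 2, 0.4), 2 * n, 20,
               dimnames = list(paste0("a", 1:(2 * n)), NULL))
  vv <- data.frame(id = paste0("s", 1:20), chrom = "chr1",
                   pos = 1:20 * 10, ref = "A", alt = "G")
  f0 <- fstScan(GenotypeMatrix(dd, vv), paste0("a", 1:n),
                paste0("a", (n + 1):(2 * n)))
  expect_lt(abs(mean(f0$fst)), 0.01)

  ## random two-group fixture vs the independent oracle; invariant <= 1
  g <- randomGenotype(40, 60, miss = 0.1, seed = 16)
  ga <- paste0("a", sprintf("%02d", 1:18))
  gb <- paste0("a", sprintf("%02d", 19:40))
  fr <- fstScan(g, ga, gb)
  d <- dosages(g)
  for (j in seq_len(60)) {
    da <- d[ga, j]; da <- da[!is.na(da)]
    db <- d[gb, j]; db <- db[!is.na(db)]
    ref <- wcOracle(da, db)
    if (fr$defined[j]) expect_equal(fr$fst[j], ref, tolerance = 1e-10)
  }
  expect_true(all(fr$fst[fr$defined] <= 1))

  ## monomorphic SNP flagged undefined, not dropped
  dm <- matrix(0, 10, 1, dimnames = list(paste0("m", 1:10), NULL))
  fm <- fstScan(GenotypeMatrix(dm, v), paste0("m", 1:5), paste0("m", 6:10))
  expect_false(fm$defined)
  expect_true(is.na(fm$fst))
  expect_equal(nrow(fm), 1)
})

test_that("Hudson and Weir-Cockerham estimators agree on balanced simulated data", {
  ds <- simulatePopulation(smallConfig(
    seed = 18, n_accessions = 120, n_pure_a = 55, n_pure_b = 55,
    n_snps = 500, n_genes = 30, n_metabolites = 10, n_epav = 0,
    n_deg = 0, n_cis_eqtl = 0, n_trans_eqtl = 0, n_met_links = 0,
    n_met_snp_links = 0, n_das = 0, n_sparse_metabolites = 0))
  pg <- pureGroups(ds@groups)
  wc <- fstScan(ds@genotype, pg$A, pg$B, method = "wc")
  hu <- fstScan(ds@genotype, pg$A, pg$B, method = "hudson")
  both <- wc$defined & hu$defined
  expect_gt(mean(both), 0.9)
  expect_lt(mean(abs(wc$fst[both] - hu$fst[both])), 0.02)
})
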