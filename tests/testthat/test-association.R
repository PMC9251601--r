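## shared fixture: an imputed genotype panel with PCA and kinship
assocFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulatePopulation(smallConfig(seed = 61))
      g <- imputeMean(filterVariants(ds@genotype))
      cache <<- list(ds = ds, g = g, pca = genotypePca(g, 5),
                     kin = kinshipMatrix(g))
    }
    cache
  }
})

test_that("GLM scan recovers an exact linear signal and matches the closed-form oracle", {
  fx <- assocFixture()
  X <- dosages(fx$g)
  j <- which.max(apply(X, 2, var))
  y <- setNames(2 * X[, j], rownames(X))
  tab <- glmScan(y, fx$g, 5, fx$pca)
  expect_equal(tab$effect[j], 2, tolerance = 1e-6)
  expect_lt(tab$p[j], 1e-100)

  ## longhand normal-equations oracle on a 100 x 50 fixture
  g <- randomGenotype(100, 50, miss = 0, seed = 71)
  gp <- genotypePca(g, 5)
  set.seed(72)
  y <- setNames(rnorm(100) + 0.4 * dosages(g)[, 7], accessions(g))
  tab <- glmScan(y, g, 5, gp)
  for (jj in c(1, 7, 25, 50)) {
    ref <- olsOracle(unname(y), dosages(g)[, jj], gp$scores[, 1:5])
    expect_equal(tab$effect[jj], ref$effect, tolerance = 1e-8)
    expect_equal(tab$se[jj], ref$se, tolerance = 1e-8)
    expect_equal(tab$p[jj], ref$p, tolerance = 1e-8)
  }
})

test_that("GLM scan is calibrated on a permuted trait and flags monomorphic SNPs", {
  set.seed(81)
  n <- 150; M <- 2000
  p <- runif(M, 0.1, 0.9)
  d <- matrix(rbinom(n * M, 2, rep(p, each = n)), n, M,
              dimnames = list(paste0("a", 1:n), NULL))
  d[, 1] <- 1 # monomorphic
  v <- data.frame(id = paste0("s", 1:M), chrom = "chr1",
                  pos = sort(sample.int(1e8, M)), ref = "A", alt = "G")
  g <- GenotypeMatrix(d, v)
  gp <- genotypePca(g, 5)
  y <- setNames(rnorm(n), paste0("a", 1:n))
  tab <- glmScan(y, g, 5, gp)
  expect_equal(tab$p[1], 1)
  expect_equal(tab$effect[1], 0)
  frac <- mean(tab$p[-1] < 0.01)
  se3 <- 3 * sqrt(0.01 * 0.99 / (M - 1))
  expect_lt(abs(frac - 0.01), se3)
  expect_true(all(tab$p > 0 & tab$p <= 1))
  expect_true(all(tab$se > 0))
  lam <- genomicInflation(tab$p)
  expect_gt(lam, 0.8); expect_lt(lam, 1.25)
})

test_that("MLM with identity kinship reproduces the GLM scan", {
  fx <- assocFixture()
  n <- nrow(dosages(fx$g))
  K <- diag(n)
  dimnames(K) <- list(accessions(fx$g), accessions(fx$g))
  set.seed(91)
  y <- setNames(rnorm(n) + 0.5 * dosages(fx$g)[, 3], accessions(fx$g))
  glm <- glmScan(y, fx$g, 3, fx$pca)
  mlm <- mlmScan(y, fx$g, K, 3, fx$pca)
  expect_equal(mlm$p, glm$p, tolerance = 1e-6)
  expect_equal(mlm$effect, glm$effect, tolerance = 1e-6)
})

test_that("MLM rejects a non-PSD kinship before scanning", {
  fx <- assocFixture()
  n <- nrow(dosages(fx$g))
  K <- diag(n); K[1, 2] <- K[2, 1] <- 2
  dimnames(K) <- list(accessions(fx$g), accessions(fx$g))
  y <- setNames(rnorm(n), accessions(fx$g))
  expect_error(mlmScan(y, fx$g, K, 3, fx$pca), "positive semi-definite")
})

test_that("REML recovers the simulated heritability on average", {
  ds <- simulatePopulation(smallConfig(
    seed = 95, n_accessions = 200, n_pure_a = 40, n_pure_b = 40,
    fst_divergence = 0.3, n_snps = 800, n_genes = 30, n_metabolites = 5,
    n_epav = 0, n_deg = 0, n_cis_eqtl = 0, n_trans_eqtl = 0,
    n_met_links = 0, n_met_snp_links = 0, n_das = 0,
    n_sparse_metabolites = 0))
  g <- imputeMean(ds@genotype)
  K <- kinshipMatrix(g)
  pca <- genotypePca(g, 3)
  mk <- mean(diag(unclass(K)))
  h2 <- vapply(1:20, function(i) {
    y <- structuredNullTrait(K, 0.5, seed = 1000 + i)
    tab <- mlmScan(y, g, K, 3, pca)
    lam <- attr(tab, "lambda")
    lam * mk / (lam * mk + 1)
  }, 0)
  expect_lt(abs(mean(h2) - 0.5), 0.15)
})

test_that("MLM controls confounding from heritable background structure", {
  fx <- assocFixture()
  lams <- t(vapply(1:3, function(i) {
    y <- structuredNullTrait(fx$kin, 0.6, seed = 300 + i)
    gl <- glmScan(y, fx$g, 5, fx$pca)
    ml <- mlmScan(y, fx$g, fx$kin, 3, fx$pca)
    c(glm = genomicInflation(gl$p), mlm = genomicInflation(ml$p))
  }, c(glm = 0, mlm = 0)))
  expect_gt(mean(lams[, "mlm"]), 0.8)
  expect_lt(mean(lams[, "mlm"]), 1.25)
  expect_gte(mean(lams[, "glm"]), mean(lams[, "mlm"]))
})

test_that("permutation thresholds are deterministic, quantile-correct and near Bonferroni for independent SNPs", {
  set.seed(101)
  n <- 120; M <- 400
  p <- runif(M, 0.1, 0.9)
  d <- matrix(rbinom(n * M, 2, rep(p, each = n)), n, M,
              dimnames = list(paste0("a", 1:n), NULL))
  v <- data.frame(id = paste0("s", 1:M), chrom = "chr1",
                  pos = sort(sample.int(1e8, M)), ref = "A", alt = "G")
  g <- GenotypeMatrix(d, v)
  gp <- genotypePca(g, 5)
  y <- setNames(rnorm(n), paste0("a", 1:n))
  th1 <- permutationThreshold(y, g, "GLM", 100, 0.05, seed = 5, pca = gp)
  th2 <- permutationThreshold(y, g, "GLM", 100, 0.05, seed = 5, pca = gp)
  expect_identical(th1$cutoff, th2$cutoff)
  thMax <- permutationThreshold(y, g, "GLM", 100, 1.0, seed = 5, pca = gp)
  expect_equal(thMax$cutoff, max(th1$minima))
  ## order-statistics sanity band around the Bonferroni cutoff
  bon <- 0.05 / M
  expect_gt(th1$cutoff, bon * 0.2)
  expect_lt(th1$cutoff, bon * 5)
  ## monotone non-increasing in alpha
  cuts <- vapply(c(0.01, 0.05, 0.2, 1), function(a)
    quantile(th1$minima, a, type = 1), 0)
  expect_true(all(diff(cuts) >= 0))
  expect_warning(permutationThreshold(y, g, "GLM", 10, 0.5, seed = 1,
                                      pca = gp), "unstable")
})

test_that("MLM permutation minima agree with the full scan", {
  fx <- assocFixture()
  y <- structuredNullTrait(fx$kin, 0.4, seed = 7)
  th <- permutationThreshold(y, fx$g, "MLM", 20, 0.25, seed = 11,
                             pca = fx$pca, kinship = fx$kin)
  setup <- TriOmicNet:::.mlmSetup(fx$g, fx$kin, fx$pca, 3)
  set.seed(11)
  P <- vapply(seq_len(20), function(i) sample(y[accessions(fx$g)]),
              numeric(length(y)))
  ref <- vapply(seq_len(20), function(i)
    min(TriOmicNet:::.mlmScanCore(setup, P[, i])$p), 0)
  expect_equal(th$minima, ref, tolerance = 1e-10)
})

test_that("co-identification intersects models exactly as a brute-force loop", {
  t1 <- data.frame(trait = "m1", snp = paste0("s", 1:6), model = "GLM",
                   effect = 1, se = 1,
                   p = c(1e-8, 1e-8, 0.5, 1e-8, 0.9, 1e-9))
  t2 <- data.frame(trait = "m1", snp = paste0("s", 1:6), model = "MLM",
                   effect = 1, se = 1,
                   p = c(1e-8, 0.4, 1e-8, 1e-8, 0.8, 1e-9))
  co <- coIdentified(list(GLM = t1, MLM = t2),
                     list(GLM = 1e-6, MLM = 1e-6), min_models = 2)
  expect_setequal(co$snp, c("s1", "s4", "s6"))
  co1 <- coIdentified(list(GLM = t1, MLM = t2),
                      list(GLM = 1e-6, MLM = 1e-6), min_models = 1)
  ref <- unique(c(t1$snp[t1$p < 1e-6], t2$snp[t2$p < 1e-6]))
  expect_setequal(co1$snp, ref)
})

test_that("QTT regression recovers a planted identity and matches the oracle", {
  fx <- assocFixture()
  e <- fx$ds@expression
  V <- log2(exprValues(e) + 1)
  j <- which.max(apply(V, 2, var))
  y <- setNames(3 * V[, j], rownames(V))
  qt <- qttScan(y, e, fx$pca, 3, alpha = 0.01)
  hit <- qt[qt$gene == colnames(V)[j], ]
  expect_equal(hit$coef, 3, tolerance = 1e-6)

  set.seed(111)
  y2 <- setNames(rnorm(nrow(V)) + 0.8 * V[, j], rownames(V))
  qt2 <- qttScan(y2, e, fx$pca, 3, alpha = 1)
  for (gn in colnames(V)[c(2, 20, j)]) {
    if (sd(V[, gn]) == 0) next
    ref <- olsOracle(unname(y2), V[, gn], fx$pca$scores[, 1:3])
    row <- qt2[qt2$gene == gn, ]
    expect_equal(row$coef, ref$effect, tolerance = 1e-8)
    expect_equal(row$p, ref$p, tolerance = 1e-8)
  }
})

test_that("QTT hit rate on a permuted metabolite is near the nominal alpha", {
  set.seed(121)
  n <- 100; G <- 500
  V <- matrix(2^rnorm(n * G, 3, 1), n, G,
              dimnames = list(paste0("a", 1:n), sprintf("g%03d", 1:G)))
  e <- ExpressionMatrix(V)
  g <- randomGenotype(n, 300, miss = 0, seed = 122)
  rownames(g@dosages) <- paste0("a", 1:n)
  gp <- genotypePca(g, 3)
  y <- setNames(rnorm(n), paste0("a", 1:n))
  qt <- qttScan(y, e, gp, 3, alpha = 0.01)
  frac <- nrow(qt) / G
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / G) + 1e-9)
})

test_that("eQTL classification respects the strict 100 kb boundary and partitions records", {
  ## controlled geometry: SNPs at known distances from two genes plus an
  ## unplaced gene; expression is an exact copy of the causal dosage
  set.seed(131)
  n <- 80
  pos <- c(5e5, 1e6, 1e6 + 99999, 1e6 + 100000 + 5000)
  M <- length(pos)
  d <- matrix(rbinom(n * M, 2, 0.5), n, M,
              dimnames = list(paste0("a", 1:n), NULL))
  v <- data.frame(id = paste0("s", 1:M), chrom = "chr1", pos = pos,
                  ref = "A", alt = "G")
  g <- GenotypeMatrix(d, v)
  ## gene1 spans s2 (inside); s3 is 99999 bp from its end; s4 is 100000
  genes <- data.frame(id = c("gA", "gB", "gU"),
                      chrom = c("chr1", "chr1", NA),
                      start = c(999000, 999000, NA),
                      end = c(1000000, 1000000, NA))
  V <- cbind(gA = d[, 2] + 0.01 * rnorm(n),
             gB = d[, 3] + 0.01 * rnorm(n),
             gU = d[, 4] + 0.01 * rnorm(n))
  V <- V - min(V) # non-negative
  rownames(V) <- paste0("a", 1:n)
  e <- ExpressionMatrix(V, genes)
  gp <- genotypePca(g, 2)
  eq <- eqtlScan(e, g, pca = gp, models = "GLM",
                 threshold = list(method = "bonferroni", alpha = 0.05),
                 min_models = 1, n_pcs_glm = 2, log_transform = FALSE)
  expect_true(all(eq$class %in% c("cis", "trans", "unassigned")))
  rA <- eq[eq$gene == "gA" & eq$snp == "s2", ]
  expect_equal(rA$class, "cis"); expect_equal(rA$distance, 0)
  rB <- eq[eq$gene == "gB" & eq$snp == "s3", ]
  expect_equal(rB$class, "cis"); expect_equal(rB$distance, 99999)
  rB4 <- eq[eq$gene == "gB" & eq$snp == "s4", ]
  ## 100000 + 5000 - 1000000... s4 sits 105000 - 0 = 105000 bp past end?
  ## distance = pos - end = 1105000 - 1000000
  rU <- eq[eq$gene == "gU", ]
  expect_true(all(rU$class == "unassigned"))
  ## strict boundary: a SNP exactly cis_max away is trans
  eq2 <- eqtlScan(e, g, pca = gp, models = "GLM",
                  threshold = list(method = "bonferroni", alpha = 0.05),
                  min_models = 1, n_pcs_glm = 2, log_transform = FALSE,
                  cis_max = 105000)
  r4 <- eq2[eq2$gene == "gU" | (eq2$gene == "gB" & eq2$snp == "s4"), ]
  rb4 <- eq2[eq2$gene == "gB" & eq2$snp == "s4", ]
  expect_equal(rb4$distance, 105000)
  expect_equal(rb4$class, "trans") # d == cis_max is not cis
  eq3 <- eqtlScan(e, g, pca = gp, models = "GLM",
                  threshold = list(method = "bonferroni", alpha = 0.05),
                  min_models = 1, n_pcs_glm = 2, log_transform = FALSE,
                  cis_max = 105001)
  expect_equal(eq3[eq3$gene == "gB" & eq3$snp == "s4", ]$class, "cis")
})
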