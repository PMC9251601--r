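## Association layers: per-SNP GLM and single-variance-component mixed
## model (P3D) scans, permutation significance thresholds, multi-model
## co-identification, QTT regression and eQTL scanning with cis/trans
## classification.

.covariates <- function(pca, accs, n_pcs) {
  if (n_pcs > 0) {
    sc <- pca$scores
    if (is.null(rownames(sc)) || !all(accs %in% rownames(sc)))
      stop("PCA scores must be rownamed by accession and cover the trait")
    cbind(rep(1, length(accs)), sc[accs, seq_len(n_pcs), drop = FALSE])
  } else {
    matrix(1, length(accs), 1)
  }
}

.assocTable <- function(trait_name, snps, model, res) {
  data.frame(trait = trait_name, snp = snps, model = model,
             effect = res$effect[, 1], se = res$se[, 1], p = res$p[, 1],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-SNP general linear model (GLM) association scan
#'
#' Ordinary least squares of the trait on intercept, SNP dosage and the
#' first `n_pcs` genotype principal components; two-sided t-test p-value
#' for the dosage coefficient. Monomorphic (or collinear-degenerate)
#' SNPs are reported with effect 0, SE Inf, p = 1.
#'
#' @param trait named numeric vector (accession-indexed); accessions with
#'   missing values are dropped.
#' @param g a complete [GenotypeMatrix-class].
#' @param n_pcs number of PC covariates (default 5).
#' @param pca a `PcaResult` from [genotypePca()].
#' @param trait_name label stored in the output.
#' @return data.frame (`AssociationTable`): `trait`, `snp`, `model`,
#'   `effect`, `se`, `p`.
#' @export
glmScan <- function(trait, g, n_pcs = 5, pca, trait_name = "trait") {
  X <- g@dosages
  if (anyNA(X)) stop("genotype matrix must be complete; run imputeMean()")
  y <- trait[rownames(X)]
  keep <- !is.na(y)
  if (sum(keep) < n_pcs + 3)
    stop("trait needs at least n_pcs + 3 non-missing accessions")
  W <- .covariates(pca, rownames(X)[keep], n_pcs)
  res <- .scanOls(matrix(y[keep]), X[keep, , drop = FALSE], W)
  .assocTable(trait_name, g@variants$id, "GLM", res)
}

## Spectral pre-computation shared by all MLM scans on one dataset.
.mlmSetup <- function(g, kinship, pca, n_pcs = 3) {
  X <- g@dosages
  if (anyNA(X)) stop("genotype matrix must be complete; run imputeMean()")
  K <- unclass(kinship)
  if (!isTRUE(all.equal(K, t(K), tolerance = 1e-8)))
    stop("kinship matrix must be symmetric")
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values), 1))
    stop("kinship matrix is not positive semi-definite")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  W <- .covariates(pca, rownames(X), n_pcs)
  list(U = U, d = d, Xs = crossprod(U, X), Ws = crossprod(U, W),
       snps = g@variants$id, accs = rownames(X))
}

## REML estimate of lambda = sigma_g^2 / sigma_e^2 by 1-D (Brent-style)
## optimisation on the log scale, in the eigenbasis of K.
.remlRatio <- function(ys, Ws, d) {
  n <- length(ys)
  q <- qr(Ws)$rank
  negll <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    sw <- sqrt(w)
    qa <- qr(Ws * sw)
    rss <- sum(qr.resid(qa, ys * sw)^2)
    0.5 * ((n - q) * log(rss) - sum(log(w)) +
             2 * sum(log(abs(diag(qr.R(qa))))))
  }
  op <- optimize(negll, c(log(1e-6), log(1e6)))
  if (!is.finite(op$objective))
    stop("REML variance-ratio estimation failed to converge")
  exp(op$minimum)
}

.mlmScanCore <- function(setup, y, lambda = NULL) {
  ys <- as.vector(crossprod(setup$U, y))
  lam <- if (is.null(lambda)) .remlRatio(ys, setup$Ws, setup$d) else lambda
  sw <- sqrt(1 / (lam * setup$d + 1))
  res <- .scanOls(matrix(ys * sw), setup$Xs * sw, setup$Ws * sw)
  res$lambda <- lam
  res
}

#' Per-SNP mixed linear model (MLM) association scan
#'
#' Fits y = W a + x s + u + e with u ~ N(0, sg^2 K) and e ~ N(0, se^2 I).
#' The variance ratio sg^2/se^2 is estimated once per trait by REML under
#' the no-SNP null via spectral decomposition of K and one-dimensional
#' optimisation (the P3D approximation), then every SNP is tested by
#' generalised least squares with the covariance fixed. With K = I the
#' scan reduces exactly to [glmScan()] with the same covariates.
#'
#' @inheritParams glmScan
#' @param kinship a `KinshipMatrix` (symmetric PSD) from
#'   [kinshipMatrix()].
#' @param n_pcs number of PC covariates (default 3).
#' @return data.frame (`AssociationTable`) with an attribute `lambda`
#'   (the estimated variance ratio).
#' @export
mlmScan <- function(trait, g, kinship, n_pcs = 3, pca,
                    trait_name = "trait") {
  y <- trait[accessions(g)]
  if (anyNA(y)) {
    keep <- which(!is.na(y))
    g <- GenotypeMatrix(g@dosages[keep, , drop = FALSE], g@variants)
    kinship <- unclass(kinship)[keep, keep]
    y <- y[keep]
  }
  setup <- .mlmSetup(g, kinship, pca, n_pcs)
  res <- .mlmScanCore(setup, y)
  out <- .assocTable(trait_name, g@variants$id, "MLM", res)
  attr(out, "lambda") <- res$lambda
  out
}

#' Empirical genome-wide significance threshold by trait permutation
#'
#' The trait is permuted across accessions `n_permutations` times; each
#' permutation records the genome-wide minimum p-value of the scan, and
#' the cutoff is the empirical `alpha`-quantile (order statistic) of
#' those minima.
#'
#' @inheritParams glmScan
#' @param model "GLM" or "MLM".
#' @param n_permutations number of permutations (default 100; fewer than
#'   20 triggers a warning).
#' @param alpha quantile level (default 0.05).
#' @param seed RNG seed, stored in the result.
#' @param kinship required for model = "MLM".
#' @return list of class `SignificanceThreshold`: `method`, `model`,
#'   `alpha`, `n_permutations`, `seed`, `cutoff`, `minima`.
#' @export
permutationThreshold <- function(trait, g, model = c("GLM", "MLM"),
                                 n_permutations = 100, alpha = 0.05,
                                 seed = 1, pca,
                                 n_pcs = if (model == "GLM") 5 else 3,
                                 kinship = NULL) {
  model <- match.arg(model)
  if (n_permutations < 20)
    warning("fewer than 20 permutations: quantile estimate is unstable")
  y <- trait[accessions(g)]
  if (anyNA(y)) {
    keep <- which(!is.na(y))
    g <- GenotypeMatrix(g@dosages[keep, , drop = FALSE], g@variants)
    if (!is.null(kinship)) kinship <- unclass(kinship)[keep, keep]
    y <- y[keep]
  }
  X <- g@dosages
  set.seed(seed)
  P <- vapply(seq_len(n_permutations), function(i) sample(y),
              numeric(length(y)))
  if (model == "GLM") {
    W <- .covariates(pca, rownames(X), n_pcs)
    res <- .scanOls(P, X, W)
    minima <- apply(res$p, 2, min)
  } else {
    if (is.null(kinship)) stop("MLM permutation threshold needs a kinship")
    setup <- .mlmSetup(g, kinship, pca, n_pcs)
    ## lean path: per permutation only the genome-wide minimum p is
    ## needed, computed from weighted sufficient statistics without
    ## re-materialising the rotated SNP matrix.
    Xs2 <- setup$Xs^2
    n <- nrow(Xs2)
    Ps <- crossprod(setup$U, P)
    minima <- vapply(seq_len(n_permutations), function(i) {
      ys <- Ps[, i]
      lam <- .remlRatio(ys, setup$Ws, setup$d)
      w <- 1 / (lam * setup$d + 1)
      sw <- sqrt(w)
      Wsw <- setup$Ws * sw
      qrW <- qr(Wsw)
      q <- qrW$rank
      Qw <- qr.Q(qrW)[, seq_len(q), drop = FALSE]
      ysw <- ys * sw
      yr <- ysw - Qw %*% crossprod(Qw, ysw)
      B <- crossprod(Qw * sw, setup$Xs)            # q x M
      sxy <- as.vector(crossprod(setup$Xs, sw * yr))
      sxx <- as.vector(crossprod(Xs2, w)) - colSums(B^2)
      ok <- sxx > 1e-10 * n
      syy <- sum(yr^2)
      df <- n - q - 1
      t2 <- sxy[ok]^2 / sxx[ok] / pmax(syy - sxy[ok]^2 / sxx[ok], 0) * df
      min(2 * pt(-sqrt(max(t2)), df))
    }, 0)
  }
  structure(list(method = "permutation", model = model, alpha = alpha,
                 n_permutations = n_permutations, seed = seed,
                 cutoff = as.numeric(quantile(minima, alpha, type = 1)),
                 minima = minima),
            class = "SignificanceThreshold")
}

#' Bonferroni genome-wide significance threshold
#'
#' @param g a [GenotypeMatrix-class] (supplies the number of tests).
#' @param alpha family-wise level (default 0.05).
#' @return A `SignificanceThreshold` with cutoff alpha / n_SNPs.
#' @export
bonferroniThreshold <- function(g, alpha = 0.05) {
  structure(list(method = "bonferroni", model = NA_character_,
                 alpha = alpha, n_permutations = NA_integer_,
                 seed = NA_integer_,
                 cutoff = alpha / ncol(g@dosages), minima = NULL),
            class = "SignificanceThreshold")
}

#' @export
print.SignificanceThreshold <- function(x, ...) {
  cat("SignificanceThreshold:", x$method,
      if (!is.na(x$model)) paste0("(", x$model, ")") else "",
      " alpha =", x$alpha, " cutoff =", format(x$cutoff), "\n")
  invisible(x)
}

.cutoffFun <- function(threshold) {
  if (inherits(threshold, "SignificanceThreshold"))
    return(function(trait) threshold$cutoff)
  if (is.numeric(threshold) && !is.null(names(threshold)))
    return(function(trait) unname(threshold[trait]))
  if (is.numeric(threshold) && length(threshold) == 1)
    return(function(trait) threshold)
  stop("unsupported threshold specification")
}

#' Trait-SNP pairs significant in several association models
#'
#' @param tables named list of `AssociationTable` data.frames, one per
#'   model.
#' @param thresholds named list (same names) of per-model thresholds:
#'   a `SignificanceThreshold`, a scalar cutoff, or a named per-trait
#'   cutoff vector.
#' @param min_models minimum number of models in which a (trait, SNP)
#'   pair must be significant (default 2).
#' @return data.frame: `trait`, `snp`, `n_models`, `models`.
#' @export
coIdentified <- function(tables, thresholds, min_models = 2) {
  if (length(tables) < min_models)
    stop("need at least min_models association tables")
  hits <- lapply(names(tables), function(m) {
    tab <- tables[[m]]
    cf <- .cutoffFun(thresholds[[m]])
    cut <- vapply(tab$trait, cf, 0)
    keep <- !is.na(tab$p) & tab$p < cut
    if (!any(keep)) return(NULL)
    data.frame(trait = tab$trait[keep], snp = tab$snp[keep], model = m,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits))
    return(data.frame(trait = character(), snp = character(),
                      n_models = integer(), models = character(),
                      stringsAsFactors = FALSE))
  key <- paste(hits$trait, hits$snp, sep = "\r")
  agg <- tapply(hits$model, key, function(m) sort(unique(m)))
  nm <- lengths(agg)
  keep <- nm >= min_models
  ks <- strsplit(names(agg)[keep], "\r", fixed = TRUE)
  data.frame(trait = vapply(ks, `[`, "", 1), snp = vapply(ks, `[`, "", 2),
             n_models = as.integer(nm[keep]),
             models = vapply(agg[keep], paste, "", collapse = "+"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quantitative trait transcript (QTT) regression scan
#'
#' Per gene, ordinary least squares of the metabolite on intercept,
#' log2(expression + 1) and the first `n_pcs` genotype principal
#' components; gene-coefficient p-values below `alpha` are reported.
#' Constant-expression genes are skipped (listed in the `skipped`
#' attribute).
#'
#' @param metabolite named numeric vector (accession-indexed, NA
#'   dropped).
#' @param e an [ExpressionMatrix-class].
#' @param pca a `PcaResult` (genotype PCA).
#' @param n_pcs number of PC covariates (default 3).
#' @param alpha reporting cutoff on the gene coefficient p (default
#'   0.01).
#' @param met_name label stored in the output.
#' @return data.frame (`QttTable`): `metabolite`, `gene`, `coef`, `se`,
#'   `p`, `n_covariates`; attribute `skipped` lists constant genes.
#' @export
qttScan <- function(metabolite, e, pca, n_pcs = 3, alpha = 0.01,
                    met_name = "metabolite") {
  V <- .log2p1(e@values)
  y <- metabolite[rownames(V)]
  keep <- !is.na(y)
  V <- V[keep, , drop = FALSE]
  W <- .covariates(pca, rownames(V), n_pcs)
  sds <- apply(V, 2, sd)
  const <- sds == 0
  res <- .scanOls(matrix(y[keep]), V, W)
  sig <- which(!const & res$p[, 1] < alpha)
  out <- data.frame(metabolite = rep(met_name, length(sig)),
                    gene = colnames(V)[sig],
                    coef = res$effect[sig, 1], se = res$se[sig, 1],
                    p = res$p[sig, 1],
                    n_covariates = rep(ncol(W) - 1L, length(sig)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- colnames(V)[const]
  attr(out, "alpha") <- alpha
  out
}

## distance from a SNP to a gene interval: 0 inside, else bp gap to the
## nearer boundary; NA when chromosomes differ or the gene is unplaced.
.snpGeneDistance <- function(snp_chrom, snp_pos, gene_chrom, gene_start,
                             gene_end) {
  ifelse(is.na(gene_chrom) | snp_chrom != gene_chrom, NA_real_,
         pmax(gene_start - snp_pos, snp_pos - gene_end, 0))
}

#' Expression-as-trait eQTL scan with cis/trans classification
#'
#' Every gene's (log2(x+1)-transformed) expression is scanned as a trait
#' under each model in `models`; an eQTL is a (gene, SNP) pair
#' significant in at least `min_models` of them. A pair is `cis` when
#' the SNP lies on the gene's chromosome strictly less than `cis_max` bp
#' from the gene interval (0 bp inside the gene), `trans` otherwise, and
#' `unassigned` when the gene is unplaced.
#'
#' @param e an [ExpressionMatrix-class].
#' @param g a complete [GenotypeMatrix-class].
#' @param kinship `KinshipMatrix`, required when "MLM" is scanned.
#' @param pca a `PcaResult`.
#' @param models character subset of c("GLM", "MLM").
#' @param threshold list: `method` = "bonferroni" or "permutation",
#'   `alpha`, and for permutation `n_permutations` and `seed` (per-gene
#'   sub-seeds are derived deterministically).
#' @param cis_max cis distance bound in bp, strict (default 100000).
#' @param min_models models required for co-identification (default all
#'   scanned models).
#' @param n_pcs_glm,n_pcs_mlm PC covariate counts (defaults 5 and 3).
#' @param log_transform scan log2(x+1) expression (default TRUE).
#' @return data.frame (`EqtlTable`): `gene`, `snp`, `snp_chrom`,
#'   `snp_pos`, `class` (cis/trans/unassigned), `distance`, `models`,
#'   `n_models`.
#' @export
eqtlScan <- function(e, g, kinship = NULL, pca,
                     models = c("GLM", "MLM"),
                     threshold = list(method = "bonferroni", alpha = 0.05),
                     cis_max = 1e5, min_models = length(models),
                     n_pcs_glm = 5, n_pcs_mlm = 3, log_transform = TRUE) {
  models <- match.arg(models, c("GLM", "MLM"), several.ok = TRUE)
  X <- g@dosages
  if (anyNA(X)) stop("genotype matrix must be complete; run imputeMean()")
  Y <- if (log_transform) .log2p1(e@values) else e@values
  Y <- Y[rownames(X), , drop = FALSE]
  genes <- e@genes
  M <- ncol(X)
  perm <- identical(threshold$method, "permutation")
  if (!perm && !identical(threshold$method, "bonferroni"))
    stop("threshold$method must be 'bonferroni' or 'permutation'")
  baseSeed <- if (is.null(threshold$seed)) 1 else threshold$seed
  nPerm <- if (is.null(threshold$n_permutations)) 100 else
    threshold$n_permutations
  alpha <- if (is.null(threshold$alpha)) 0.05 else threshold$alpha

  sigTabs <- list()
  cutTabs <- list()
  for (mod in models) {
    nP <- if (mod == "GLM") n_pcs_glm else n_pcs_mlm
    if (mod == "MLM") {
      if (is.null(kinship)) stop("MLM eQTL scan needs a kinship matrix")
      setup <- .mlmSetup(g, kinship, pca, nP)
    } else {
      W <- .covariates(pca, rownames(X), nP)
    }
    rows <- list()
    cuts <- numeric(ncol(Y))
    for (j in seq_len(ncol(Y))) {
      yj <- Y[, j]
      if (sd(yj) == 0) { cuts[j] <- NA; next }
      pj <- if (mod == "GLM") .scanOls(matrix(yj), X, W)$p[, 1]
            else .mlmScanCore(setup, yj)$p[, 1]
      cut <- if (!perm) alpha / M else
        permutationThreshold(setNames(yj, rownames(X)), g, model = mod,
                             n_permutations = nPerm, alpha = alpha,
                             seed = .subSeed(baseSeed,
                                             j + ncol(Y) * (mod == "MLM")),
                             pca = pca, n_pcs = nP,
                             kinship = kinship)$cutoff
      cuts[j] <- cut
      hit <- which(pj < cut)
      if (length(hit))
        rows[[length(rows) + 1L]] <-
          data.frame(trait = colnames(Y)[j], snp = g@variants$id[hit],
                     model = mod, p = pj[hit], stringsAsFactors = FALSE)
    }
    sigTabs[[mod]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(trait = character(), snp = character(),
                 model = character(), p = numeric())
    cutTabs[[mod]] <- setNames(cuts, colnames(Y))
  }
  co <- coIdentified(sigTabs, lapply(sigTabs, function(x) Inf),
                     min_models = min_models)
  ## thresholds were already applied per model; coIdentified with Inf
  ## cutoffs just intersects the stored significant sets.
  gi <- match(co$trait, genes$id)
  si <- match(co$snp, g@variants$id)
  dist <- .snpGeneDistance(g@variants$chrom[si], g@variants$pos[si],
                           genes$chrom[gi], genes$start[gi], genes$end[gi])
  cls <- ifelse(is.na(genes$chrom[gi]), "unassigned",
         ifelse(!is.na(dist) & dist < cis_max, "cis", "trans"))
  out <- data.frame(gene = co$trait, snp = co$snp,
                    snp_chrom = g@variants$chrom[si],
                    snp_pos = g@variants$pos[si],
                    class = cls, distance = dist,
                    models = co$models, n_models = co$n_models,
                    stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- cutTabs
  attr(out, "cis_max") <- cis_max
  class(out) <- c("EqtlTable", "data.frame")
  out
}
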