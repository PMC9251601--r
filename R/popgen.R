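## Population-genetics layer: variant filtering, LD pruning, mean
## imputation, genotype PCA, VanRaden kinship and two-population Fst.

#' Filter variants on minor allele frequency and missingness
#'
#' Retains SNPs with minor-allele frequency >= `maf_min` (computed on
#' non-missing dosages) and missing fraction <= `max_missing`
#' (plink-style `maf 0.05, geno 0.3` semantics: keep at the boundary).
#' SNP order is preserved.
#'
#' @param g a [GenotypeMatrix-class].
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param max_missing maximum per-SNP missing fraction (default 0.3).
#' @return A filtered [GenotypeMatrix-class].
#' @export
filterVariants <- function(g, maf_min = 0.05, max_missing = 0.3) {
  d <- g@dosages
  if (!ncol(d)) stop("empty genotype matrix")
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(d))
  keep <- !is.na(maf) & maf >= maf_min & miss <= max_missing
  if (!any(keep)) warning("all SNPs removed by variant filters")
  .subsetSnps(g, which(keep))
}

#' Replace missing dosages by the per-SNP mean
#'
#' SNPs with all values missing are removed with a warning.
#'
#' @param g a [GenotypeMatrix-class].
#' @return A complete [GenotypeMatrix-class] (no `NA`); note the filled
#'   values are fractional means, downstream code treats dosages as
#'   numeric.
#' @export
imputeMean <- function(g) {
  d <- g@dosages
  allMiss <- colSums(!is.na(d)) == 0
  if (any(allMiss)) {
    warning(sum(allMiss), " SNP(s) with all values missing removed")
    g <- .subsetSnps(g, which(!allMiss))
    d <- g@dosages
  }
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d))
    d[idx] <- mu[(idx - 1) %/% nrow(d) + 1]
  }
  g@dosages <- d
  g
}

## squared Pearson correlation matrix of dosage columns; undefined
## (zero-variance) pairs count as 0.
.r2mat <- function(X) {
  r <- suppressWarnings(cor(X))
  r[!is.finite(r)] <- 0
  r^2
}

## one sliding pass over a chromosome's kept SNPs; returns updated keep set
.prunePass <- function(X, maf, pos, kept, window, step, r2max) {
  i <- 1L
  repeat {
    if (i > length(kept)) break
    win <- kept[i:min(i + window - 1L, length(kept))]
    if (length(win) >= 2) {
      r2 <- .r2mat(X[, win, drop = FALSE])
      diag(r2) <- 0
      alive <- rep(TRUE, length(win))
      repeat {
        r2a <- r2
        r2a[!alive, ] <- 0
        r2a[, !alive] <- 0
        mx <- which(r2a > r2max, arr.ind = TRUE)
        if (!nrow(mx)) break
        mx <- mx[mx[, 1] < mx[, 2], , drop = FALSE]
        pair <- mx[order(mx[, 1], mx[, 2]), , drop = FALSE][1, ]
        a <- win[pair[1]]; b <- win[pair[2]]
        drop <- if (maf[a] < maf[b]) pair[1]
                else if (maf[b] < maf[a]) pair[2]
                else if (pos[a] > pos[b]) pair[1] else pair[2]
        alive[drop] <- FALSE
      }
      kept <- setdiff(kept, win[!alive])
    }
    i <- i + step
  }
  kept
}

#' Sliding-window LD pruning
#'
#' Greedy windowed pruning in the style of plink `--indep-pairwise`:
#' within each window of `window_snps` consecutive retained SNPs on a
#' chromosome, while any pair has squared Pearson dosage correlation
#' > `r2_max`, the member with the lower MAF is removed (ties: the later
#' position); the window then slides by `step_snps`. Passes repeat until
#' stable, and a final single-step sweep guarantees that no retained pair
#' within any window of `window_snps` consecutive retained SNPs exceeds
#' `r2_max`. Missing dosages are mean-imputed for the correlation
#' computation only.
#'
#' @param g a [GenotypeMatrix-class].
#' @param window_snps window size in SNPs (default 50).
#' @param step_snps slide step in SNPs (default 10).
#' @param r2_max maximum allowed squared correlation (default 0.2).
#' @return Character vector of retained SNP IDs (in map order).
#' @export
ldPrune <- function(g, window_snps = 50, step_snps = 10, r2_max = 0.2) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  if (step_snps < 1) stop("step_snps must be >= 1")
  gc <- imputeMean(g)
  X <- gc@dosages
  v <- gc@variants
  p <- colMeans(X) / 2
  maf <- pmin(p, 1 - p)
  keptAll <- character(0)
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    kept <- idx
    for (st in c(step_snps, 1L)) { # main pass, then step-1 cleanup
      repeat {
        newKept <- .prunePass(X, maf, v$pos, kept, window_snps, st, r2_max)
        if (length(newKept) == length(kept)) break
        kept <- newKept
      }
    }
    keptAll <- c(keptAll, v$id[kept])
  }
  keptAll
}

#' Principal component analysis of a genotype matrix
#'
#' Columns are standardised to centre 2*p and scale sqrt(2*p*(1-p))
#' (monomorphic columns dropped); the top-k components come from the
#' singular value decomposition of the standardised matrix. The sign of
#' each component is fixed so its largest-magnitude loading is positive.
#'
#' @param g a complete [GenotypeMatrix-class] (impute first).
#' @param k number of components.
#' @return list of class `PcaResult` with `scores` (accessions x k),
#'   `loadings` (SNPs x k, rownames = SNP ids of polymorphic SNPs) and
#'   `explained_variance` (k fractions, non-increasing).
#' @export
genotypePca <- function(g, k = 5) {
  X <- g@dosages
  if (anyNA(X)) stop("genotype matrix must be complete; run imputeMean()")
  if (k >= nrow(X)) stop("k must be smaller than the number of accessions")
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  Xs <- sweep(X[, keep, drop = FALSE], 2, 2 * p[keep])
  Xs <- sweep(Xs, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  sv <- svd(Xs, nu = k, nv = k)
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(k)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(X)[keep], paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = sv$d[seq_len(k)]^2 / sum(sv$d^2)),
            class = "PcaResult")
}

#' VanRaden genomic relationship (kinship) matrix
#'
#' K = Z Z' / (2 * sum(p*(1-p))) with Z the column-centred dosage matrix
#' (centre 2*p). Symmetric and positive semi-definite by construction.
#'
#' @param g a complete [GenotypeMatrix-class].
#' @return accessions x accessions numeric matrix of class `KinshipMatrix`.
#' @export
kinshipMatrix <- function(g) {
  X <- g@dosages
  if (anyNA(X)) stop("genotype matrix must be complete; run imputeMean()")
  p <- colMeans(X) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("no polymorphic SNPs: kinship undefined")
  Z <- sweep(X, 2, 2 * p)
  K <- tcrossprod(Z) / denom
  structure((K + t(K)) / 2, class = c("KinshipMatrix", "matrix"))
}

## Weir-Cockerham two-population variance components for one SNP.
## Inputs: dosage vectors (non-missing) of the two groups.
.wcComponents <- function(da, db) {
  n1 <- length(da); n2 <- length(db)
  if (n1 == 0 || n2 == 0) return(c(a = NA, b = NA, c = NA))
  r <- 2
  p1 <- mean(da) / 2; p2 <- mean(db) / 2
  h1 <- mean(da == 1); h2 <- mean(db == 1)
  nb <- (n1 + n2) / r
  nc <- (r * nb - (n1^2 + n2^2) / (r * nb)) / (r - 1)
  pb <- (n1 * p1 + n2 * p2) / (r * nb)
  s2 <- (n1 * (p1 - pb)^2 + n2 * (p2 - pb)^2) / ((r - 1) * nb)
  hb <- (n1 * h1 + n2 * h2) / (r * nb)
  if (pb <= 0 || pb >= 1) return(c(a = NA, b = NA, c = NA)) # monomorphic
  a <- nb / nc * (s2 - 1 / (nb - 1) *
                    (pb * (1 - pb) - s2 * (r - 1) / r - hb / 4))
  b <- nb / (nb - 1) *
    (pb * (1 - pb) - s2 * (r - 1) / r - hb * (2 * nb - 1) / (4 * nb))
  c(a = a, b = b, c = hb / 2)
}

#' Per-SNP two-population Fst
#'
#' Weir-Cockerham theta-hat per SNP from the genotypes of two groups
#' (default), or the Hudson estimator for cross-checking. SNPs
#' monomorphic across both groups (or with a group lacking non-missing
#' calls) are flagged undefined (`NA` estimate), not dropped.
#'
#' @param g a [GenotypeMatrix-class].
#' @param group_a,group_b disjoint non-empty accession ID vectors.
#' @param method "wc" (Weir-Cockerham, default) or "hudson".
#' @return data.frame of class `FstResult`: `snp`, `chrom`, `pos`, `fst`,
#'   variance components `a`, `b`, `c` (WC only), group sample sizes
#'   `n_a`, `n_b` (non-missing genotypes), and `defined`.
#' @export
fstScan <- function(g, group_a, group_b, method = c("wc", "hudson")) {
  method <- match.arg(method)
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  d <- g@dosages
  A <- d[group_a, , drop = FALSE]
  B <- d[group_b, , drop = FALSE]
  M <- ncol(d)
  out <- data.frame(snp = g@variants$id, chrom = g@variants$chrom,
                    pos = g@variants$pos, fst = NA_real_,
                    a = NA_real_, b = NA_real_, c = NA_real_,
                    n_a = colSums(!is.na(A)), n_b = colSums(!is.na(B)),
                    defined = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(M)) {
    da <- A[, j][!is.na(A[, j])]
    db <- B[, j][!is.na(B[, j])]
    if (!length(da) || !length(db)) next
    if (method == "wc") {
      cmp <- .wcComponents(da, db)
      if (anyNA(cmp)) next
      out$a[j] <- cmp["a"]; out$b[j] <- cmp["b"]; out$c[j] <- cmp["c"]
      tot <- sum(cmp)
      if (tot != 0) {
        out$fst[j] <- cmp["a"] / tot
        out$defined[j] <- TRUE
      }
    } else {
      n1 <- 2 * length(da); n2 <- 2 * length(db)
      p1 <- sum(da) / n1; p2 <- sum(db) / n2
      if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) next
      if (n1 < 2 || n2 < 2) next
      num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
        p2 * (1 - p2) / (n2 - 1)
      den <- p1 * (1 - p2) + p2 * (1 - p1)
      if (den > 0) {
        out$fst[j] <- num / den
        out$defined[j] <- TRUE
      }
    }
  }
  class(out) <- c("FstResult", "data.frame")
  out
}
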