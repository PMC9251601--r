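## Expression- and metabolite-layer classifications and two-group tests:
## low-expression filtering, presence and abundance classes, ePAV, DEG
## and DAS calling.

#' Remove genes with low average expression
#'
#' Genes whose mean abundance across accessions is below `mean_min`
#' (default 1 FPKM) are removed; a gene with mean exactly at the
#' threshold is retained.
#'
#' @param e an [ExpressionMatrix-class] (accession level).
#' @param mean_min minimum mean abundance (default 1).
#' @return A filtered [ExpressionMatrix-class].
#' @export
filterLowExpression <- function(e, mean_min = 1) {
  keep <- colMeans(e@values) >= mean_min
  .subsetGenes(e, which(keep))
}

#' Classify genes by expression presence across accessions
#'
#' A gene is "present" in an accession when its value is strictly greater
#' than `presence_min`. Classes: `core` = present in all n accessions;
#' `near_core` = present in strictly more than floor(`near_core_frac` * n)
#' accessions (but not all); `accession_specific` = present in exactly 1;
#' `silent` = present in none; `rare` = present in fewer than
#' ceiling(`rare_frac` * n) accessions (but in at least 2);
#' `intermediate` = the remainder. For n = 134 at the default fractions
#' the integer cutoffs are "present in > 127" (near-core) and
#' "present in < 7" (rare).
#'
#' @param e an [ExpressionMatrix-class].
#' @param presence_min presence threshold, strict (default 0).
#' @param near_core_frac near-core fraction (default 0.95).
#' @param rare_frac rare fraction (default 0.05).
#' @return list of class `PresenceProfile`: `profile` data.frame
#'   (`gene`, `n_present`, `class`), `counts` per class,
#'   `near_core_cutoff` (present in strictly more than this),
#'   `rare_cutoff` (present in strictly fewer than this), `n_accessions`.
#' @export
classifyPresence <- function(e, presence_min = 0, near_core_frac = 0.95,
                             rare_frac = 0.05) {
  v <- e@values
  n <- nrow(v)
  npres <- colSums(v > presence_min)
  hi <- floor(near_core_frac * n)
  lo <- ceiling(rare_frac * n)
  cls <- ifelse(npres == 0, "silent",
         ifelse(npres == 1, "accession_specific",
         ifelse(npres == n, "core",
         ifelse(npres > hi, "near_core",
         ifelse(npres < lo, "rare", "intermediate")))))
  lev <- c("core", "near_core", "intermediate", "rare",
           "accession_specific", "silent")
  structure(list(
    profile = data.frame(gene = colnames(v), n_present = as.integer(npres),
                         class = factor(cls, levels = lev),
                         stringsAsFactors = FALSE),
    counts = table(factor(cls, levels = lev)),
    near_core_cutoff = hi, rare_cutoff = lo, n_accessions = n),
    class = "PresenceProfile")
}

#' Classify expression abundance per accession (HEG/MEG/LEG)
#'
#' Per accession, a gene is highly expressed (HEG) at abundance >=
#' `high_min`, medium (MEG) at `mid_min` <= abundance < `high_min`, and
#' low (LEG) below `mid_min`. "Shared" sets are genes with the same
#' label in every accession.
#'
#' @param e an [ExpressionMatrix-class].
#' @param high_min HEG threshold (default 20).
#' @param mid_min MEG threshold (default 5).
#' @return list with `labels` (accessions x genes character matrix) and
#'   `shared` (list of gene-ID vectors `HEG`, `MEG`, `LEG`).
#' @export
classifyAbundance <- function(e, high_min = 20, mid_min = 5) {
  v <- e@values
  lab <- matrix("LEG", nrow(v), ncol(v), dimnames = dimnames(v))
  lab[v >= mid_min] <- "MEG"
  lab[v >= high_min] <- "HEG"
  shared <- lapply(c(HEG = "HEG", MEG = "MEG", LEG = "LEG"), function(cl)
    colnames(v)[colSums(lab == cl) == nrow(v)])
  list(labels = lab, shared = shared)
}

.pureValues <- function(mat, design) {
  pg <- pureGroups(design)
  if (length(pg$A) < 1 || length(pg$B) < 1)
    stop("both pure groups must be non-empty")
  list(A = mat[intersect(pg$A, rownames(mat)), , drop = FALSE],
       B = mat[intersect(pg$B, rownames(mat)), , drop = FALSE])
}

#' Call expression presence/absence variation (ePAV) between pure groups
#'
#' A gene is an A-ePAV when it is present (value > `presence_min`) in at
#' least `min_carrier_frac` of group-A accessions and has zero presence
#' in every group-B accession; symmetrically for B-ePAV. The default
#' `min_carrier_frac = 1` is the strict reading of "expressed only in"
#' one pure group.
#'
#' @param e an [ExpressionMatrix-class].
#' @param design a [GroupDesign-class] with two pure groups.
#' @param presence_min strict presence threshold (default 0).
#' @param min_carrier_frac required presence fraction in the carrier
#'   group (default 1).
#' @return list with character vectors `A` and `B` of ePAV gene IDs and
#'   the thresholds used.
#' @export
callEpav <- function(e, design, presence_min = 0, min_carrier_frac = 1) {
  pv <- .pureValues(e@values, design)
  presA <- colMeans(pv$A > presence_min)
  presB <- colMeans(pv$B > presence_min)
  gidn <- colnames(e@values)
  list(A = gidn[presA >= min_carrier_frac & presB == 0],
       B = gidn[presB >= min_carrier_frac & presA == 0],
       presence_min = presence_min, min_carrier_frac = min_carrier_frac)
}

## Welch two-sample t-test on the columns of two matrices; returns
## data.frame with means, lfc (A - B) and p. Columns constant in both
## groups get p = 1 if the means are equal, else p ~ 0.
.welchColumns <- function(A, B) {
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2, var); vB <- apply(B, 2, var)
  nA <- nrow(A); nB <- nrow(B)
  s2 <- vA / nA + vB / nB
  tt <- (mA - mB) / sqrt(s2)
  df <- s2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * pt(-abs(tt), df)
  zero <- s2 == 0 | !is.finite(df)
  p[zero] <- ifelse(abs(mA[zero] - mB[zero]) < 1e-12, 1, .Machine$double.xmin)
  p <- pmax(p, .Machine$double.xmin)
  data.frame(mean_a = mA, mean_b = mB, stat = tt, p = p)
}

#' Call differentially expressed genes between the pure groups
#'
#' Log2 fold change is the difference of group means on the
#' log2(value + 1) scale; significance is a two-sided unequal-variance
#' (Welch) t-test on the same scale. A gene is called when
#' |lfc| >= `lfc_min` and the selected (raw or BH-adjusted) p < `alpha`.
#'
#' @param e an [ExpressionMatrix-class].
#' @param design a [GroupDesign-class]; each pure group needs >= 2
#'   accessions.
#' @param lfc_min minimum |log2 fold change| (default 2).
#' @param alpha significance level (default 0.01).
#' @param adjust "none" (raw p, default) or "BH"
#'   (Benjamini-Hochberg-adjusted p gates the call).
#' @return data.frame of class `DiffTable`: `feature`, `mean_a`,
#'   `mean_b` (log2-scale means), `lfc`, `p`, `padj`, `called`; the
#'   thresholds used are stored as attributes.
#' @export
callDeg <- function(e, design, lfc_min = 2, alpha = 0.01,
                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  pv <- .pureValues(.log2p1(e@values), design)
  if (nrow(pv$A) < 2 || nrow(pv$B) < 2)
    stop("each pure group needs at least 2 accessions")
  w <- .welchColumns(pv$A, pv$B)
  out <- data.frame(feature = colnames(e@values),
                    mean_a = w$mean_a, mean_b = w$mean_b,
                    lfc = w$mean_a - w$mean_b, p = w$p,
                    padj = p.adjust(w$p, "BH"),
                    stringsAsFactors = FALSE)
  psel <- if (adjust == "BH") out$padj else out$p
  out$called <- abs(out$lfc) >= lfc_min & psel < alpha
  attr(out, "thresholds") <- list(lfc_min = lfc_min, alpha = alpha,
                                  adjust = adjust)
  class(out) <- c("DiffTable", "data.frame")
  out
}

#' Call differentially accumulated metabolite signatures (DAS)
#'
#' A signature is eligible when it is detected (non-missing and > 0) in
#' strictly more than `min_present` accessions overall. For eligible
#' signatures the fold change is the ratio of group means of the raw
#' abundances (A / B, detected entries only) and significance is a
#' two-sided Student-style two-sample t-test on raw abundances. Call =
#' eligible AND (fc > `fc_hi` OR fc < `fc_lo`) AND p < `alpha`. A zero
#' group-B mean gives an infinite fold change, still callable through
#' the `fc_hi` rule.
#'
#' @param m a [MetaboliteMatrix-class].
#' @param design a [GroupDesign-class].
#' @param min_present eligibility count, strict (default 8).
#' @param fc_hi,fc_lo fold-change gates (defaults 2 and 0.5).
#' @param alpha significance level (default 0.01).
#' @return data.frame of class `DiffTable`: `feature`, `n_detected`,
#'   `eligible`, `mean_a`, `mean_b`, `fc`, `p`, `padj`, `called`.
#' @export
callDas <- function(m, design, min_present = 8, fc_hi = 2, fc_lo = 0.5,
                    alpha = 0.01) {
  v <- m@values
  pv <- .pureValues(v, design)
  nDet <- colSums(!is.na(v) & v > 0)
  K <- ncol(v)
  mA <- mB <- fc <- p <- rep(NA_real_, K)
  for (j in seq_len(K)) {
    a <- pv$A[, j][!is.na(pv$A[, j])]
    b <- pv$B[, j][!is.na(pv$B[, j])]
    if (length(a) < 2 || length(b) < 2) next
    mA[j] <- mean(a); mB[j] <- mean(b)
    fc[j] <- if (mB[j] == 0) Inf else mA[j] / mB[j]
    if (var(a) == 0 && var(b) == 0) {
      p[j] <- if (abs(mA[j] - mB[j]) < 1e-12) 1 else .Machine$double.xmin
    } else {
      p[j] <- t.test(a, b, var.equal = TRUE)$p.value
    }
  }
  p <- pmax(p, .Machine$double.xmin)
  out <- data.frame(feature = colnames(v), n_detected = as.integer(nDet),
                    eligible = nDet > min_present,
                    mean_a = mA, mean_b = mB, fc = fc, p = p,
                    padj = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out$called <- out$eligible & !is.na(out$fc) & !is.na(out$p) &
    (out$fc > fc_hi | out$fc < fc_lo) & out$p < alpha
  attr(out, "thresholds") <- list(min_present = min_present, fc_hi = fc_hi,
                                  fc_lo = fc_lo, alpha = alpha)
  class(out) <- c("DiffTable", "data.frame")
  out
}
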