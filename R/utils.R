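## Internal numerical helpers shared by the association scans.

.log2p1 <- function(x) log2(x + 1)

## Orthonormal basis of the column space of W (drops collinear columns).
.qbasis <- function(W) {
  qrW <- qr(W)
  qr.Q(qrW)[, seq_len(qrW$rank), drop = FALSE]
}

## Vectorised per-predictor OLS via Frisch-Waugh-Lovell: regress each
## column of Y on [W, X_j] and test the X_j coefficient. Y is n x T,
## X is n x M, W is n x q (full column set, intercept included).
## Returns M x T matrices of effects, SEs and two-sided t-test p-values.
## Predictors with (residual) variance ~0 are degenerate: effect 0,
## SE Inf, p 1.
.scanOls <- function(Y, X, W) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(X)
  Q <- .qbasis(W)
  q <- ncol(Q)
  df <- n - q - 1
  if (df < 1) stop("not enough observations for the covariate set")
  Xr <- X - Q %*% crossprod(Q, X)
  Yr <- Y - Q %*% crossprod(Q, Y)
  sxx <- colSums(Xr^2)
  ok <- sxx > 1e-10 * n
  sxx[!ok] <- 1 # placeholder, overwritten below
  sxy <- crossprod(Xr, Yr)                       # M x T
  syy <- colSums(Yr^2)                           # T
  beta <- sxy / sxx
  rss <- pmax(rep(syy, each = nrow(beta)) - beta * sxy, 0)
  dim(rss) <- dim(beta)
  se <- sqrt(rss / df / sxx)
  tt <- beta / se
  p <- 2 * pt(-abs(tt), df)
  p <- pmax(p, .Machine$double.xmin)
  dim(p) <- dim(beta)
  beta[!ok, ] <- 0
  se[!ok, ] <- Inf
  p[!ok, ] <- 1
  list(effect = beta, se = se, p = p, df = df, degenerate = !ok)
}

## Genomic-control inflation factor from a vector of p-values.
#' Genomic inflation factor
#'
#' Median-based genomic-control lambda: the median association chi-squared
#' statistic divided by the null median (0.4549...). Values near 1 indicate
#' a well-calibrated scan; values > 1 indicate confounding inflation.
#'
#' @param p numeric vector of p-values.
#' @return scalar lambda.
#' @export
genomicInflation <- function(p) {
  p <- p[is.finite(p) & p > 0 & p <= 1]
  qchisq(median(p), df = 1, lower.tail = FALSE) / qchisq(0.5, df = 1)
}

## Deterministic seed stream: derive sub-seeds from a master seed so that
## independent stages do not share RNG state. Kept below 2^31.
.subSeed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * k) %% 2147483647
}
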