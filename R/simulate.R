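#' Configuration for the synthetic multi-omics generator
#'
#' Defines the study conditions emulated by [simulatePopulation()]: a
#' two-subpopulation (plus admixed pool) genotype structure generated by
#' the Balding-Nichols construction, log-normal gene expression with
#' planted ePAV / DEG / cis- and trans-eQTL structure, and metabolites
#' generated as a Gaussian linear model on the log2-abundance scale from
#' linked gene expressions and SNP dosages. Defaults mirror the
#' population analysed downstream: 134 accessions with pure groups of 12
#' (A) and 19 (B), the remainder admixed.
#'
#' @param n_accessions total accessions.
#' @param n_pure_a,n_pure_b sizes of the two pure groups; the remaining
#'   accessions are admixed ("derived") with a per-accession admixture
#'   proportion drawn Uniform(0,1).
#' @param fst_divergence Balding-Nichols drift parameter F in (0,1).
#' @param n_chromosomes,n_snps,chrom_length genome layout (positions in bp).
#' @param n_genes,frac_unplaced_genes,frac_sparse_genes gene panel; sparse
#'   genes are stochastically expressed (exercises presence classes).
#' @param n_metabolites,n_sparse_metabolites metabolite signatures; sparse
#'   signatures are detected in few accessions (exercises the DAS
#'   eligibility rule).
#' @param n_epav,n_deg,n_cis_eqtl,n_trans_eqtl,n_met_links,n_met_snp_links,n_das
#'   planted-truth counts.
#' @param deg_log2fc planted expression shift between pure groups (log2).
#' @param eqtl_beta fraction of accession-level expression variance
#'   explained by a planted eQTL.
#' @param met_link_frac fraction of log2-metabolite variance explained by
#'   a planted gene/SNP link.
#' @param das_log2fc planted metabolite group shift (log2).
#' @param sd_biological,sd_replicate,sd_metabolite noise SDs on the log2
#'   scale (per accession, per replicate, per metabolite).
#' @param n_replicates biological replicates per accession (averaged).
#' @param geno_missing_frac,met_missing_frac missing-at-random rates.
#' @param cis_genes optional explicit gene IDs to receive planted
#'   cis-eQTLs (must be placed genes).
#' @param seed integer RNG seed.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(n_accessions = 134, n_pure_a = 12, n_pure_b = 19,
                      fst_divergence = 0.15, n_chromosomes = 5,
                      n_snps = 10000, chrom_length = 2e7,
                      n_genes = 2000, frac_unplaced_genes = 0.05,
                      frac_sparse_genes = 0.10,
                      n_metabolites = 100, n_sparse_metabolites = 5,
                      n_epav = 30, n_deg = 30, n_cis_eqtl = 20,
                      n_trans_eqtl = 10, n_met_links = 15,
                      n_met_snp_links = 5, n_das = 10,
                      deg_log2fc = 3, eqtl_beta = 0.3,
                      met_link_frac = 0.5, das_log2fc = 2.5,
                      sd_biological = 0.6, sd_replicate = 0.5,
                      sd_metabolite = 1, n_replicates = 3,
                      geno_missing_frac = 0.02, met_missing_frac = 0.05,
                      cis_genes = NULL, seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_accessions", "n_pure_a", "n_pure_b", "n_chromosomes",
              "n_snps", "n_genes", "n_metabolites", "n_replicates")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop("SimConfig: ", nm, " must be positive")
  fracs <- c("fst_divergence", "frac_unplaced_genes", "frac_sparse_genes",
             "eqtl_beta", "met_link_frac", "geno_missing_frac",
             "met_missing_frac")
  for (nm in fracs)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("SimConfig: ", nm, " must be in [0, 1]")
  if (cfg$fst_divergence <= 0 || cfg$fst_divergence >= 1)
    stop("SimConfig: fst_divergence must be in (0, 1)")
  if (n_pure_a + n_pure_b > n_accessions)
    stop("SimConfig: pure groups exceed total accessions")
  placeable <- n_genes - round(frac_unplaced_genes * n_genes)
  if (n_epav + n_deg + n_cis_eqtl + n_trans_eqtl >
      placeable - round(frac_sparse_genes * n_genes))
    stop("SimConfig: planted gene counts exceed available placed genes")
  if (n_met_links + n_met_snp_links + n_das + n_sparse_metabolites >
      n_metabolites)
    stop("SimConfig: planted metabolite counts exceed n_metabolites")
  if (n_met_links > 0 && n_cis_eqtl == 0)
    stop("SimConfig: metabolite gene links require planted cis-eQTL genes")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a population-scale multi-omics dataset with planted truth
#'
#' Genotypes follow the Balding-Nichols construction: an ancestral allele
#' frequency p ~ Uniform(0.05, 0.95) per SNP, subpopulation frequencies
#' ~ Beta(p(1-F)/F, (1-p)(1-F)/F), pure accessions drawing dosages
#' Binomial(2, p_subpop) and admixed accessions drawing from the mixture
#' frequency a*p_A + (1-a)*p_B with a per-accession admixture proportion
#' a ~ Uniform(0,1). Expression is log-normal per gene with planted ePAV
#' (exact zeros in the non-carrier pure group), DEG (log2 shift between
#' pure groups, scaled by ancestry in admixed accessions) and eQTL
#' (beta x standardised dosage on the log2 scale) structure; replicate
#' noise is added on the log scale and replicate values averaged on the
#' abundance scale. Metabolite log2-abundances are weighted sums of
#' standardised log2 gene expression and SNP dosages plus Gaussian noise;
#' a configurable fraction of entries is masked as not detected.
#' Deterministic for a fixed seed.
#'
#' @param config a `SimConfig` from [simConfig()].
#' @return A [SyntheticDataset-class].
#' @export
simulatePopulation <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_accessions
  M <- config$n_snps
  nchr <- config$n_chromosomes

  ## ---- genome map ---------------------------------------------------------
  per <- diff(round(seq(0, M, length.out = nchr + 1)))
  chrom <- rep(paste0("chr", seq_len(nchr)), per)
  pos <- unlist(lapply(per, function(m)
    sort(sample.int(config$chrom_length, m))))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  vtab <- data.frame(id = sprintf("snp%05d", seq_len(M)), chrom = chrom,
                     pos = pos, ref = ref, alt = unname(alt),
                     stringsAsFactors = FALSE)

  ## ---- population structure ----------------------------------------------
  FF <- config$fst_divergence
  p0 <- runif(M, 0.05, 0.95)
  sh <- (1 - FF) / FF
  pA <- rbeta(M, p0 * sh, (1 - p0) * sh)
  pB <- rbeta(M, p0 * sh, (1 - p0) * sh)
  nA <- config$n_pure_a; nB <- config$n_pure_b; nD <- n - nA - nB
  acc <- sprintf("acc%03d", seq_len(n))
  groups <- setNames(c(rep("pureA", nA), rep("pureB", nB),
                       rep("derived", nD)), acc)
  admix <- runif(nD) # pureA ancestry fraction of each derived accession
  G0 <- matrix(0L, n, M, dimnames = list(acc, vtab$id))
  G0[seq_len(nA), ] <- rbinom(nA * M, 2, rep(pA, each = nA))
  G0[nA + seq_len(nB), ] <- rbinom(nB * M, 2, rep(pB, each = nB))
  if (nD > 0) {
    pd <- outer(admix, pA) + outer(1 - admix, pB)
    G0[nA + nB + seq_len(nD), ] <- rbinom(nD * M, 2, pd)
  }
  G <- G0
  if (config$geno_missing_frac > 0)
    G[runif(n * M) < config$geno_missing_frac] <- NA

  ## ---- gene panel and planted gene sets ----------------------------------
  Gn <- config$n_genes
  gid <- sprintf("g%04d", seq_len(Gn))
  nUnp <- round(config$frac_unplaced_genes * Gn)
  unplaced <- sort(sample.int(Gn, nUnp))
  gchrom <- rep(NA_character_, Gn)
  gstart <- rep(NA_integer_, Gn)
  gend <- rep(NA_integer_, Gn)
  placedIdx <- setdiff(seq_len(Gn), unplaced)
  gchrom[placedIdx] <- sample(paste0("chr", seq_len(nchr)),
                              length(placedIdx), replace = TRUE)
  gstart[placedIdx] <- sample.int(config$chrom_length - 6000,
                                  length(placedIdx), replace = TRUE)
  gend[placedIdx] <- gstart[placedIdx] + sample(500:5000,
                                                length(placedIdx),
                                                replace = TRUE)
  gtab <- data.frame(id = gid, chrom = gchrom, start = gstart, end = gend,
                     stringsAsFactors = FALSE)
  nSparse <- round(config$frac_sparse_genes * Gn)
  sparse <- sort(sample(placedIdx, min(nSparse, length(placedIdx))))
  ## planted features live in genes expressed clearly above the
  ## detection floor: a planted log2 shift is only recoverable on the
  ## log2(x+1) scale when the baseline is not compressed by the +1.
  muG <- rnorm(Gn, 2, 1.5)
  pool <- setdiff(placedIdx[muG[placedIdx] >= 2], sparse)

  resample <- function(x, k) x[sample.int(length(x), k)] # sample() scalar-safe
  pick <- function(k) {
    if (k == 0) return(integer(0))
    out <- resample(pool, k)
    pool <<- setdiff(pool, out)
    out
  }
  epavIdx <- pick(config$n_epav)
  degIdx <- pick(config$n_deg)

  ## cis-eQTL genes need a SNP strictly within 100 kb of the gene interval
  snpDist <- function(j) {
    same <- which(vtab$chrom == gtab$chrom[j])
    if (!length(same)) return(integer(0))
    d <- pmax(gtab$start[j] - vtab$pos[same], vtab$pos[same] - gtab$end[j], 0)
    same[d < 1e5]
  }
  if (!is.null(config$cis_genes)) {
    cisIdx <- match(config$cis_genes, gid)
    if (anyNA(cisIdx)) stop("configuration error: unknown cis gene id")
    if (any(is.na(gtab$chrom[cisIdx])))
      stop("configuration error: planted cis-eQTL requested for an unplaced gene")
    pool <- setdiff(pool, cisIdx)
  } else {
    cand <- pool[vapply(pool, function(j) length(snpDist(j)) > 0, TRUE)]
    if (length(cand) < config$n_cis_eqtl)
      stop("configuration error: too few placed genes with a nearby SNP")
    cisIdx <- if (config$n_cis_eqtl) resample(cand, config$n_cis_eqtl)
              else integer(0)
    pool <- setdiff(pool, cisIdx)
  }
  transIdx <- pick(config$n_trans_eqtl)

  sdTot <- sqrt(config$sd_biological^2 +
                config$sd_replicate^2 / config$n_replicates)
  eqtlRows <- list()
  addEqtl <- function(geneIdx, snpIdx, cis) {
    f <- config$eqtl_beta
    b <- if (f > 0) sqrt(f / (1 - f)) * sdTot else 0
    d <- if (is.na(gtab$chrom[geneIdx]) ||
             vtab$chrom[snpIdx] != gtab$chrom[geneIdx]) NA_real_
         else max(gtab$start[geneIdx] - vtab$pos[snpIdx],
                  vtab$pos[snpIdx] - gtab$end[geneIdx], 0)
    data.frame(snp = vtab$id[snpIdx], gene = gid[geneIdx], beta = b,
               cis = cis, distance = d, stringsAsFactors = FALSE)
  }
  for (j in cisIdx) {
    s <- snpDist(j)
    if (!length(s))
      stop("configuration error: no SNP within 100 kb of gene ", gid[j])
    eqtlRows[[length(eqtlRows) + 1L]] <- addEqtl(j, resample(s, 1), TRUE)
  }
  for (j in transIdx) {
    other <- which(vtab$chrom != gtab$chrom[j])
    eqtlRows[[length(eqtlRows) + 1L]] <-
      addEqtl(j, resample(other, 1), FALSE)
  }
  eqtlTruth <- if (length(eqtlRows)) do.call(rbind, eqtlRows) else
    data.frame(snp = character(), gene = character(), beta = numeric(),
               cis = logical(), distance = numeric())

  ## ---- expression ---------------------------------------------------------
  L <- matrix(muG, n, Gn, byrow = TRUE, dimnames = list(acc, gid))
  towards <- function(group) { # per-accession ancestry toward a pure group
    w <- numeric(n)
    w[groups == group] <- 1
    if (nD > 0)
      w[groups == "derived"] <- if (group == "pureA") admix else 1 - admix
    w
  }
  degGroups <- rep(c("pureA", "pureB"), length.out = length(degIdx))
  for (i in seq_along(degIdx))
    L[, degIdx[i]] <- L[, degIdx[i]] + config$deg_log2fc * towards(degGroups[i])
  for (r in seq_len(nrow(eqtlTruth))) {
    z <- as.vector(scale(G0[, eqtlTruth$snp[r]]))
    if (anyNA(z)) z <- rep(0, n) # monomorphic draw: no effect possible
    L[, eqtlTruth$gene[r]] <- L[, eqtlTruth$gene[r]] + eqtlTruth$beta[r] * z
  }
  L <- L + matrix(rnorm(n * Gn, 0, config$sd_biological), n, Gn)

  present <- matrix(TRUE, n, Gn)
  for (j in sparse) present[, j] <- runif(n) < runif(1, 0.01, 0.9)
  epavGroups <- rep(c("pureA", "pureB"), length.out = length(epavIdx))
  for (i in seq_along(epavIdx)) {
    carrier <- epavGroups[i]
    other <- if (carrier == "pureA") "pureB" else "pureA"
    w <- towards(carrier)
    keep <- groups == carrier | (groups == "derived" & runif(n) < w)
    keep[groups == other] <- FALSE
    present[, epavIdx[i]] <- keep
  }

  E <- matrix(0, n, Gn)
  for (r in seq_len(config$n_replicates))
    E <- E + 2^(L + matrix(rnorm(n * Gn, 0, config$sd_replicate),
                           n, Gn)) * present
  E <- E / config$n_replicates
  dimnames(E) <- list(acc, gid)

  ## ---- metabolites --------------------------------------------------------
  K <- config$n_metabolites
  mid <- sprintf("met%03d", seq_len(K))
  mpool <- seq_len(K)
  mpick <- function(k) {
    out <- if (k) resample(mpool, k) else integer(0)
    mpool <<- setdiff(mpool, out)
    out
  }
  linkMet <- mpick(config$n_met_links)
  snpLinkMet <- mpick(config$n_met_snp_links)
  dasMet <- mpick(config$n_das)
  sparseMet <- mpick(config$n_sparse_metabolites)

  muM <- rnorm(K, 5, 1)
  ML <- matrix(muM, n, K, byrow = TRUE, dimnames = list(acc, mid))
  bMet <- sqrt(config$met_link_frac / (1 - config$met_link_frac)) *
    config$sd_metabolite
  linkRows <- list()
  if (length(linkMet)) {
    srcGenes <- rep(eqtlTruth$gene[eqtlTruth$cis], length.out = length(linkMet))
    for (i in seq_along(linkMet)) {
      z <- as.vector(scale(.log2p1(E[, srcGenes[i]])))
      ML[, linkMet[i]] <- ML[, linkMet[i]] + bMet * z
      linkRows[[length(linkRows) + 1L]] <-
        data.frame(metabolite = mid[linkMet[i]], source_type = "gene",
                   source_id = srcGenes[i], weight = bMet,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(snpLinkMet)) {
    srcSnps <- sample(vtab$id, length(snpLinkMet))
    for (i in seq_along(snpLinkMet)) {
      z <- as.vector(scale(G0[, srcSnps[i]]))
      if (anyNA(z)) z <- rep(0, n)
      ML[, snpLinkMet[i]] <- ML[, snpLinkMet[i]] + bMet * z
      linkRows[[length(linkRows) + 1L]] <-
        data.frame(metabolite = mid[snpLinkMet[i]], source_type = "snp",
                   source_id = srcSnps[i], weight = bMet,
                   stringsAsFactors = FALSE)
    }
  }
  metLinks <- if (length(linkRows)) do.call(rbind, linkRows) else
    data.frame(metabolite = character(), source_type = character(),
               source_id = character(), weight = numeric())
  dasGroups <- rep(c("pureA", "pureB"), length.out = length(dasMet))
  for (i in seq_along(dasMet))
    ML[, dasMet[i]] <- ML[, dasMet[i]] +
      config$das_log2fc * towards(dasGroups[i])
  ML <- ML + matrix(rnorm(n * K, 0, config$sd_metabolite), n, K)
  Mv <- 2^ML
  if (config$met_missing_frac > 0)
    Mv[runif(n * K) < config$met_missing_frac] <- NA
  for (j in sparseMet) Mv[runif(n) > runif(1, 0.01, 0.1), j] <- NA

  truth <- list(
    epav = data.frame(gene = gid[epavIdx], group = epavGroups,
                      stringsAsFactors = FALSE),
    deg = data.frame(gene = gid[degIdx], group = degGroups,
                     log2fc = rep(config$deg_log2fc, length(degIdx)),
                     stringsAsFactors = FALSE),
    eqtl = eqtlTruth,
    met_links = metLinks,
    das = data.frame(metabolite = mid[dasMet], group = dasGroups,
                     log2fc = rep(config$das_log2fc, length(dasMet)),
                     stringsAsFactors = FALSE))

  new("SyntheticDataset",
      genotype = GenotypeMatrix(G, vtab),
      expression = ExpressionMatrix(E, gtab),
      metabolites = MetaboliteMatrix(Mv),
      groups = GroupDesign(groups, c("pureA", "pureB")),
      truth = truth,
      config = unclass(config))
}
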