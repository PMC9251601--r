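## Independent re-verification of emitted evidence: every candidate pair,
## rich eQTL and dual-role call can be re-tested from its stored
## evidence, and LD-pruning output can be checked exhaustively. These
## run as standing checks in the pipeline test-suite.

#' Re-test the defining predicate of every candidate pair
#'
#' For each emitted pair, checks from first principles that (a) at least
#' one stored supporting SNP's window overlaps the gene interval
#' (distance <= window), (b) every stored supporting SNP is significant
#' for that metabolite, and (c) the pair is a QTT hit.
#'
#' @param pairs `CandidatePair` data.frame.
#' @param sig_snps significant (trait, snp) table used to build it.
#' @param variants,genes coordinate tables.
#' @param qtt `QttTable`.
#' @param window window half-width in bp.
#' @return TRUE, or stops describing the first failing pair.
#' @export
verifyCandidatePairs <- function(pairs, sig_snps, variants, genes, qtt,
                                 window = attr(pairs, "window")) {
  if (!nrow(pairs)) return(TRUE)
  qkey <- paste(qtt$metabolite, qtt$gene, sep = "\r")
  skey <- paste(sig_snps$trait, sig_snps$snp, sep = "\r")
  for (i in seq_len(nrow(pairs))) {
    snps <- strsplit(pairs$support_snps[i], ",", fixed = TRUE)[[1]]
    si <- match(snps, variants$id)
    gi <- match(pairs$gene[i], genes$id)
    if (anyNA(si) || is.na(gi))
      stop("pair ", i, ": unknown SNP or gene id")
    d <- .snpGeneDistance(variants$chrom[si], variants$pos[si],
                          genes$chrom[gi], genes$start[gi], genes$end[gi])
    if (!any(!is.na(d) & d <= window))
      stop("pair ", i, ": no supporting SNP within the window")
    if (!all(paste(pairs$metabolite[i], snps, sep = "\r") %in% skey))
      stop("pair ", i, ": supporting SNP not significant for metabolite")
    if (!paste(pairs$metabolite[i], pairs$gene[i], sep = "\r") %in% qkey)
      stop("pair ", i, ": not a QTT hit")
  }
  TRUE
}

#' Exhaustively verify LD-pruning output
#'
#' Checks that within every window of `window_snps` consecutive retained
#' SNPs on a chromosome, no pair has squared dosage correlation
#' exceeding `r2_max`.
#'
#' @param g the [GenotypeMatrix-class] that was pruned.
#' @param kept character vector of retained SNP IDs.
#' @param window_snps,r2_max the pruning parameters.
#' @return TRUE, or stops naming the offending pair.
#' @export
verifyLdPrune <- function(g, kept, window_snps = 50, r2_max = 0.2) {
  gc <- imputeMean(g)
  X <- gc@dosages
  v <- gc@variants
  for (ch in unique(v$chrom)) {
    ids <- v$id[v$chrom == ch]
    ids <- ids[ids %in% kept]
    if (length(ids) < 2) next
    for (s in seq_len(max(length(ids) - 1, 1))) {
      win <- ids[s:min(s + window_snps - 1, length(ids))]
      if (length(win) < 2) next
      r2 <- .r2mat(X[, win, drop = FALSE])
      diag(r2) <- 0
      if (any(r2 > r2_max)) {
        ij <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        stop("retained pair exceeds r2_max: ", win[ij[1]], " / ",
             win[ij[2]], " (r2 = ", round(max(r2), 3), ")")
      }
    }
  }
  TRUE
}

#' Re-tally rich and dual-role calls
#'
#' Recounts, by brute force, the distinct candidate genes per eQTL SNP
#' (for richness) and re-tests host-gene containment (for dual-role
#' calls) against the emitted annotations.
#'
#' @param pairs `CandidatePair` data.frame.
#' @param eqtl `EqtlTable`.
#' @param genes gene coordinate table.
#' @param rich,dual_role the emitted annotation vectors.
#' @param min_genes_rich richness bound (strict).
#' @param flank dual-role flank in bp.
#' @return TRUE, or stops on the first mismatch.
#' @export
verifyAnnotations <- function(pairs, eqtl, genes, rich, dual_role,
                              min_genes_rich = 10, flank = 0) {
  cand <- unique(pairs$gene)
  sub <- unique(eqtl[eqtl$gene %in% cand, c("gene", "snp")])
  richRef <- character(0)
  for (s in unique(sub$snp))
    if (length(unique(sub$gene[sub$snp == s])) > min_genes_rich)
      richRef <- c(richRef, s)
  if (!setequal(richRef, rich)) stop("rich-eQTL set mismatch on recount")
  dualRef <- character(0)
  snps <- unique(eqtl[, c("snp", "snp_chrom", "snp_pos")])
  for (ge in cand) {
    gi <- match(ge, genes$id)
    if (is.na(genes$chrom[gi])) next
    inGene <- snps$snp_chrom == genes$chrom[gi] &
      snps$snp_pos >= genes$start[gi] - flank &
      snps$snp_pos <= genes$end[gi] + flank
    if (any(inGene)) dualRef <- c(dualRef, ge)
  }
  if (!setequal(dualRef, dual_role)) stop("dual-role set mismatch on recount")
  TRUE
}
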