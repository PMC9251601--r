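## Orchestration of the full workflow:
## data -> popgen -> omics -> association -> network,
## with per-stage table outputs and a checksummed run manifest.

#' Pipeline configuration
#'
#' Collects every stage threshold (defaulting to the values used
#' throughout the package: MAF 0.05 / missingness 0.3, LD pruning
#' 50/10/0.2, mean FPKM 1, presence > 0 with 95%/5% cutoffs, FPKM 20/5
#' abundance classes, DEG |lfc| >= 2 & p < 0.01, DAS present > 8 &
#' fc > 2 or < 0.5 & p < 0.01, GLM 5 PCs / MLM 3 PCs, QTT p < 0.01 with
#' 3 PCs, cis < 100 kb, candidate window 1.5 Mb, pleiotropy > 10
#' metabolites, richness > 10 genes) plus the input source: either a
#' `simulate` block ([simConfig()]) or file paths.
#'
#' @param out_dir output directory.
#' @param simulate a `SimConfig`, or NULL when `inputs` is given.
#' @param inputs named list of paths (`genotype`, `expression`, `coords`,
#'   `metabolites`, `groups`, optional `pure` labels).
#' @param seed master seed for all stage randomness (permutations).
#' @param maf_min,max_missing variant filters.
#' @param ld_window,ld_step,ld_r2 LD-pruning parameters.
#' @param mean_fpkm_min low-expression filter.
#' @param n_pcs_glm,n_pcs_mlm,n_pcs_qtt PC covariate counts.
#' @param gwas_models,gwas_threshold,gwas_min_models metabolite GWAS
#'   settings; `gwas_threshold` is a list (`method` =
#'   "permutation"/"bonferroni", `alpha`, `n_permutations`).
#' @param log10_metabolites log10-transform metabolite traits for
#'   GWAS/QTT (default TRUE).
#' @param qtt_alpha QTT reporting cutoff.
#' @param eqtl_models,eqtl_threshold,cis_max eQTL settings.
#' @param candidate_window,min_metabolites,min_genes_rich,dual_flank
#'   network settings.
#' @param deg_lfc_min,deg_alpha,deg_adjust,das_min_present,das_fc_hi,das_fc_lo,das_alpha
#'   omics-layer thresholds.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(out_dir, simulate = simConfig(), inputs = NULL,
                           seed = 1, maf_min = 0.05, max_missing = 0.3,
                           ld_window = 50, ld_step = 10, ld_r2 = 0.2,
                           mean_fpkm_min = 1,
                           n_pcs_glm = 5, n_pcs_mlm = 3, n_pcs_qtt = 3,
                           gwas_models = c("GLM", "MLM"),
                           gwas_threshold = list(method = "permutation",
                                                 alpha = 0.05,
                                                 n_permutations = 100),
                           gwas_min_models = 2,
                           log10_metabolites = TRUE, qtt_alpha = 0.01,
                           eqtl_models = c("GLM", "MLM"),
                           eqtl_threshold = list(method = "bonferroni",
                                                 alpha = 0.05),
                           cis_max = 1e5, candidate_window = 1.5e6,
                           min_metabolites = 10, min_genes_rich = 10,
                           dual_flank = 0,
                           deg_lfc_min = 2, deg_alpha = 0.01,
                           deg_adjust = "none",
                           das_min_present = 8, das_fc_hi = 2,
                           das_fc_lo = 0.5, das_alpha = 0.01) {
  cfg <- as.list(environment())
  if (is.null(simulate) && is.null(inputs))
    stop("either a simulate block or input paths must be provided")
  stopifnot(maf_min >= 0, maf_min <= 0.5, max_missing >= 0,
            max_missing <= 1, cis_max > 0, candidate_window > 0)
  class(cfg) <- "PipelineConfig"
  cfg
}

.logStage <- function(...) message("[TriOmicNet] ", ...)

#' Run the full multi-omics pipeline
#'
#' Executes the stages in dependency order, writes every stage table
#' under `out_dir` and returns a manifest of emitted files with
#' checksums plus per-stage record counts. Deterministic for a fixed
#' configuration seed. The `data` stage may be resumed from a previous
#' run's `data/` directory, and the `network` stage from previously
#' written association tables.
#'
#' @param config a `PipelineConfig`.
#' @param stages character subset of
#'   c("data", "popgen", "omics", "association", "network"); stages with
#'   unmet in-memory prerequisites re-read the corresponding files.
#' @return list of class `RunArtifacts`: `manifest` (data.frame `file`,
#'   `stage`, `md5`), `counts` (named list), `out_dir`, and the main
#'   result objects.
#' @export
runPipeline <- function(config,
                        stages = c("data", "popgen", "omics",
                                   "association", "network")) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(), stage = character(),
                         stringsAsFactors = FALSE)
  emit <- function(stage, ...) {
    files <- c(...)
    manifest <<- rbind(manifest,
                       data.frame(file = files, stage = stage,
                                  stringsAsFactors = FALSE))
  }
  counts <- list()
  res <- list()
  wt <- function(df, name) {
    p <- file.path(out, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  ## ---- data ---------------------------------------------------------------
  dataDir <- file.path(out, "data")
  if ("data" %in% stages) {
    if (!is.null(config$simulate)) {
      .logStage("simulating dataset (seed ", config$simulate$seed, ")")
      ds <- simulatePopulation(config$simulate)
      paths <- writeDataset(ds, dataDir)
      emit("data", paths)
      inp <- list(genotype = ds@genotype, expression = ds@expression,
                  metabolites = ds@metabolites, groups = ds@groups)
      res$dataset <- ds
    } else {
      ip <- config$inputs
      inp <- readInputs(ip$genotype, ip$expression, ip$coords,
                        ip$metabolites, ip$groups, ip$pure)
    }
  } else {
    .logStage("resuming data stage from ", dataDir)
    inp <- readInputs(file.path(dataDir, "genotype.vcf"),
                      file.path(dataDir, "expression.tsv"),
                      file.path(dataDir, "gene_coords.tsv"),
                      file.path(dataDir, "metabolites.tsv"),
                      file.path(dataDir, "groups.tsv"))
  }
  counts$accessions <- length(accessions(inp$genotype))
  counts$snps_input <- nrow(variants(inp$genotype))

  ## ---- popgen -------------------------------------------------------------
  needAssoc <- any(c("popgen", "association", "network") %in% stages)
  if (needAssoc) {
    .logStage("variant filtering (maf >= ", config$maf_min,
              ", missing <= ", config$max_missing, ")")
    gf <- filterVariants(inp$genotype, config$maf_min, config$max_missing)
    gi <- imputeMean(gf)
    counts$snps_filtered <- nrow(variants(gi))
    .logStage("retained ", counts$snps_filtered, " SNPs; LD pruning")
    kept <- ldPrune(gi, config$ld_window, config$ld_step, config$ld_r2)
    counts$snps_pruned <- length(kept)
    pca <- genotypePca(gi, max(config$n_pcs_glm, config$n_pcs_mlm,
                               config$n_pcs_qtt))
    kin <- kinshipMatrix(gi)
    pg <- pureGroups(inp$groups)
    fst <- fstScan(gi, pg$A, pg$B)
    counts$fst_fixed <- sum(fst$defined & fst$fst >= 1 - 1e-12)
    emit("popgen",
         { p <- file.path(out, "ld_pruned_snps.txt")
           writeLines(kept, p); p },
         wt(fst, "fst.tsv"),
         wt(data.frame(accession = rownames(pca$scores), pca$scores),
            "pca_scores.tsv"))
    res$popgen <- list(filtered = gi, pruned = kept, pca = pca,
                       kinship = kin, fst = fst)
  }

  ## ---- omics --------------------------------------------------------------
  if (any(c("omics", "association", "network") %in% stages)) {
    ef <- filterLowExpression(inp$expression, config$mean_fpkm_min)
    counts$genes_expressed <- ncol(exprValues(ef))
    pres <- classifyPresence(ef)
    abund <- classifyAbundance(ef)
    epav <- callEpav(inp$expression, inp$groups)
    deg <- callDeg(ef, inp$groups, config$deg_lfc_min, config$deg_alpha,
                   config$deg_adjust)
    das <- callDas(inp$metabolites, inp$groups, config$das_min_present,
                   config$das_fc_hi, config$das_fc_lo, config$das_alpha)
    counts$epav_a <- length(epav$A); counts$epav_b <- length(epav$B)
    counts$deg <- sum(deg$called); counts$das <- sum(das$called)
    .logStage(counts$genes_expressed, " expressed genes; ",
              counts$epav_a + counts$epav_b, " ePAVs, ", counts$deg,
              " DEGs, ", counts$das, " DASs")
    emit("omics",
         wt(pres$profile, "presence_classes.tsv"),
         wt(as.data.frame(deg), "deg.tsv"),
         wt(as.data.frame(das), "das.tsv"),
         { p <- file.path(out, "epav.tsv")
           write.table(data.frame(
             gene = c(epav$A, epav$B),
             group = rep(inp$groups@pure, c(length(epav$A),
                                            length(epav$B)))),
             p, sep = "\t", quote = FALSE, row.names = FALSE); p })
    res$omics <- list(expression = ef, presence = pres, abundance = abund,
                      epav = epav, deg = deg, das = das)
  }

  ## ---- association --------------------------------------------------------
  if ("association" %in% stages) {
    mv <- metValues(inp$metabolites)
    traits <- if (config$log10_metabolites) log10(mv) else mv
    mets <- colnames(traits)
    sigList <- list()
    for (i in seq_along(mets)) {
      y <- traits[, i]
      names(y) <- rownames(traits)
      keep <- names(y)[!is.na(y)]
      if (length(keep) < config$n_pcs_glm + 3) next
      gsub_ <- GenotypeMatrix(dosages(res$popgen$filtered)[keep, ,
                                                           drop = FALSE],
                              variants(res$popgen$filtered))
      ksub <- unclass(res$popgen$kinship)[keep, keep]
      tabs <- list()
      ths <- list()
      for (mod in config$gwas_models) {
        nP <- if (mod == "GLM") config$n_pcs_glm else config$n_pcs_mlm
        tabs[[mod]] <- if (mod == "GLM")
          glmScan(y, gsub_, nP, res$popgen$pca, mets[i])
        else mlmScan(y, gsub_, ksub, nP, res$popgen$pca, mets[i])
        ths[[mod]] <- if (identical(config$gwas_threshold$method,
                                    "permutation"))
          permutationThreshold(y[keep], gsub_, mod,
                               config$gwas_threshold$n_permutations,
                               config$gwas_threshold$alpha,
                               seed = .subSeed(config$seed, i),
                               pca = res$popgen$pca, n_pcs = nP,
                               kinship = if (mod == "MLM") ksub)
        else bonferroniThreshold(gsub_, config$gwas_threshold$alpha)
      }
      co <- coIdentified(tabs, ths, config$gwas_min_models)
      if (nrow(co)) sigList[[mets[i]]] <- co
    }
    sig <- if (length(sigList)) do.call(rbind, sigList) else
      data.frame(trait = character(), snp = character(),
                 n_models = integer(), models = character())
    rownames(sig) <- NULL
    counts$sig_snps <- nrow(sig)
    qttList <- lapply(seq_along(mets), function(i) {
      y <- traits[, i]
      names(y) <- rownames(traits)
      if (sum(!is.na(y)) < config$n_pcs_qtt + 3) return(NULL)
      qttScan(y, res$omics$expression, res$popgen$pca, config$n_pcs_qtt,
              config$qtt_alpha, mets[i])
    })
    qtt <- do.call(rbind, qttList)
    if (is.null(qtt))
      qtt <- data.frame(metabolite = character(), gene = character(),
                        coef = numeric(), se = numeric(), p = numeric(),
                        n_covariates = integer())
    rownames(qtt) <- NULL
    counts$qtt_pairs <- nrow(qtt)
    .logStage(counts$sig_snps, " significant (metabolite, SNP) pairs; ",
              counts$qtt_pairs, " QTT pairs; eQTL scan")
    eqtl <- eqtlScan(res$omics$expression, res$popgen$filtered,
                     res$popgen$kinship, res$popgen$pca,
                     models = config$eqtl_models,
                     threshold = c(config$eqtl_threshold,
                                   list(seed = .subSeed(config$seed, 0))),
                     cis_max = config$cis_max,
                     n_pcs_glm = config$n_pcs_glm,
                     n_pcs_mlm = config$n_pcs_mlm)
    counts$eqtls <- nrow(eqtl)
    counts$eqtls_cis <- sum(eqtl$class == "cis")
    counts$eqtls_trans <- sum(eqtl$class == "trans")
    emit("association", wt(sig, "gwas_significant.tsv"),
         wt(qtt, "qtt.tsv"), wt(as.data.frame(eqtl), "eqtl.tsv"))
    res$association <- list(sig = sig, qtt = qtt, eqtl = eqtl)
  }

  ## ---- network ------------------------------------------------------------
  if ("network" %in% stages) {
    if (is.null(res$association)) {
      .logStage("resuming network stage from association tables")
      sig <- read.table(file.path(out, "gwas_significant.tsv"),
                        header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
      qtt <- read.table(file.path(out, "qtt.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
      eqtl <- read.table(file.path(out, "eqtl.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
      res$association <- list(sig = sig, qtt = qtt, eqtl = eqtl)
    }
    a <- res$association
    vtab <- variants(res$popgen$filtered)
    gtab <- geneInfo(res$omics$expression)
    pairs <- candidateGenes(a$sig, vtab, gtab, a$qtt,
                            config$candidate_window)
    pleio <- pleiotropicGenes(pairs, config$min_metabolites)
    links <- linkEqtls(pairs, a$eqtl, config$min_genes_rich)
    dual <- dualRoleGenes(pairs, a$eqtl, gtab, config$dual_flank)
    net <- buildNetwork(pairs, links,
                        list(pleiotropic = pleio, rich = links$rich,
                             dual_role = dual))
    summ <- networkSummary(net)
    counts$candidate_pairs <- nrow(pairs)
    counts$candidate_genes <- length(unique(pairs$gene))
    counts$rich_eqtls <- length(links$rich)
    counts$dual_role_genes <- length(dual)
    .logStage(counts$candidate_pairs, " candidate pairs, ",
              counts$rich_eqtls, " rich eQTLs, ", counts$dual_role_genes,
              " dual-role genes")
    netPaths <- exportNetwork(net, out)
    emit("network", wt(as.data.frame(pairs), "candidate_pairs.tsv"),
         wt(links$links, "eqtl_gene_links.tsv"), netPaths,
         { p <- file.path(out, "network_summary.yaml")
           yaml::write_yaml(lapply(unclass(summ), function(x)
             if (is.na(x)) "undefined" else x), p); p })
    res$network <- list(pairs = pairs, pleiotropic = pleio,
                        links = links, dual_role = dual, net = net,
                        summary = summ)
  }

  manifest$md5 <- unname(tools::md5sum(manifest$file))
  manifest$file <- sub(paste0("^", out, "/?"), "", manifest$file)
  mf <- file.path(out, "manifest.tsv")
  write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  structure(c(list(manifest = manifest, counts = counts, out_dir = out),
              res),
            class = "RunArtifacts")
}
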