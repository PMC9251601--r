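## Readers and writers for the external interfaces: VCF genotypes,
## tab-separated matrices (feature rows, accession columns), group
## labels and truth tables.

#' Write a synthetic dataset to a directory
#'
#' Emits `genotype.vcf` (VCF 4.2, GT-only), `expression.tsv`,
#' `gene_coords.tsv`, `metabolites.tsv`, `groups.tsv`,
#' `truth_<table>.tsv` and `sim_config.yaml`. Matrix files have features
#' as rows and a header row of accession IDs. Files round-trip through
#' the package readers (dosages exactly; abundances to numeric-text
#' precision).
#'
#' @param ds a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, named vector of file paths.
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotype = file.path(dir, "genotype.vcf"),
             expression = file.path(dir, "expression.tsv"),
             genes = file.path(dir, "gene_coords.tsv"),
             metabolites = file.path(dir, "metabolites.tsv"),
             groups = file.path(dir, "groups.tsv"),
             config = file.path(dir, "sim_config.yaml"))
  writeGenotypeVcf(ds@genotype, paths["genotype"])
  writeMatrixTable(exprValues(ds@expression), paths["expression"], "gene")
  write.table(geneInfo(ds@expression), paths["genes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeMatrixTable(metValues(ds@metabolites), paths["metabolites"],
                   "metabolite")
  gl <- groupLabels(ds@groups)
  con <- file(paths["groups"], "w")
  writeLines(paste0("#pure\t", paste(ds@groups@pure, collapse = "\t")), con)
  write.table(data.frame(accession = names(gl), group = unname(gl)),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  for (nm in names(ds@truth)) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    write.table(ds@truth[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[paste0("truth_", nm)] <- p
  }
  yaml::write_yaml(ds@config, paths["config"])
  invisible(paths)
}

#' Write a genotype matrix as a plain-text VCF (GT only)
#'
#' Dosages 0/1/2 map to GT `0/0`, `0/1`, `1/1`; missing maps to `./.`.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeGenotypeVcf <- function(g, path) {
  v <- g@variants
  d <- t(g@dosages) # SNPs x accessions
  gtMap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtMap[d[ok] + 1]
  chroms <- unique(v$chrom)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=TriOmicNet",
           sprintf("##contig=<ID=%s>", chroms),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(g@dosages)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses GT fields with vcfR and converts to alt-allele dosages 0/1/2
#' (`NA` for missing or partially missing genotypes).
#'
#' @param path VCF file (plain or gzipped).
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypeVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alleles <- gsub("\\|", "/", gt)
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[alleles == "0/0"] <- 0
  dose[alleles %in% c("0/1", "1/0")] <- 1
  dose[alleles == "1/1"] <- 2
  GenotypeMatrix(t(dose),
                 data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                            pos = as.integer(fix[, "POS"]),
                            ref = fix[, "REF"], alt = fix[, "ALT"],
                            stringsAsFactors = FALSE))
}

#' Write a feature x accession matrix as TSV
#'
#' @param values accessions x features matrix (transposed on output so
#'   the header row holds accession IDs).
#' @param path output file.
#' @param feature_col name of the first (feature ID) column.
#' @return Invisibly, the path.
#' @export
writeMatrixTable <- function(values, path, feature_col = "feature") {
  df <- data.frame(colnames(values), t(values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readMatrixTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df[[1]]
  m
}

#' Read an expression matrix (and optional gene coordinates)
#'
#' @param path TSV with gene rows, accession-ID header.
#' @param coords_path optional TSV with columns `id`, `chrom`, `start`,
#'   `end` (`chrom` empty/NA = unplaced).
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionTable <- function(path, coords_path = NULL) {
  m <- .readMatrixTable(path)
  genes <- NULL
  if (!is.null(coords_path)) {
    genes <- read.table(coords_path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE,
                        colClasses = c(chrom = "character"))
    genes$chrom[genes$chrom %in% c("", "NA")] <- NA_character_
  }
  ExpressionMatrix(m, genes)
}

#' Read a metabolite matrix
#' @param path TSV with metabolite rows, accession-ID header (`NA` = not
#'   detected).
#' @return A [MetaboliteMatrix-class].
#' @export
readMetaboliteTable <- function(path) MetaboliteMatrix(.readMatrixTable(path))

#' Read group labels
#'
#' @param path TSV with columns `accession`, `group`; an optional first
#'   comment line `#pure<TAB>A<TAB>B` names the pure groups.
#' @param pure optional character(2) overriding the pure group labels.
#' @return A [GroupDesign-class].
#' @export
readGroupTable <- function(path, pure = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(pure) && startsWith(first, "#pure"))
    pure <- strsplit(first, "\t")[[1]][2:3]
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (is.null(pure)) stop("pure group labels not given and not in file")
  GroupDesign(setNames(df$group, df$accession), pure)
}

#' Read and reconcile all pipeline inputs
#'
#' Loads the genotype VCF, expression and metabolite tables and group
#' labels, then restricts every layer to the common accession set
#' (mismatches are reported); accession order follows the genotype file.
#'
#' @param genotype_path VCF file.
#' @param expression_path,coords_path expression TSV and gene
#'   coordinates.
#' @param metabolite_path metabolite TSV.
#' @param groups_path group-label TSV.
#' @param pure optional character(2) pure group labels.
#' @return list with `genotype`, `expression`, `metabolites`, `groups`.
#' @export
readInputs <- function(genotype_path, expression_path, coords_path,
                       metabolite_path, groups_path, pure = NULL) {
  g <- readGenotypeVcf(genotype_path)
  e <- readExpressionTable(expression_path, coords_path)
  m <- readMetaboliteTable(metabolite_path)
  d <- readGroupTable(groups_path, pure)
  common <- Reduce(intersect, list(accessions(g), accessions(e),
                                   accessions(m), accessions(d)))
  if (!length(common)) stop("empty accession intersection across inputs")
  allIds <- unique(c(accessions(g), accessions(e), accessions(m),
                     accessions(d)))
  if (length(common) < length(allIds))
    message("dropping ", length(allIds) - length(common),
            " accession(s) absent from some layer")
  common <- accessions(g)[accessions(g) %in% common]
  list(genotype = GenotypeMatrix(g@dosages[common, , drop = FALSE],
                                 g@variants),
       expression = ExpressionMatrix(e@values[common, , drop = FALSE],
                                     e@genes),
       metabolites = MetaboliteMatrix(m@values[common, , drop = FALSE]),
       groups = GroupDesign(groupLabels(d)[common], d@pure))
}
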