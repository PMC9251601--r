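#' @import methods
#' @importFrom stats rnorm runif rbinom rbeta pt quantile median var sd
#'   cor optimize p.adjust t.test qchisq complete.cases setNames
#' @importFrom utils read.table write.table head
NULL

## Central S4 containers. Matrices are accessions x features throughout;
## rownames are accession IDs, colnames are feature IDs.

#' GenotypeMatrix: accessions x SNP dosages with variant metadata
#'
#' Holds biallelic SNP dosages coded 0/1/2 (alt-allele count, `NA` =
#' missing) together with per-SNP metadata. Positions are 1-based
#' (VCF convention) and must be strictly increasing within a chromosome.
#'
#' @slot dosages numeric matrix, accessions x SNPs, values in {0,1,2,NA}.
#' @slot variants data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per SNP, in dosage column order.
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", variants = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  v <- object@variants
  msg <- character()
  if (!all(c("id", "chrom", "pos", "ref", "alt") %in% names(v)))
    msg <- c(msg, "variants must have columns id, chrom, pos, ref, alt")
  if (nrow(v) != ncol(d))
    msg <- c(msg, "variant count must equal dosage column count")
  if (is.null(rownames(d)))
    msg <- c(msg, "dosages must have accession rownames")
  vals <- d[!is.na(d)]
  ## raw calls are 0/1/2; mean-imputed matrices carry fractional dosages
  if (length(vals) && (min(vals) < 0 || max(vals) > 2))
    msg <- c(msg, "dosage values must lie in [0, 2] or be NA")
  if (nrow(v) > 1) {
    bad <- unlist(lapply(split(v$pos, v$chrom), function(p) any(diff(p) <= 0)))
    if (any(bad))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages accessions x SNPs numeric matrix with values 0/1/2/NA.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosages, variants) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  colnames(dosages) <- variants$id
  storage.mode(dosages) <- "double"
  new("GenotypeMatrix", dosages = dosages, variants = variants)
}

#' ExpressionMatrix: accessions x gene abundances with gene coordinates
#'
#' FPKM-like non-negative abundances. Genes may be unplaced
#' (`chrom = NA`), in which case they cannot take part in coordinate-based
#' operations (cis/trans calls, candidate windows).
#'
#' @slot values numeric matrix, accessions x genes, values >= 0.
#' @slot genes data.frame with columns `id`, `chrom` (NA = unplaced),
#'   `start`, `end` (1-based inclusive).
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", genes = "data.frame"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  g <- object@genes
  msg <- character()
  if (!all(c("id", "chrom", "start", "end") %in% names(g)))
    msg <- c(msg, "genes must have columns id, chrom, start, end")
  if (nrow(g) != ncol(v))
    msg <- c(msg, "gene count must equal value column count")
  if (anyDuplicated(g$id))
    msg <- c(msg, "gene ids must be unique")
  if (any(v[!is.na(v)] < 0))
    msg <- c(msg, "expression values must be non-negative")
  placed <- !is.na(g$chrom)
  if (any(placed) && any(g$start[placed] > g$end[placed]))
    msg <- c(msg, "gene start must be <= end for placed genes")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values accessions x genes non-negative numeric matrix.
#' @param genes data.frame of gene coordinates (`id`, `chrom`, `start`,
#'   `end`); unplaced genes have `chrom = NA`. If missing, all genes are
#'   treated as unplaced.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, genes = NULL) {
  if (is.null(genes)) {
    genes <- data.frame(id = colnames(values), chrom = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes <- genes[match(colnames(values), genes$id), , drop = FALSE]
  rownames(genes) <- NULL
  new("ExpressionMatrix", values = values, genes = genes)
}

#' MetaboliteMatrix: accessions x metabolite-signature abundances
#'
#' Abundances are non-negative; `NA` means the signature was not detected
#' in that accession.
#'
#' @slot values numeric matrix, accessions x signatures.
#' @export
setClass("MetaboliteMatrix", representation(values = "matrix"))

setValidity("MetaboliteMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v))) msg <- c(msg, "values must have accession rownames")
  if (is.null(colnames(v))) msg <- c(msg, "values must have metabolite colnames")
  if (any(v[!is.na(v)] < 0)) msg <- c(msg, "abundances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a MetaboliteMatrix
#' @param values accessions x metabolites numeric matrix (NA = not detected).
#' @return A [MetaboliteMatrix-class] object.
#' @export
MetaboliteMatrix <- function(values) new("MetaboliteMatrix", values = values)

#' GroupDesign: accession group labels and the two pure contrast groups
#'
#' Maps each accession to a group label and designates the two "pure"
#' groups used for all two-group contrasts (ePAV, DEG, DAS, Fst).
#'
#' @slot groups named character vector, accession -> group label.
#' @slot pure character(2), labels of the two pure groups (A first).
#' @export
setClass("GroupDesign",
  representation(groups = "character", pure = "character"))

setValidity("GroupDesign", function(object) {
  msg <- character()
  if (is.null(names(object@groups)))
    msg <- c(msg, "groups must be named by accession")
  if (length(object@pure) != 2 || anyDuplicated(object@pure))
    msg <- c(msg, "exactly two distinct pure group labels required")
  if (!all(object@pure %in% object@groups))
    msg <- c(msg, "pure group labels must occur among group labels")
  if (length(msg)) msg else TRUE
})

#' Construct a GroupDesign
#' @param groups named character vector mapping accession IDs to labels.
#' @param pure character(2): the two pure group labels (first = group A).
#' @return A [GroupDesign-class] object.
#' @export
GroupDesign <- function(groups, pure) {
  new("GroupDesign", groups = groups, pure = as.character(pure))
}

#' SyntheticDataset: a simulated multi-omics dataset with planted truth
#'
#' @slot genotype [GenotypeMatrix-class].
#' @slot expression [ExpressionMatrix-class] (accession level, replicate
#'   mean).
#' @slot metabolites [MetaboliteMatrix-class].
#' @slot groups [GroupDesign-class].
#' @slot truth list of data.frames describing planted structure
#'   (`epav`, `deg`, `eqtl`, `met_links`, `das`).
#' @slot config the `SimConfig` used.
#' @export
setClass("SyntheticDataset",
  representation(genotype = "GenotypeMatrix",
                 expression = "ExpressionMatrix",
                 metabolites = "MetaboliteMatrix",
                 groups = "GroupDesign",
                 truth = "list",
                 config = "list"))

setValidity("SyntheticDataset", function(object) {
  a <- rownames(object@genotype@dosages)
  msg <- character()
  if (!identical(a, rownames(object@expression@values)) ||
      !identical(a, rownames(object@metabolites@values)))
    msg <- c(msg, "accession sets must be identical across omics layers")
  if (!all(a %in% names(object@groups@groups)))
    msg <- c(msg, "group labels must cover all accessions")
  if (length(msg)) msg else TRUE
})

## ---- generics & accessors -------------------------------------------------

#' Accession IDs of an omics container
#' @param x a TriOmicNet container.
#' @return character vector of accession IDs.
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname accessions
#' @export
setMethod("accessions", "GenotypeMatrix", function(x) rownames(x@dosages))
#' @rdname accessions
#' @export
setMethod("accessions", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessions
#' @export
setMethod("accessions", "MetaboliteMatrix", function(x) rownames(x@values))
#' @rdname accessions
#' @export
setMethod("accessions", "GroupDesign", function(x) names(x@groups))
#' @rdname accessions
#' @export
setMethod("accessions", "SyntheticDataset",
          function(x) rownames(x@genotype@dosages))

#' Dosage matrix of a GenotypeMatrix
#' @param x a [GenotypeMatrix-class].
#' @return accessions x SNPs numeric matrix.
#' @export
dosages <- function(x) x@dosages

#' Variant metadata of a GenotypeMatrix
#' @param x a [GenotypeMatrix-class].
#' @return data.frame with id, chrom, pos, ref, alt.
#' @export
variants <- function(x) x@variants

#' Expression values
#' @param x an [ExpressionMatrix-class].
#' @return accessions x genes matrix.
#' @export
exprValues <- function(x) x@values

#' Gene coordinate table
#' @param x an [ExpressionMatrix-class].
#' @return data.frame with id, chrom, start, end.
#' @export
geneInfo <- function(x) x@genes

#' Metabolite abundance values
#' @param x a [MetaboliteMatrix-class].
#' @return accessions x metabolites matrix.
#' @export
metValues <- function(x) x@values

#' Group labels
#' @param x a [GroupDesign-class].
#' @return named character vector accession -> label.
#' @export
groupLabels <- function(x) x@groups

#' Accessions belonging to the pure groups
#' @param x a [GroupDesign-class].
#' @return list with elements `A` and `B` of accession IDs.
#' @export
pureGroups <- function(x) {
  list(A = names(x@groups)[x@groups == x@pure[1]],
       B = names(x@groups)[x@groups == x@pure[2]])
}

#' Planted truth of a synthetic dataset
#' @param x a [SyntheticDataset-class].
#' @return list of data.frames (`epav`, `deg`, `eqtl`, `met_links`, `das`).
#' @export
planted <- function(x) x@truth

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat("GenotypeMatrix:", nrow(d), "accessions x", ncol(d), "SNPs\n")
  cat("  chromosomes:", paste(unique(object@variants$chrom), collapse = ", "),
      "\n")
  cat("  missing:", sprintf("%.2f%%", 100 * mean(is.na(d))), "\n")
})

setMethod("show", "ExpressionMatrix", function(object) {
  v <- object@values
  cat("ExpressionMatrix:", nrow(v), "accessions x", ncol(v), "genes\n")
  cat("  unplaced genes:", sum(is.na(object@genes$chrom)), "\n")
})

setMethod("show", "MetaboliteMatrix", function(object) {
  v <- object@values
  cat("MetaboliteMatrix:", nrow(v), "accessions x", ncol(v), "signatures\n")
  cat("  not detected:", sprintf("%.2f%%", 100 * mean(is.na(v))), "\n")
})

setMethod("show", "GroupDesign", function(object) {
  tab <- table(object@groups)
  cat("GroupDesign:", length(object@groups), "accessions;",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  pure contrast:", object@pure[1], "vs", object@pure[2], "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset with planted truth\n")
  show(object@genotype); show(object@expression); show(object@metabolites)
  show(object@groups)
  tr <- object@truth
  cat("  planted:", nrow(tr$epav), "ePAV,", nrow(tr$deg), "DEG,",
      nrow(tr$eqtl), "eQTL,", nrow(tr$met_links), "metabolite links,",
      nrow(tr$das), "shifted metabolites\n")
})

## internal: subset a GenotypeMatrix by SNP index
.subsetSnps <- function(g, idx) {
  GenotypeMatrix(g@dosages[, idx, drop = FALSE],
                 g@variants[idx, , drop = FALSE])
}

## internal: subset genes of an ExpressionMatrix
.subsetGenes <- function(e, idx) {
  ExpressionMatrix(e@values[, idx, drop = FALSE],
                   e@genes[idx, , drop = FALSE])
}
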