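## Tripartite metabolite-gene-eQTL network assembly: candidate-gene
## colocalization (GWAS window x QTT), pleiotropy/richness/dual-role
## annotation, graph construction and summary tallies.

#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom igraph graph_from_data_frame make_empty_graph V E
#'   vertex_attr edge_attr write_graph read_graph vcount ecount
#'   as_data_frame
NULL

#' Candidate genes by GWAS-window x QTT colocalization
#'
#' A (metabolite, gene) pair is a candidate when the gene's interval
#' overlaps `[s - window, s + window]` for at least one SNP `s`
#' significant for that metabolite AND the pair is a QTT hit. Unplaced
#' genes can never satisfy the window and are excluded.
#'
#' @param sig_snps data.frame with columns `trait` (metabolite) and
#'   `snp` (e.g. from [coIdentified()]).
#' @param variants variant table (`id`, `chrom`, `pos`), e.g.
#'   [variants()].
#' @param genes gene coordinate table (`id`, `chrom`, `start`, `end`).
#' @param qtt `QttTable` from [qttScan()] (already filtered at its
#'   alpha).
#' @param window half-width of the candidate window in bp (default
#'   1.5e6).
#' @return data.frame (`CandidatePair`): `metabolite`, `gene`,
#'   `n_support_snps`, `support_snps` (comma-separated),
#'   `min_distance` (bp from gene interval to the nearest supporting
#'   SNP), `qtt_p`.
#' @export
candidateGenes <- function(sig_snps, variants, genes, qtt,
                           window = 1.5e6) {
  empty <- data.frame(metabolite = character(), gene = character(),
                      n_support_snps = integer(),
                      support_snps = character(), min_distance = numeric(),
                      qtt_p = numeric(), stringsAsFactors = FALSE)
  if (!nrow(sig_snps) || !nrow(qtt)) return(structure(empty,
    class = c("CandidatePair", "data.frame"), window = window))
  si <- match(sig_snps$snp, variants$id)
  if (anyNA(si)) stop("significant SNP absent from variant table")
  placed <- !is.na(genes$chrom)
  gp <- genes[placed, , drop = FALSE]
  gr <- GRanges(gp$chrom, IRanges(gp$start, gp$end))
  sr <- GRanges(variants$chrom[si],
                IRanges(pmax(variants$pos[si] - window, 1),
                        variants$pos[si] + window))
  ov <- findOverlaps(gr, sr)
  if (!length(ov)) return(structure(empty,
    class = c("CandidatePair", "data.frame"), window = window))
  hit <- data.frame(
    metabolite = sig_snps$trait[subjectHits(ov)],
    gene = gp$id[queryHits(ov)],
    snp = sig_snps$snp[subjectHits(ov)],
    distance = .snpGeneDistance(variants$chrom[si][subjectHits(ov)],
                                variants$pos[si][subjectHits(ov)],
                                gp$chrom[queryHits(ov)],
                                gp$start[queryHits(ov)],
                                gp$end[queryHits(ov)]),
    stringsAsFactors = FALSE)
  qkey <- paste(qtt$metabolite, qtt$gene, sep = "\r")
  hit <- hit[paste(hit$metabolite, hit$gene, sep = "\r") %in% qkey, ,
             drop = FALSE]
  if (!nrow(hit)) return(structure(empty,
    class = c("CandidatePair", "data.frame"), window = window))
  key <- paste(hit$metabolite, hit$gene, sep = "\r")
  agg <- split(hit, key)
  out <- do.call(rbind, lapply(agg, function(h) {
    data.frame(metabolite = h$metabolite[1], gene = h$gene[1],
               n_support_snps = length(unique(h$snp)),
               support_snps = paste(unique(h$snp), collapse = ","),
               min_distance = min(h$distance),
               stringsAsFactors = FALSE)
  }))
  out$qtt_p <- qtt$p[match(paste(out$metabolite, out$gene, sep = "\r"),
                           qkey)]
  rownames(out) <- NULL
  structure(out[order(out$metabolite, out$gene), , drop = FALSE],
            class = c("CandidatePair", "data.frame"), window = window)
}

#' Pleiotropic candidate genes
#'
#' Genes associated with strictly more than `min_metabolites` distinct
#' metabolites among the candidate pairs.
#'
#' @param pairs `CandidatePair` data.frame from [candidateGenes()].
#' @param min_metabolites strict lower bound (default 10).
#' @return character vector of gene IDs.
#' @export
pleiotropicGenes <- function(pairs, min_metabolites = 10) {
  if (!nrow(pairs)) return(character(0))
  tab <- tapply(pairs$metabolite, pairs$gene,
                function(m) length(unique(m)))
  sort(names(tab)[tab > min_metabolites])
}

#' Link candidate genes to their eQTLs and flag candidate-gene-rich eQTLs
#'
#' Restricts an `EqtlTable` to genes that appear among the candidate
#' pairs, emits the distinct (gene, eQTL SNP) links, and flags as "rich"
#' every eQTL SNP linked to strictly more than `min_genes_rich` distinct
#' candidate genes.
#'
#' @param pairs `CandidatePair` data.frame.
#' @param eqtl `EqtlTable` from [eqtlScan()].
#' @param min_genes_rich strict lower bound (default 10).
#' @return list: `links` (data.frame `gene`, `snp`, `class`), `rich`
#'   (character vector of rich eQTL SNP IDs).
#' @export
linkEqtls <- function(pairs, eqtl, min_genes_rich = 10) {
  cand <- unique(pairs$gene)
  sub <- eqtl[eqtl$gene %in% cand, c("gene", "snp", "class"), drop = FALSE]
  sub <- unique(sub)
  rownames(sub) <- NULL
  tab <- if (nrow(sub)) tapply(sub$gene, sub$snp,
                               function(g) length(unique(g)))
         else integer(0)
  list(links = sub, rich = sort(names(tab)[tab > min_genes_rich]),
       min_genes_rich = min_genes_rich)
}

#' Genes that are both candidate genes and eQTL hosts
#'
#' A candidate gene is dual-role when at least one eQTL SNP lies within
#' its interval (optionally extended by `flank` bp on both sides).
#'
#' @param pairs `CandidatePair` data.frame.
#' @param eqtl `EqtlTable` (needs `snp_chrom`, `snp_pos`).
#' @param genes gene coordinate table.
#' @param flank bp extension of the gene interval (default 0: strict
#'   host-gene containment).
#' @return character vector of gene IDs.
#' @export
dualRoleGenes <- function(pairs, eqtl, genes, flank = 0) {
  cand <- unique(pairs$gene)
  gi <- genes[genes$id %in% cand & !is.na(genes$chrom), , drop = FALSE]
  snps <- unique(eqtl[, c("snp", "snp_chrom", "snp_pos")])
  if (!nrow(gi) || !nrow(snps)) return(character(0))
  gr <- GRanges(gi$chrom, IRanges(pmax(gi$start - flank, 1),
                                  gi$end + flank))
  sr <- GRanges(snps$snp_chrom, IRanges(snps$snp_pos, snps$snp_pos))
  ov <- findOverlaps(gr, sr)
  sort(unique(gi$id[queryHits(ov)]))
}

#' Assemble the tripartite metabolite-gene-eQTL network
#'
#' Builds a typed graph with metabolite, gene and eQTL-SNP nodes,
#' gene-metabolite edges (from candidate pairs) and eQTL-gene edges
#' (from the link table), carrying pleiotropy / richness / dual-role
#' annotations. Referential integrity is enforced.
#'
#' @param pairs `CandidatePair` data.frame.
#' @param links link list from [linkEqtls()] (or a data.frame with
#'   `gene`, `snp`, `class`).
#' @param annotations list with optional character vectors
#'   `pleiotropic` (genes), `rich` (eQTL SNPs), `dual_role` (genes).
#' @return An igraph object of class `TripartiteNetwork` with vertex
#'   attributes `type` ("metabolite", "gene", "eqtl_snp"),
#'   `pleiotropic`, `rich`, `dual_role`, and edge attributes `type`
#'   ("gene_metabolite", "eqtl_gene") and `class` (cis/trans for
#'   eQTL-gene edges).
#' @export
buildNetwork <- function(pairs, links, annotations = list()) {
  linkDf <- if (is.data.frame(links)) links else links$links
  mets <- unique(pairs$metabolite)
  geneIds <- unique(c(pairs$gene, linkDf$gene))
  snps <- unique(linkDf$snp)
  if (nrow(linkDf) && !all(linkDf$gene %in% c(pairs$gene, linkDf$gene)))
    stop("dangling edge endpoint in link table")
  for (nm in c("pleiotropic", "rich", "dual_role")) {
    bad <- setdiff(annotations[[nm]],
                   if (nm == "rich") snps else geneIds)
    if (length(bad))
      stop("annotation refers to unknown node id: ", bad[1])
  }
  nodes <- data.frame(
    name = c(mets, geneIds, snps),
    type = rep(c("metabolite", "gene", "eqtl_snp"),
               c(length(mets), length(geneIds), length(snps))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$name))
    stop("node id used by more than one node type: ",
         nodes$name[duplicated(nodes$name)][1])
  nodes$pleiotropic <- nodes$name %in% annotations$pleiotropic
  nodes$rich <- nodes$name %in% annotations$rich
  nodes$dual_role <- nodes$name %in% annotations$dual_role
  edges <- rbind(
    if (nrow(pairs)) data.frame(from = pairs$gene, to = pairs$metabolite,
                                type = "gene_metabolite",
                                class = NA_character_,
                                stringsAsFactors = FALSE),
    if (nrow(linkDf)) data.frame(from = linkDf$snp, to = linkDf$gene,
                                 type = "eqtl_gene", class = linkDf$class,
                                 stringsAsFactors = FALSE))
  net <- if (is.null(edges) || !nrow(edges)) {
    g <- make_empty_graph(directed = FALSE)
    if (nrow(nodes)) g <- igraph::add_vertices(
      g, nrow(nodes), name = nodes$name, type = nodes$type,
      pleiotropic = nodes$pleiotropic, rich = nodes$rich,
      dual_role = nodes$dual_role)
    g
  } else {
    bad <- setdiff(c(edges$from, edges$to), nodes$name)
    if (length(bad)) stop("dangling edge endpoint: ", bad[1])
    graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  }
  class(net) <- c("TripartiteNetwork", class(net))
  net
}

#' Summary tallies of a tripartite network
#'
#' Counts nodes and edges by type and reports candidate-gene-rich eQTLs
#' as a percentage of all eQTL SNPs, rounded to one decimal (e.g. rich =
#' 303 of 3407 gives 8.9). With zero eQTL SNPs the fraction is
#' undefined (`NA`).
#'
#' @param net a `TripartiteNetwork` from [buildNetwork()].
#' @return list of class `NetworkSummary`: `n_metabolites`, `n_genes`,
#'   `n_eqtl_snps`, `n_gene_metabolite_edges`, `n_eqtl_gene_links`,
#'   `n_rich_eqtls`, `rich_fraction_pct`, `n_pleiotropic_genes`,
#'   `n_dual_role_genes`.
#' @export
networkSummary <- function(net) {
  ty <- vertex_attr(net, "type")
  et <- if (ecount(net)) edge_attr(net, "type") else character(0)
  nEqtl <- sum(ty == "eqtl_snp")
  nRich <- sum(vertex_attr(net, "rich") & ty == "eqtl_snp")
  structure(list(
    n_metabolites = sum(ty == "metabolite"),
    n_genes = sum(ty == "gene"),
    n_eqtl_snps = nEqtl,
    n_gene_metabolite_edges = sum(et == "gene_metabolite"),
    n_eqtl_gene_links = sum(et == "eqtl_gene"),
    n_rich_eqtls = nRich,
    rich_fraction_pct = if (nEqtl > 0) round(100 * nRich / nEqtl, 1)
                        else NA_real_,
    n_pleiotropic_genes = sum(vertex_attr(net, "pleiotropic") &
                                ty == "gene"),
    n_dual_role_genes = sum(vertex_attr(net, "dual_role") & ty == "gene")),
    class = "NetworkSummary")
}

#' @export
print.NetworkSummary <- function(x, ...) {
  cat("Tripartite network summary\n")
  cat("  metabolites:          ", x$n_metabolites, "\n")
  cat("  candidate genes:      ", x$n_genes, "\n")
  cat("  eQTL SNPs:            ", x$n_eqtl_snps, "\n")
  cat("  gene-metabolite edges:", x$n_gene_metabolite_edges, "\n")
  cat("  eQTL-gene links:      ", x$n_eqtl_gene_links, "\n")
  cat("  rich eQTLs:           ", x$n_rich_eqtls,
      if (!is.na(x$rich_fraction_pct))
        sprintf("(%.1f%% of eQTLs)", x$rich_fraction_pct) else "", "\n")
  cat("  pleiotropic genes:    ", x$n_pleiotropic_genes, "\n")
  cat("  dual-role genes:      ", x$n_dual_role_genes, "\n")
  invisible(x)
}

#' Export a tripartite network
#'
#' Writes GraphML (the round-trip format of record), SIF and plain
#' node/edge tab-separated tables.
#'
#' @param net a `TripartiteNetwork`.
#' @param dir output directory (created if needed).
#' @param basename file stem (default "network").
#' @return Invisibly, the paths written.
#' @export
exportNetwork <- function(net, dir, basename = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(basename,
                                 c(".graphml", ".sif", "_nodes.tsv",
                                   "_edges.tsv")))
  g2 <- net
  class(g2) <- "igraph"
  if (ecount(g2)) {
    cl <- edge_attr(g2, "class")
    cl[is.na(cl)] <- ""
    g2 <- igraph::set_edge_attr(g2, "class", value = cl)
  }
  write_graph(g2, paths[1], format = "graphml")
  ed <- as_data_frame(g2, what = "edges")
  sif <- if (nrow(ed)) paste(ed$from, ed$type, ed$to) else character(0)
  writeLines(sif, paths[2])
  nd <- as_data_frame(g2, what = "vertices")
  write.table(nd, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ed, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Import a tripartite network from GraphML
#'
#' @param path a GraphML file written by [exportNetwork()].
#' @return A `TripartiteNetwork`.
#' @export
importNetwork <- function(path) {
  g <- read_graph(path, format = "graphml")
  if (ecount(g)) {
    cl <- edge_attr(g, "class")
    cl[cl == ""] <- NA_character_
    g <- igraph::set_edge_attr(g, "class", value = cl)
  }
  class(g) <- c("TripartiteNetwork", class(g))
  g
}
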