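# Tissue expression: log2 transform, expressed-gene calls, and the
# gene x tissue bi-clustering (Euclidean distance, complete linkage).

#' Log2-transform an FPKM experiment
#'
#' Adds a \code{log2} assay holding \code{log2(FPKM + pseudocount)}. FPKM
#' matrices contain zeros, so a pseudocount (default 1, making
#' FPKM 0 map to 0) is applied before the log. Transforming an already
#' transformed experiment is a state error.
#'
#' @param se \code{SummarizedExperiment} with an \code{fpkm} assay.
#' @param pseudocount added before taking log2.
#' @return the experiment with a \code{log2} assay.
#' @export
logTransformFpkm <- function(se, pseudocount = 1) {
  if ("log2" %in% assayNames(se))
    stop("experiment is already log2-transformed")
  assays(se)$log2 <- log2(assay(se, "fpkm") + pseudocount)
  se
}

#' Call expressed genes from FPKM
#'
#' A gene is expressed when any tissue-replicate column reaches
#' \code{threshold} FPKM. The tissue count reports in how many distinct
#' tissues that happens.
#'
#' @param se \code{SummarizedExperiment} with an \code{fpkm} assay.
#' @param threshold FPKM call threshold.
#' @return \code{DataFrame}: \code{gene_id}, \code{expressed},
#'   \code{max_fpkm}, \code{n_tissues_expressed}.
#' @export
callExpressed <- function(se, threshold = 1) {
  m <- assay(se, "fpkm")
  tissue <- colData(se)$tissue
  maxF <- apply(m, 1L, max)
  nT <- apply(m >= threshold, 1L, function(v)
    length(unique(tissue[v])))
  S4Vectors::DataFrame(gene_id = rownames(m),
                       expressed = maxF >= threshold,
                       max_fpkm = unname(maxF),
                       n_tissues_expressed = as.integer(nT))
}

#' Bi-cluster genes and tissues
#'
#' Hierarchical clustering of the log2 matrix rows (genes) and columns
#' (tissue replicates) with Euclidean distance and complete linkage, plus
#' the heatmap matrix reordered by both dendrograms. Complete linkage
#' guarantees non-decreasing merge heights; this is asserted on every run.
#'
#' @param se \code{SummarizedExperiment}; [logTransformFpkm()] is applied
#'   on the fly when the \code{log2} assay is absent.
#' @return list with \code{genes} and \code{tissues} (\code{hclust}
#'   objects) and \code{matrix} (reordered log2 matrix). Convert a
#'   dendrogram to newick with [dendrogramNewick()].
#' @export
biclusterExpression <- function(se) {
  if (!"log2" %in% assayNames(se)) se <- logTransformFpkm(se)
  m <- assay(se, "log2")
  stopifnot(nrow(m) >= 2L, ncol(m) >= 2L)
  hg <- hclust(dist(m), method = "complete")
  ht <- hclust(dist(t(m)), method = "complete")
  stopifnot(!is.unsorted(hg$height), !is.unsorted(ht$height))
  list(genes = hg, tissues = ht,
       matrix = m[hg$order, ht$order, drop = FALSE])
}

#' Serialize an hclust dendrogram as newick
#'
#' @param h an \code{hclust} object.
#' @return single newick string.
#' @export
dendrogramNewick <- function(h) {
  ape::write.tree(ape::as.phylo(h))
}
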