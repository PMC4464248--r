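#' Gene template for a TPS subfamily
#'
#' A \code{TpsTemplate} bundles the reference protein, its coding sequence,
#' and the exon-length chain used both by the synthetic-genome forge (to
#' plant genes) and by the gene-model builder (to guide exon inference and
#' defect counting). Subfamilies TPS-a, -b1, -b2 and -g use seven exons;
#' TPS-c, -e and -f use between 9 and 14.
#'
#' @slot templateId single identifier.
#' @slot subfamily one of \code{TPS-a}, \code{TPS-b1}, \code{TPS-b2},
#'   \code{TPS-c}, \code{TPS-e}, \code{TPS-f}, \code{TPS-g}, or
#'   \code{decoy} for non-TPS control templates.
#' @slot protein amino-acid sequence (no terminal stop character).
#' @slot cds coding sequence including the terminal stop codon, so
#'   \code{nchar(cds) == 3 * nchar(protein) + 3}.
#' @slot exonLengths integer vector of exon lengths in nucleotides; sums to
#'   \code{nchar(cds)}. Individual exons need not be multiples of 3.
#' @slot motifPositions named list of 1-based protein offsets for the
#'   planted diagnostic motifs (\code{RRx8W}, \code{RLLR}, \code{DDxxD},
#'   \code{NSE/DTE}).
#' @seealso [tpsTemplates()], [forgeGenome()], [buildGeneModel()]
#' @export
setClass("TpsTemplate", representation(
  templateId = "character",
  subfamily = "character",
  protein = "character",
  cds = "character",
  exonLengths = "integer",
  motifPositions = "list"))

TPS_SUBFAMILIES <- c("TPS-a", "TPS-b1", "TPS-b2", "TPS-c", "TPS-e",
                     "TPS-f", "TPS-g")
SEVEN_EXON_SUBFAMILIES <- c("TPS-a", "TPS-b1", "TPS-b2", "TPS-g")

setValidity("TpsTemplate", function(object) {
  msg <- character()
  n <- length(object@exonLengths)
  if (object@subfamily %in% SEVEN_EXON_SUBFAMILIES && n != 7L)
    msg <- c(msg, sprintf("subfamily %s requires 7 exons, got %d",
                          object@subfamily, n))
  if (object@subfamily %in% c("TPS-c", "TPS-e", "TPS-f") &&
      (n < 9L || n > 14L))
    msg <- c(msg, sprintf("subfamily %s requires 9-14 exons, got %d",
                          object@subfamily, n))
  if (sum(object@exonLengths) != 3L * nchar(object@protein) + 3L)
    msg <- c(msg, "exon lengths must sum to 3 * protein length + 3")
  if (nchar(object@cds) != 3L * nchar(object@protein) + 3L)
    msg <- c(msg, "cds length must be 3 * protein length + 3")
  dd <- object@motifPositions[["DDxxD"]]
  if (!is.null(dd)) {
    win <- substr(object@protein, dd, dd + 4L)
    if (!grepl("^DD..D$", win))
      msg <- c(msg, "no DDxxD-compatible window at motifPositions$DDxxD")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TpsTemplate identifier accessor
#' @param x,object a \code{TpsTemplate}
#' @export
setGeneric("templateId", function(x) standardGeneric("templateId"))
#' @export
setMethod("templateId", "TpsTemplate", function(x) x@templateId)

#' @describeIn TpsTemplate subfamily accessor
#' @export
setGeneric("subfamily", function(x) standardGeneric("subfamily"))
#' @export
setMethod("subfamily", "TpsTemplate", function(x) x@subfamily)

#' @describeIn TpsTemplate template protein (character)
#' @export
setGeneric("templateProtein", function(x) standardGeneric("templateProtein"))
#' @export
setMethod("templateProtein", "TpsTemplate", function(x) x@protein)

#' @describeIn TpsTemplate template CDS including terminal stop (character)
#' @export
setGeneric("templateCds", function(x) standardGeneric("templateCds"))
#' @export
setMethod("templateCds", "TpsTemplate", function(x) x@cds)

#' @describeIn TpsTemplate exon length chain (integer vector, nt)
#' @export
setGeneric("exonLengths", function(x) standardGeneric("exonLengths"))
#' @export
setMethod("exonLengths", "TpsTemplate", function(x) x@exonLengths)

#' @describeIn TpsTemplate planted motif offsets (named list)
#' @export
setGeneric("motifPositions", function(x) standardGeneric("motifPositions"))
#' @export
setMethod("motifPositions", "TpsTemplate", function(x) x@motifPositions)

setMethod("show", "TpsTemplate", function(object) {
  cat(sprintf("TpsTemplate %s (%s): %d aa, %d exons\n",
              object@templateId, object@subfamily, nchar(object@protein),
              length(object@exonLengths)))
})

#' Ground-truth ledger for a forged genome
#'
#' Records every planted gene (coordinates, truth category, injected
#' defects, expression truth, ortholog link), the tandem clusters laid out
#' by the forge, duplication/loss events for two-species forges, and the
#' seed, so that pipeline output can be scored against known truth. The
#' ledger round-trips losslessly through a directory of TSV files plus a
#' YAML config echo ([writeTruthLedger()], [readTruthLedger()]).
#'
#' @slot genes \code{DataFrame}, one row per planted gene.
#' @slot clusters \code{DataFrame}, one row per planted tandem cluster.
#' @slot events \code{DataFrame} of duplication/loss records.
#' @slot seed integer seed the forge ran under.
#' @export
setClass("TruthLedger", representation(
  genes = "DataFrame",
  clusters = "DataFrame",
  events = "DataFrame",
  seed = "integer"))

setValidity("TruthLedger", function(object) {
  msg <- character()
  if (nrow(object@clusters) > 0) {
    members <- unlist(strsplit(object@clusters$members, ","))
    if (!all(members %in% object@genes$gene_id))
      msg <- c(msg, "cluster members missing from gene table")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TruthLedger planted-gene table
#' @param x,object a \code{TruthLedger}
#' @export
setGeneric("ledgerGenes", function(x) standardGeneric("ledgerGenes"))
#' @export
setMethod("ledgerGenes", "TruthLedger", function(x) x@genes)

#' @describeIn TruthLedger planted-cluster table
#' @export
setGeneric("ledgerClusters", function(x) standardGeneric("ledgerClusters"))
#' @export
setMethod("ledgerClusters", "TruthLedger", function(x) x@clusters)

#' @describeIn TruthLedger duplication/loss event table
#' @export
setGeneric("ledgerEvents", function(x) standardGeneric("ledgerEvents"))
#' @export
setMethod("ledgerEvents", "TruthLedger", function(x) x@events)

setMethod("show", "TruthLedger", function(object) {
  cat(sprintf("TruthLedger: %d genes, %d clusters, %d events (seed %d)\n",
              nrow(object@genes), nrow(object@clusters),
              nrow(object@events), object@seed))
  if (nrow(object@genes)) {
    tab <- table(object@genes$truth_category)
    cat("  categories:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = " "), "\n")
  }
})

#' Exon-chain gene model at a candidate locus
#'
#' Product of [buildGeneModel()]: the ordered exon chain, the spliced CDS,
#' its translation (premature stops appear as \code{*}), the guiding
#' template, and the fraction of the template the model covers. Models at
#' scaffold edges or abutting assembly gaps are flagged so that truncation
#' is not mistaken for pseudogenization.
#'
#' @slot geneId model identifier.
#' @slot exons \code{GRanges} of exons, ordered 5' to 3' on the transcript.
#' @slot cds spliced coding sequence (reverse-complemented for minus-strand
#'   models).
#' @slot protein translation of \code{cds}; internal stops rendered
#'   \code{*}.
#' @slot templateId guiding [TpsTemplate-class] identifier.
#' @slot coverage fraction of the template CDS covered by the model
#'   alignment, in [0, 1].
#' @slot edgeTruncated \code{TRUE} when the model abuts a scaffold end or a
#'   run of >= 50 N bases.
#' @export
setClass("TpsGeneModel", representation(
  geneId = "character",
  exons = "GRanges",
  cds = "character",
  protein = "character",
  templateId = "character",
  coverage = "numeric",
  edgeTruncated = "logical"))

setValidity("TpsGeneModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (length(ex)) {
    if (length(unique(as.character(GenomicRanges::strand(ex)))) != 1L)
      msg <- c(msg, "exons must share one strand")
    tx <- if (as.character(GenomicRanges::strand(ex))[1] == "-")
      rev(seq_along(ex)) else seq_along(ex)
    st <- GenomicRanges::start(ex)[order(tx)]
    if (is.unsorted(st))
      msg <- c(msg, "exons must be ordered 5' to 3' on the transcript")
    red <- GenomicRanges::reduce(ex)
    if (sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(ex)))
      msg <- c(msg, "exons must not overlap")
  }
  if (!is.na(object@coverage) &&
      (object@coverage < 0 || object@coverage > 1))
    msg <- c(msg, "coverage must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn TpsGeneModel model identifier
#' @param x,object a \code{TpsGeneModel}
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @export
setMethod("geneId", "TpsGeneModel", function(x) x@geneId)

#' @describeIn TpsGeneModel exon chain as \code{GRanges}
#' @export
setGeneric("modelExons", function(x) standardGeneric("modelExons"))
#' @export
setMethod("modelExons", "TpsGeneModel", function(x) x@exons)

#' @describeIn TpsGeneModel spliced CDS (character)
#' @export
setGeneric("modelCds", function(x) standardGeneric("modelCds"))
#' @export
setMethod("modelCds", "TpsGeneModel", function(x) x@cds)

#' @describeIn TpsGeneModel translated protein (character)
#' @export
setGeneric("modelProtein", function(x) standardGeneric("modelProtein"))
#' @export
setMethod("modelProtein", "TpsGeneModel", function(x) x@protein)

#' @describeIn TpsGeneModel template coverage fraction
#' @export
setGeneric("modelCoverage", function(x) standardGeneric("modelCoverage"))
#' @export
setMethod("modelCoverage", "TpsGeneModel", function(x) x@coverage)

#' @describeIn TpsGeneModel scaffold-edge truncation flag
#' @export
setGeneric("edgeTruncated", function(x) standardGeneric("edgeTruncated"))
#' @export
setMethod("edgeTruncated", "TpsGeneModel", function(x) x@edgeTruncated)

#' @describeIn TpsGeneModel genomic span of the model
#' @export
setGeneric("modelRange", function(x) standardGeneric("modelRange"))
#' @export
setMethod("modelRange", "TpsGeneModel", function(x) {
  r <- range(x@exons)
  names(r) <- x@geneId
  r
})

setMethod("show", "TpsGeneModel", function(object) {
  r <- range(object@exons)
  cat(sprintf(
    "TpsGeneModel %s: %s:%d-%d(%s), %d exons, %d nt CDS, coverage %.2f%s\n",
    object@geneId, as.character(GenomicRanges::seqnames(r)),
    GenomicRanges::start(r), GenomicRanges::end(r),
    as.character(GenomicRanges::strand(r)), length(object@exons),
    nchar(object@cds), object@coverage,
    if (object@edgeTruncated) " [edge]" else ""))
})
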