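# Ledger persistence: one TSV per entity class plus a YAML echo of the
# seed, so a forged data set can be archived and re-scored later.

#' Write a truth ledger to a directory
#'
#' Writes \code{genes.tsv}, \code{clusters.tsv}, \code{events.tsv} and
#' \code{meta.yaml}. The ledger round-trips losslessly through
#' [readTruthLedger()].
#'
#' @param ledger a [TruthLedger-class].
#' @param dir output directory (created when absent).
#' @export
writeTruthLedger <- function(ledger, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f)
    write.table(as.data.frame(df), file.path(dir, f), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "NA")
  wr(ledgerGenes(ledger), "genes.tsv")
  wr(ledgerClusters(ledger), "clusters.tsv")
  wr(ledgerEvents(ledger), "events.tsv")
  write_yaml(list(seed = ledger@seed), file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a truth ledger back from a directory
#'
#' @param dir directory written by [writeTruthLedger()].
#' @return a [TruthLedger-class].
#' @export
readTruthLedger <- function(dir) {
  rd <- function(f, classes = NA) {
    p <- file.path(dir, f)
    S4Vectors::DataFrame(read.delim(p, stringsAsFactors = FALSE,
                                    colClasses = classes))
  }
  genes <- rd("genes.tsv")
  if (nrow(genes)) {
    for (col in c("start", "end", "injected_frameshifts",
                  "injected_stops"))
      genes[[col]] <- as.integer(genes[[col]])
    genes$is_expressed_truth <- as.logical(genes$is_expressed_truth)
    for (col in c("ortholog_of", "species", "exon_starts", "exon_ends"))
      genes[[col]] <- as.character(genes[[col]])
  }
  meta <- read_yaml(file.path(dir, "meta.yaml"))
  new("TruthLedger", genes = genes, clusters = rd("clusters.tsv"),
      events = rd("events.tsv"), seed = as.integer(meta$seed))
}

#' Write the truth ledger as GFF3
#'
#' Mirrors planted gene and exon coordinates as a standard
#' gene/mRNA/exon hierarchy (1-based inclusive, per the GFF3 spec).
#'
#' @param ledger a [TruthLedger-class].
#' @param path output GFF3 file.
#' @export
writeTruthGff3 <- function(ledger, path) {
  g <- as.data.frame(ledgerGenes(ledger))
  if (!nrow(g)) stop("ledger has no genes")
  rows <- list()
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    es <- as.integer(strsplit(g$exon_starts[i], ",")[[1]])
    ee <- as.integer(strsplit(g$exon_ends[i], ",")[[1]])
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold = g$scaffold[i],
      start = c(g$start[i], g$start[i], es),
      end = c(g$end[i], g$end[i], ee),
      strand = g$strand[i],
      type = c("gene", "mRNA", rep("exon", length(es))),
      ID = c(gid, paste0(gid, ".m"),
             paste0(gid, ".exon", seq_along(es))),
      Parent = c(NA_character_, gid,
                 rep(paste0(gid, ".m"), length(es))))
  }
  d <- do.call(rbind, rows)
  gr <- GRanges(d$scaffold, IRanges(d$start, d$end), strand = d$strand,
                type = d$type, ID = d$ID, Parent = d$Parent)
  export.gff3(gr, path)
  invisible(path)
}

#' Planted gene spans as GRanges
#'
#' Convenience accessor: ledger gene coordinates as a named
#' \code{GRanges}, for overlap-based scoring of pipeline output.
#'
#' @param ledger a [TruthLedger-class].
#' @param species optional species filter (\code{"A"}/\code{"B"}).
#' @return named \code{GRanges} with ledger columns as metadata.
#' @export
ledgerRanges <- function(ledger, species = NULL) {
  g <- as.data.frame(ledgerGenes(ledger))
  if (!is.null(species)) g <- g[!is.na(g$species) & g$species == species, ]
  gr <- GRanges(g$scaffold, IRanges(g$start, g$end), strand = g$strand)
  names(gr) <- g$gene_id
  mcols(gr) <- S4Vectors::DataFrame(
    g[, setdiff(names(g), c("scaffold", "start", "end", "strand")),
      drop = FALSE])
  gr
}

#' Extract the planted CDS and protein of a ledger gene
#'
#' Splices the ledger exon coordinates out of the genome (reverse
#' complementing minus-strand genes), providing the planted-truth CDS and
#' translation for round-trip checks.
#'
#' @param ledger a [TruthLedger-class].
#' @param genome the forged \code{DNAStringSet}.
#' @param geneId one ledger gene id.
#' @return list with \code{cds} and \code{protein}.
#' @export
ledgerGeneSequence <- function(ledger, genome, geneId) {
  g <- as.data.frame(ledgerGenes(ledger))
  i <- match(geneId, g$gene_id)
  if (is.na(i)) stop("unknown gene id ", geneId)
  es <- as.integer(strsplit(g$exon_starts[i], ",")[[1]])
  ee <- as.integer(strsplit(g$exon_ends[i], ",")[[1]])
  chrSeq <- genome[[g$scaffold[i]]]
  pieces <- vapply(seq_along(es), function(j)
    as.character(Biostrings::subseq(chrSeq, es[j], ee[j])), character(1))
  cds <- paste(pieces, collapse = "")
  if (g$strand[i] == "-") cds <- revComp(cds)
  list(cds = cds, protein = translateCds(cds))
}
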