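#' Read a genome assembly from FASTA
#'
#' Thin, validating wrapper around [Biostrings::readDNAStringSet()]: record
#' ids are the first whitespace-delimited token of each header, order is
#' preserved, duplicate ids and empty sequences are format errors, and only
#' A/C/G/T/N (case-insensitive) are accepted. Assemblies with N gaps parse;
#' downstream stages treat N as mismatch.
#'
#' @param path path to a FASTA file.
#' @return a \code{DNAStringSet}.
#' @export
readGenome <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence ids in ", path)
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence in ", path)
  freq <- Biostrings::alphabetFrequency(x)
  extra <- setdiff(colnames(freq), c("A", "C", "G", "T", "N"))
  if (any(freq[, extra, drop = FALSE] > 0))
    stop("non-ACGTN characters in ", path)
  x
}

#' Read protein sequences from FASTA
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return an \code{AAStringSet} with first-token ids.
#' @export
readProteins <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence ids in ", path)
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence in ", path)
  x
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param x a \code{DNAStringSet} or \code{AAStringSet} (or named character
#'   vector).
#' @param path output file.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read an FPKM expression matrix
#'
#' Expects a rectangular TSV whose first column holds gene ids and whose
#' remaining column labels follow the \code{tissue_replicate} convention
#' (for example \code{Rt_2} for the second root replicate). Values must be
#' non-negative numbers. Returns a \code{SummarizedExperiment} with an
#' \code{fpkm} assay and \code{colData} columns \code{tissue} and
#' \code{replicate}.
#'
#' @param path path to the TSV.
#' @return a \code{SummarizedExperiment}.
#' @export
readFpkm <- function(path) {
  stopifnot(file.exists(path))
  nf <- unique(count.fields(path, sep = "\t", quote = ""))
  if (length(nf) != 1L)
    stop("ragged rows in ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("FPKM table needs a gene column plus values")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric FPKM values in ", path)
  if (any(m < 0)) stop("negative FPKM values in ", path)
  rownames(m) <- ids
  fpkmExperiment(m)
}

# Assemble the SummarizedExperiment and parse tissue_replicate labels.
fpkmExperiment <- function(m) {
  lab <- colnames(m)
  ok <- grepl("^.+_[0-9]+$", lab)
  tissue <- ifelse(ok, sub("_[0-9]+$", "", lab), lab)
  replicate <- ifelse(ok, as.integer(sub("^.*_", "", lab)), NA_integer_)
  SummarizedExperiment(
    assays = list(fpkm = m),
    colData = S4Vectors::DataFrame(tissue = tissue,
                                   replicate = as.integer(replicate),
                                   row.names = lab))
}

#' Write an FPKM experiment as TSV
#'
#' Columns are labelled \code{tissue_replicate}; the first column is
#' \code{gene_id}. The output round-trips through [readFpkm()].
#'
#' @param se \code{SummarizedExperiment} with an \code{fpkm} assay.
#' @param path output file.
#' @export
writeFpkm <- function(se, path) {
  m <- assay(se, "fpkm")
  tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export gene models as GFF3
#'
#' Writes the standard gene/mRNA/exon/CDS hierarchy with 1-based inclusive
#' coordinates and correct CDS phase, via \pkg{rtracklayer}.
#'
#' @param models list of [TpsGeneModel-class] objects.
#' @param path output GFF3 file.
#' @export
writeModelsGff3 <- function(models, path) {
  rows <- lapply(unname(models), modelGffRows)
  gr <- do.call(c, rows)
  export.gff3(gr, path)
  invisible(path)
}

modelGffRows <- function(model) {
  ex <- modelExons(model)
  if (!length(ex)) return(GRanges())
  gid <- geneId(model)
  r <- range(ex)
  minus <- as.character(strand(ex))[1] == "-"
  txOrder <- if (minus) order(-start(ex)) else order(start(ex))
  cum <- cumsum(c(0L, width(ex)[txOrder]))
  phase <- as.integer((3L - cum[seq_along(ex)] %% 3L) %% 3L)
  phase <- phase[order(txOrder)]  # back to storage order

  gene <- GRanges(seqnames(r), ranges(r), strand(r),
                  type = "gene", ID = gid, Parent = NA_character_,
                  phase = NA_integer_)
  mrna <- GRanges(seqnames(r), ranges(r), strand(r),
                  type = "mRNA", ID = paste0(gid, ".m"), Parent = gid,
                  phase = NA_integer_)
  exon <- GRanges(seqnames(ex), ranges(ex), strand(ex),
                  type = "exon",
                  ID = paste0(gid, ".exon", seq_along(ex)),
                  Parent = paste0(gid, ".m"), phase = NA_integer_)
  cds <- GRanges(seqnames(ex), ranges(ex), strand(ex),
                 type = "CDS",
                 ID = paste0(gid, ".cds", seq_along(ex)),
                 Parent = paste0(gid, ".m"), phase = phase)
  c(gene, mrna, exon, cds)
}

#' Export intervals as a BED6 track
#'
#' Used for cluster spans; BED is 0-based half-open, the conversion happens
#' inside \pkg{rtracklayer}.
#'
#' @param gr a \code{GRanges} with optional \code{name}/\code{score}
#'   metadata columns.
#' @param path output BED file.
#' @export
writeBed6 <- function(gr, path) {
  export.bed(gr, path)
  invisible(path)
}
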