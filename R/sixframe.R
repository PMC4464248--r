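#' Six-frame translation with coordinate maps
#'
#' Translates a nucleotide sequence in all six frames (0-2 forward, 0-2 on
#' the reverse complement). Stop codons are rendered \code{*}; codons
#' containing N translate to \code{X} unless unambiguous. Each translated
#' residue maps back to its genomic codon via [aaToGenomic()].
#'
#' @param seq a \code{DNAString}, \code{DNAStringSet} element or character
#'   scalar.
#' @return a list of six entries, each \code{list(strand, frame, aa)} with
#'   \code{frame} in 0:2 and \code{aa} the translated character string.
#' @examples
#' sixFrameTranslate("ATGGCC")[[1]]$aa  # "MA"
#' @export
sixFrameTranslate <- function(seq) {
  x <- Biostrings::DNAString(as.character(seq))
  L <- length(x)
  stopifnot(L >= 3L)
  rc <- Biostrings::reverseComplement(x)
  out <- vector("list", 6L)
  i <- 1L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") x else rc
    for (f in 0:2) {
      n <- 3L * ((L - f) %/% 3L)
      aa <- if (n >= 3L)
        as.character(Biostrings::translate(
          Biostrings::subseq(s, f + 1L, f + n), if.fuzzy.codon = "solve"))
      else ""
      out[[i]] <- list(strand = strand, frame = f, aa = aa)
      i <- i + 1L
    }
  }
  out
}

#' Map a translated-frame residue range to genomic coordinates
#'
#' @param strand \code{"+"} or \code{"-"} (frame of the reverse
#'   complement).
#' @param frame frame offset 0-2.
#' @param aaStart,aaEnd 1-based residue positions within the frame
#'   translation.
#' @param seqLength length of the genomic sequence.
#' @return integer vector \code{c(start, end)}, 1-based inclusive genomic
#'   coordinates of the codon span.
#' @export
aaToGenomic <- function(strand, frame, aaStart, aaEnd, seqLength) {
  out <- if (strand == "+") {
    c(frame + 3 * (aaStart - 1) + 1, frame + 3 * aaEnd)
  } else {
    c(seqLength - frame - 3 * aaEnd + 1,
      seqLength - frame - 3 * (aaStart - 1))
  }
  as.integer(out)
}
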