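#' Reference gene templates for the seven TPS subfamilies
#'
#' Builds one [TpsTemplate-class] per subfamily: a randomly drawn protein of
#' subfamily-typical length with the four diagnostic motifs planted at fixed
#' offsets (RR(x)8W and RLLR in the N-terminal region, DDxxD and NSE/DTE in
#' the C-terminal half), a back-translated CDS with terminal stop codon, and
#' an exon-length chain. The mono-, sesqui- and hemiterpene subfamilies
#' (TPS-a, -b1, -b2, -g) get seven exons; the diterpene-capable subfamilies
#' get more (TPS-c 14, TPS-e 12, TPS-f 11). Exon lengths are drawn once per
#' template under the given seed, so the same seed always yields the same
#' template set.
#'
#' These templates serve two roles: the synthetic forge plants (possibly
#' mutated) copies of them, and the search/model stages use them as seed
#' proteins and alignment guides.
#'
#' @param seed integer seed fixing the template draw.
#' @return named list of [TpsTemplate-class] objects, one per subfamily.
#' @examples
#' tpl <- tpsTemplates()
#' sapply(tpl, function(t) length(exonLengths(t)))
#' @export
tpsTemplates <- function(seed = 101L) {
  lens <- c("TPS-a" = 555L, "TPS-b1" = 560L, "TPS-b2" = 565L,
            "TPS-c" = 790L, "TPS-e" = 760L, "TPS-f" = 730L,
            "TPS-g" = 550L)
  nExons <- c("TPS-a" = 7L, "TPS-b1" = 7L, "TPS-b2" = 7L, "TPS-c" = 14L,
              "TPS-e" = 12L, "TPS-f" = 11L, "TPS-g" = 7L)
  withSeed(seed, {
    out <- lapply(names(lens), function(sf) {
      makeTemplate(paste0("tpl_", sub("TPS-", "", sf)), sf,
                   proteinLength = lens[[sf]], nExons = nExons[[sf]])
    })
    names(out) <- names(lens)
    out
  })
}

# Build a single template: random protein, planted motifs, random codon
# back-translation, exon split with every exon >= minExon nucleotides.
makeTemplate <- function(templateId, subfamily, proteinLength, nExons,
                         minExon = 80L) {
  L <- as.integer(proteinLength)
  aa <- strsplit(randomProtein(L), "")[[1]]

  plant <- function(pos, residues) {
    keep <- !is.na(residues)
    aa[pos + which(keep) - 1L] <<- residues[keep]
  }
  motifs <- list()
  # RR(x)8W at offset 20, RLLR at offset 38: both inside the first 60 aa.
  motifs[["RRx8W"]] <- 20L
  plant(20L, c("R", "R", rep(NA, 8L), "W"))
  motifs[["RLLR"]] <- 38L
  plant(38L, c("R", "L", "L", "R"))
  # DDxxD just past the middle; NSE/DTE ~120 residues downstream.
  dd <- as.integer(floor(0.55 * L))
  motifs[["DDxxD"]] <- dd
  plant(dd, c("D", "D", NA, NA, "D"))
  nse <- as.integer(floor(0.75 * L))
  motifs[["NSE/DTE"]] <- nse
  plant(nse, c("N", "D", NA, NA, "S", NA, NA, NA, "E"))

  # the planted DDxxD must be the leftmost exact match in the C-terminal
  # half: break any chance D-D-x-x-D arising earlier in the draw
  protectedPos <- c(dd:(dd + 4L), nse:(nse + 8L))
  half <- as.integer(floor(L / 2) + 1L)
  for (s in half:(dd - 1L)) {
    if (aa[s] == "D" && aa[s + 1L] == "D" && aa[s + 4L] == "D") {
      fixable <- setdiff(c(s, s + 1L, s + 4L), protectedPos)
      if (length(fixable))
        aa[fixable[1L]] <- "E"  # conservative D->E, keeps codon-draw parity
    }
  }

  protein <- paste(aa, collapse = "")
  cds <- paste0(backTranslate(protein), sample(stopCodons, 1L))
  exonLens <- splitLengths(nchar(cds), nExons, minExon)
  new("TpsTemplate", templateId = templateId, subfamily = subfamily,
      protein = protein, cds = cds, exonLengths = exonLens,
      motifPositions = motifs)
}

# Random composition of `total` into `n` parts, each >= minPart.
splitLengths <- function(total, n, minPart) {
  stopifnot(total >= n * minPart)
  free <- total - n * minPart
  cuts <- sort(sample.int(free + 1L, n - 1L, replace = TRUE) - 1L)
  parts <- diff(c(0L, cuts, free))
  as.integer(parts + minPart)
}

#' Non-TPS decoy template
#'
#' A multi-exon gene template whose protein is unrelated to any TPS
#' subfamily. Planted decoys exercise the reverse-confirmation step: a
#' locus whose best reverse hit is a decoy protein must not be confirmed
#' as a TPS gene.
#'
#' @param seed integer seed.
#' @param proteinLength decoy protein length in residues.
#' @param nExons exon count (decoys use the subfamily label
#'   \code{"decoy"}, exempt from the TPS exon-count rules).
#' @return a [TpsTemplate-class].
#' @export
decoyTemplate <- function(seed = 202L, proteinLength = 520L, nExons = 5L) {
  withSeed(seed, {
    L <- as.integer(proteinLength)
    protein <- randomProtein(L)
    # Guarantee a DDxxD-free decoy is not required; decoys are recognised
    # by overall similarity, not motifs.
    cds <- paste0(backTranslate(protein), sample(stopCodons, 1L))
    new("TpsTemplate", templateId = "tpl_decoy", subfamily = "decoy",
        protein = protein, cds = cds,
        exonLengths = splitLengths(nchar(cds), as.integer(nExons), 80L),
        motifPositions = list())
  })
}
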