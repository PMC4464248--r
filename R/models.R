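# Template-guided gene modelling. A candidate locus arrives as a chained set
# of translated HSP blocks; the builder chains them colinearly in genome and
# template-protein coordinates, merges blocks separated by less than one
# intron length (frameshifts split a single exon into two frames), snaps
# intron boundaries to GT..AG within a small window by re-scoring the
# junction against the template CDS, and splices the exon chain into a CDS.

#' Build an exon-chain gene model at a candidate locus
#'
#' @param locus a single-locus \code{GRanges} row from
#'   [mergeHitsToLoci()].
#' @param hsps the HSP \code{GRanges} the loci were built from.
#' @param template guiding [TpsTemplate-class]; normally the template whose
#'   seed protein was the locus's best hit.
#' @param genome \code{DNAStringSet}.
#' @param geneId identifier for the model; defaults to
#'   \code{locus$locus_id} or a coordinate-derived id.
#' @param snapWindow half-width (bp) of the window searched for canonical
#'   GT/AG dinucleotides around each alignment-derived intron boundary.
#' @param minIntron genomic gaps between chained blocks smaller than this
#'   are treated as intra-exon breaks (frameshift artefacts), not introns.
#' @return a [TpsGeneModel-class], or \code{NULL} when no colinear chain of
#'   HSP blocks exists (model failure; the locus is kept by callers).
#' @export
buildGeneModel <- function(locus, hsps, template, genome, geneId = NULL,
                           snapWindow = 15L, minIntron = 50L) {
  sub <- hsps[unlist(locus$hsp)]
  own <- sub[sub$seed_id == templateId(template)]
  if (length(own)) sub <- own
  if (!length(sub)) return(NULL)

  sc <- as.character(seqnames(locus))
  chrSeq <- genome[[sc]]
  L <- length(chrSeq)
  minus <- as.character(strand(locus)) == "-"
  pad <- 500L
  regStart <- max(1L, start(locus) - pad)
  regEnd <- min(L, end(locus) + pad)
  region <- Biostrings::subseq(chrSeq, regStart, regEnd)
  if (minus) region <- Biostrings::reverseComplement(region)
  regionChar <- as.character(region)
  W <- nchar(regionChar)

  # HSPs in transcript-local coordinates (1-based on `regionChar`)
  if (minus) {
    ls <- regEnd - end(sub) + 1L
    le <- regEnd - start(sub) + 1L
  } else {
    ls <- start(sub) - regStart + 1L
    le <- end(sub) - regStart + 1L
  }
  blocks <- data.frame(ls = ls, le = le, ss = sub$seed_start,
                       se = sub$seed_end, score = sub$score)
  blocks <- blocks[order(blocks$ls, blocks$ss), , drop = FALSE]

  chain <- chainBlocks(blocks)
  if (!length(chain)) return(NULL)
  ch <- blocks[chain, , drop = FALSE]

  # Group chained blocks into exons and refine intron boundaries as we
  # go. A small genomic gap with contiguous seed coordinates is a
  # frameshift split inside one exon; a gap with substantial seed-
  # coordinate overlap is an intron that the ungapped extensions overran
  # (the GT..AG search window widens to cover the overrun). Junctions
  # where no GT/AG pair exists and the gap is small collapse back into
  # one exon.
  tcds <- templateCds(template)
  exons <- list(c(ch$ls[1], ch$le[1], ch$ss[1], ch$se[1]))
  for (i in seq_len(nrow(ch))[-1]) {
    cur <- exons[[length(exons)]]
    gap <- ch$ls[i] - cur[2] - 1L
    o <- max(0L, cur[4] - ch$ss[i] + 1L)
    merge <- FALSE
    if (gap < minIntron && o <= 8L) {
      merge <- TRUE
    } else {
      j <- refineJunction(regionChar, cur[2], ch$ls[i], cur[4], ch$ss[i],
                          tcds,
                          dRange = c(-(3L * o + snapWindow), snapWindow),
                          aRange = c(-snapWindow, 3L * o + snapWindow),
                          donorMin = cur[1] + 3L, acceptorMax = ch$le[i] - 3L)
      if (is.null(j)) {
        if (gap < minIntron) merge <- TRUE
        else j <- c(cur[2], ch$ls[i])  # keep unrefined boundary
      }
      if (!merge) {
        cur[2] <- j[1]
        exons[[length(exons)]] <- cur
        exons[[length(exons) + 1L]] <- c(j[2], ch$le[i], ch$ss[i],
                                         ch$se[i])
      }
    }
    if (merge) {
      cur[2] <- max(cur[2], ch$le[i]); cur[4] <- max(cur[4], ch$se[i])
      exons[[length(exons)]] <- cur
    }
  }
  ex <- do.call(rbind, exons)
  colnames(ex) <- c("ls", "le", "ss", "se")

  # extend the terminal exons toward the template protein ends
  ext5 <- min(3L * (ex[1, "ss"] - 1L), 45L)
  ex[1, "ls"] <- max(1L, ex[1, "ls"] - ext5)
  protLen <- nchar(templateProtein(template))
  ext3 <- min(3L * (protLen - ex[nrow(ex), "se"]) + 3L, 48L)
  ex[nrow(ex), "le"] <- min(W, ex[nrow(ex), "le"] + ext3)

  cds <- paste(substring(regionChar, ex[, "ls"], ex[, "le"]), collapse = "")

  # back to genomic coordinates; storage order is transcript order
  if (minus) {
    gStart <- regEnd - ex[, "le"] + 1L
    gEnd <- regEnd - ex[, "ls"] + 1L
  } else {
    gStart <- regStart + ex[, "ls"] - 1L
    gEnd <- regStart + ex[, "le"] - 1L
  }
  exGr <- GRanges(sc, IRanges(gStart, gEnd),
                  strand = if (minus) "-" else "+",
                  seqinfo = seqinfo(locus))

  gid <- geneId %||%
    (if (!is.null(locus$locus_id)) locus$locus_id else
       sprintf("%s_%d_%s", sc, min(gStart), if (minus) "m" else "p"))

  cov <- cdsCoverage(cds, tcds)
  model <- new("TpsGeneModel", geneId = gid, exons = exGr, cds = cds,
               protein = translateCds(cds), templateId = templateId(template),
               coverage = cov,
               edgeTruncated = nearEdgeOrGap(chrSeq, min(gStart), max(gEnd)))
  model
}

# Highest-scoring colinear chain (genome and template coordinates both
# increasing); O(n^2) DP, n = number of HSPs at one locus.
chainBlocks <- function(b, seedOverlap = 5L) {
  n <- nrow(b)
  if (!n) return(integer())
  dp <- b$score
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (b$ls[i] > b$ls[j] && b$le[i] > b$le[j] &&
          b$ss[i] >= b$ss[j] - seedOverlap && b$se[i] >= b$se[j] &&
          dp[j] + b$score[i] > dp[i]) {
        dp[i] <- dp[j] + b$score[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(dp)
  out <- integer()
  while (!is.na(i)) { out <- c(i, out); i <- prev[i] }
  out
}

# Choose donor/acceptor positions: among GT (donor) and AG (acceptor)
# dinucleotides within the search ranges around the alignment breakpoints,
# pick the pair whose spliced junction aligns best to the template CDS
# around the corresponding protein position; ties prefer the smallest
# shift.
refineJunction <- function(region, e1, s2, seedEnd1, seedStart2, tcds,
                           dRange, aRange, donorMin = 1L,
                           acceptorMax = NULL) {
  W <- nchar(region)
  if (is.null(acceptorMax)) acceptorMax <- W
  dCand <- integer(0)
  for (d in dRange[1]:dRange[2]) {
    pos <- e1 + d
    if (pos >= donorMin && pos + 2L <= W &&
        substr(region, pos + 1L, pos + 2L) == "GT")
      dCand <- c(dCand, d)
  }
  aCand <- integer(0)
  for (a in aRange[1]:aRange[2]) {
    pos <- s2 + a
    if (pos - 2L >= 1L && pos <= acceptorMax &&
        substr(region, pos - 2L, pos - 1L) == "AG")
      aCand <- c(aCand, a)
  }
  if (!length(dCand) || !length(aCand)) return(NULL)

  tLo <- max(1L, 3L * (min(seedEnd1, seedStart2) - 25L))
  tHi <- min(nchar(tcds), 3L * (max(seedEnd1, seedStart2) + 25L))
  tWin <- Biostrings::DNAString(substr(tcds, tLo, tHi))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2)

  best <- NULL; bestScore <- -Inf
  for (d in dCand) for (a in aCand) {
    if ((s2 + a) - (e1 + d) <= 4L) next  # intron must fit GT..AG
    left <- substr(region, max(1L, e1 + d - 44L), e1 + d)
    right <- substr(region, s2 + a, min(W, s2 + a + 44L))
    piece <- paste0(left, right)
    sc <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(piece), tWin, substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 2, type = "global-local"))
    better <- is.null(best) || sc > bestScore + 1e-9 ||
      (abs(sc - bestScore) <= 1e-9 && abs(d) + abs(a) < abs(best[1]) +
         abs(best[2]))
    if (better) { bestScore <- sc; best <- c(d, a) }
  }
  if (is.null(best)) return(NULL)
  c(e1 + best[1], s2 + best[2])
}

cdsCoverage <- function(cds, tcds) {
  if (!nchar(cds)) return(0)
  aln <- cdsAlignment(cds, tcds)
  min(1, width(Biostrings::subject(aln)) / nchar(tcds))
}

cdsAlignment <- function(cds, tcds) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cds), Biostrings::DNAString(tcds),
    substitutionMatrix = mat, gapOpening = 12, gapExtension = 3,
    type = "local")
}

# TRUE when the model abuts a scaffold end or a run of >= 50 Ns.
nearEdgeOrGap <- function(chrSeq, gStart, gEnd, margin = 10L, nRun = 50L) {
  L <- length(chrSeq)
  if (gStart <= margin || gEnd >= L - margin + 1L) return(TRUE)
  flank <- function(a, b) as.character(Biostrings::subseq(chrSeq,
                                                          max(1L, a),
                                                          min(L, b)))
  pat <- sprintf("N{%d,}", nRun)
  grepl(pat, flank(gStart - nRun - margin, gStart + margin)) ||
    grepl(pat, flank(gEnd - margin, gEnd + nRun + margin))
}

#' Count reading-frame defects in a gene model
#'
#' Aligns the model CDS to the template CDS and tallies the two defect
#' classes of the functional/pseudogene rubric. A frameshift is a cluster
#' of alignment indels whose net length is not divisible by 3; indels
#' closer than \code{collapseWindow} bp collapse to their net length first,
#' so one mutational event is never double-counted. A premature stop is an
#' in-frame stop codon, read in template codon coordinates so that the
#' scrambled translation downstream of a frameshift does not inflate the
#' count, at a position before \code{prematureFraction} of the expected
#' protein length. The terminal stop codon is never counted.
#'
#' @param model a [TpsGeneModel-class] (non-empty CDS required).
#' @param template the guiding [TpsTemplate-class].
#' @param collapseWindow bp window within which indels collapse to their
#'   net length.
#' @param prematureFraction stops at template-protein positions at or past
#'   this fraction of the expected length are not counted.
#' @return list with \code{n_frameshifts}, \code{n_premature_stops},
#'   \code{n_defects}, \code{coverage}, and the template-CDS offsets
#'   \code{frameshift_pos} and \code{stop_pos}.
#' @export
countDefects <- function(model, template, collapseWindow = 30L,
                         prematureFraction = 0.95) {
  cds <- modelCds(model)
  if (!nchar(cds)) stop("model has an empty CDS")
  tcds <- templateCds(template)
  aln <- cdsAlignment(cds, tcds)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  subj <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  tOff <- start(Biostrings::subject(aln)) - 1L

  # template coordinate of every alignment column (position of the last
  # consumed template base)
  tpos <- tOff + cumsum(subj != "-")

  # ---- indel events ----
  gapP <- pat == "-"; gapS <- subj == "-"
  events <- data.frame(pos = integer(), len = integer())
  for (isIns in c(FALSE, TRUE)) {
    mask <- if (isIns) gapS else gapP
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs))
      events <- rbind(events, data.frame(
        pos = tpos[starts[runs]],
        len = (if (isIns) 1L else -1L) * r$lengths[runs]))
  }
  nFs <- 0L; fsPos <- integer()
  if (nrow(events)) {
    events <- events[order(events$pos), , drop = FALSE]
    grp <- cumsum(c(1L, diff(events$pos) > collapseWindow))
    for (g in split(events, grp)) {
      if (sum(g$len) %% 3L != 0L) {
        nFs <- nFs + 1L
        fsPos <- c(fsPos, g$pos[1])
      }
    }
  }

  # ---- premature stops, read in template codon frame ----
  protLen <- nchar(templateProtein(template))
  cut <- floor(prematureFraction * protLen)
  keep <- !gapS
  codon <- (tpos[keep] - 1L) %/% 3L + 1L
  chars <- pat[keep]
  byCodon <- split(chars, codon)
  full <- vapply(byCodon, function(v) length(v) == 3L && !any(v == "-"),
                 logical(1))
  codStr <- vapply(byCodon[full], paste, character(1), collapse = "")
  codIdx <- as.integer(names(byCodon))[full]
  aaOk <- codStr %in% names(Biostrings::GENETIC_CODE)
  isStop <- rep(FALSE, length(codStr))
  isStop[aaOk] <- Biostrings::GENETIC_CODE[codStr[aaOk]] == "*"
  # a "stop" read right next to an indel is an artifact of ambiguous gap
  # placement (a codon read across the frame-repair boundary), not a
  # mutation: leave those uncounted
  if (nrow(events) && any(isStop)) {
    nearIndel <- vapply(3L * codIdx - 2L, function(p)
      any(abs(events$pos - p) <= 12L), logical(1))
    isStop <- isStop & !nearIndel
  }
  prem <- isStop & codIdx <= cut
  nStop <- sum(prem)
  list(n_frameshifts = nFs,
       n_premature_stops = as.integer(nStop),
       n_defects = nFs + as.integer(nStop),
       coverage = min(1, width(Biostrings::subject(aln)) / nchar(tcds)),
       frameshift_pos = fsPos,
       stop_pos = 3L * codIdx[prem] - 2L)
}

#' Summarize exon-intron structure across gene models
#'
#' @param models list of [TpsGeneModel-class] objects.
#' @param subfamilies named character vector mapping gene ids to
#'   subfamilies (optional).
#' @return list with \code{genes} (per-gene exon counts), \code{introns}
#'   (per-intron lengths, numbered from the 5' end) and \code{modal}
#'   (modal exon count per subfamily).
#' @export
exonStructureSummary <- function(models, subfamilies = NULL) {
  stopifnot(length(models) >= 1L)
  ids <- vapply(models, geneId, character(1))
  nEx <- vapply(models, function(m) length(modelExons(m)), integer(1))
  sf <- if (is.null(subfamilies)) rep(NA_character_, length(ids))
        else unname(subfamilies[ids])
  genes <- S4Vectors::DataFrame(gene_id = ids, subfamily = sf,
                                n_exons = nEx)
  introns <- do.call(rbind, lapply(models, function(m) {
    ex <- modelExons(m)
    if (length(ex) < 2L) return(NULL)
    st <- sort(start(ex)); en <- sort(end(ex))
    lens <- st[-1] - en[-length(en)] - 1L
    if (as.character(strand(ex))[1] == "-") lens <- rev(lens)
    data.frame(gene_id = geneId(m), intron = seq_along(lens),
               length = lens)
  }))
  if (is.null(introns))
    introns <- data.frame(gene_id = character(), intron = integer(),
                          length = integer())
  modal <- if (all(is.na(sf))) S4Vectors::DataFrame() else {
    tab <- tapply(nEx, sf, function(v) {
      t <- table(v); as.integer(names(t)[which.max(t)])
    })
    S4Vectors::DataFrame(subfamily = names(tab),
                         modal_exons = as.integer(tab))
  }
  list(genes = genes, introns = S4Vectors::DataFrame(introns),
       modal = modal)
}
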