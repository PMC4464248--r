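# Translated homology search: exact amino-acid k-mer seeding between the
# six-frame translation of the genome and a set of seed proteins, followed
# by ungapped x-drop extension under BLOSUM62. Gapped refinement is left to
# the template-guided model builder; locus chaining below only needs block
# coordinates.

#' Find high-scoring segment pairs between a genome and seed proteins
#'
#' Every exact amino-acid k-mer shared between a frame translation of the
#' genome and a seed protein nucleates an ungapped extension in both
#' directions, trimmed at the maximum-scoring endpoints and abandoned when
#' the running score drops more than \code{xdrop} below the best so far.
#' Extensions scoring below \code{minScore} are discarded. Output order is
#' deterministic: scaffold, start, descending score.
#'
#' @param genome \code{DNAStringSet} (or path to FASTA).
#' @param seeds named \code{AAStringSet}, named character vector, or list
#'   of [TpsTemplate-class] objects used as seed proteins.
#' @param k amino-acid seed word length.
#' @param xdrop ungapped extension abandon threshold (raw BLOSUM62 score).
#' @param minScore minimum HSP score retained.
#' @param maxExtend cap on extension length per side, residues.
#' @return \code{GRanges} of HSPs with metadata columns \code{seed_id},
#'   \code{frame}, \code{score}, \code{seed_start}, \code{seed_end}.
#' @seealso [mergeHitsToLoci()], [reverseConfirm()]
#' @export
seedAndExtend <- function(genome, seeds, k = 5L, xdrop = 20, minScore = 50,
                          maxExtend = 2000L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- readGenome(genome)
  seeds <- asSeedProteins(seeds)
  if (!length(seeds)) stop("seed set is empty")
  if (any(nchar(seeds) < k))
    stop("k exceeds the shortest seed protein length")
  B <- blosum62()

  seedChars <- lapply(seeds, function(s) strsplit(s, "")[[1]])
  idx <- buildKmerIndex(seeds, k)

  res <- list()
  for (sc in names(genome)) {
    chrSeq <- genome[[sc]]
    L <- length(chrSeq)
    if (L < 3L) next
    frames <- sixFrameTranslate(chrSeq)
    for (fr in frames) {
      n <- nchar(fr$aa)
      if (n < k) next
      fchars <- strsplit(fr$aa, "")[[1]]
      kms <- substring(fr$aa, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
      hitPos <- which(kms %in% names(idx))
      if (!length(hitPos)) next
      covered <- new.env(parent = emptyenv())
      for (p in hitPos) {
        ent <- idx[[kms[p]]]
        for (j in seq_len(nrow(ent))) {
          sid <- ent$seed[j]; spos <- ent$pos[j]
          key <- paste0(sid, "@", p - spos)
          prevEnd <- covered[[key]]
          if (!is.null(prevEnd) && p <= prevEnd) next
          h <- extendHit(fchars, seedChars[[sid]], p, spos, k, B,
                         xdrop, maxExtend)
          covered[[key]] <- h$aaEnd
          if (h$score < minScore) next
          g <- aaToGenomic(fr$strand, fr$frame, h$aaStart, h$aaEnd, L)
          res[[length(res) + 1L]] <- list(
            scaffold = sc, start = g[1], end = g[2], strand = fr$strand,
            frame = fr$frame, seed_id = sid, score = h$score,
            seed_start = h$seedStart, seed_end = h$seedEnd)
        }
      }
    }
  }
  hspGRanges(res, genome)
}

asSeedProteins <- function(seeds) {
  if (is.list(seeds) && !length(seeds)) return(character())
  if (is.list(seeds) && methods::is(seeds[[1]], "TpsTemplate")) {
    out <- vapply(seeds, templateProtein, character(1))
    names(out) <- vapply(seeds, templateId, character(1))
    return(out)
  }
  if (methods::is(seeds, "AAStringSet")) return(setNames(as.character(seeds),
                                                         names(seeds)))
  if (is.character(seeds)) return(seeds)
  stop("unsupported seed type")
}

buildKmerIndex <- function(seeds, k) {
  tabs <- lapply(names(seeds), function(sid) {
    s <- seeds[[sid]]
    n <- nchar(s)
    if (n < k) return(NULL)
    pos <- seq_len(n - k + 1L)
    data.frame(kmer = substring(s, pos, pos + k - 1L), seed = sid, pos = pos,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  tab <- tab[!grepl("[*X]", tab$kmer), , drop = FALSE]
  split(tab[c("seed", "pos")], tab$kmer)
}

# Ungapped x-drop extension around an exact k-mer match.
extendHit <- function(fchars, schars, p, spos, k, B, xdrop, maxExtend) {
  n <- length(fchars); m <- length(schars)
  core <- sum(B[cbind(fchars[p:(p + k - 1L)], schars[spos:(spos + k - 1L)])])

  extendDir <- function(fi, si, step) {
    len <- if (step > 0L) min(n - fi + 1L, m - si + 1L, maxExtend)
           else min(fi, si, maxExtend)
    if (len <= 0L) return(c(0L, 0))
    ii <- fi + step * (seq_len(len) - 1L)
    jj <- si + step * (seq_len(len) - 1L)
    sc <- B[cbind(fchars[ii], schars[jj])]
    cum <- cumsum(sc)
    bad <- which(cummax(cum) - cum > xdrop)
    lim <- if (length(bad)) bad[1L] - 1L else len
    if (lim <= 0L) return(c(0L, 0))
    best <- which.max(cum[seq_len(lim)])
    if (cum[best] <= 0) return(c(0L, 0))
    c(best, cum[best])
  }
  r <- extendDir(p + k, spos + k, 1L)
  l <- extendDir(p - 1L, spos - 1L, -1L)
  list(aaStart = p - l[1L], aaEnd = p + k - 1L + r[1L],
       seedStart = spos - l[1L], seedEnd = spos + k - 1L + r[1L],
       score = core + r[2L] + l[2L])
}

hspGRanges <- function(res, genome) {
  si <- GenomeInfoDb::Seqinfo(names(genome), Biostrings::width(genome))
  if (!length(res)) {
    gr <- GRanges(seqinfo = si)
    mcols(gr) <- S4Vectors::DataFrame(seed_id = character(),
      frame = integer(), score = numeric(), seed_start = integer(),
      seed_end = integer())
    return(gr)
  }
  d <- do.call(rbind, lapply(res, as.data.frame))
  gr <- GRanges(d$scaffold, IRanges(d$start, d$end), strand = d$strand,
                seed_id = d$seed_id, frame = as.integer(d$frame),
                score = d$score, seed_start = as.integer(d$seed_start),
                seed_end = as.integer(d$seed_end), seqinfo = si)
  gr <- unique(gr)
  gr[order(as.integer(seqnames(gr)), start(gr), -gr$score)]
}

#' Chain HSPs into candidate loci and apply the exon-count filter
#'
#' HSPs of one seed protein on one scaffold and strand, walked in
#' transcript order, are chained into a candidate locus while the genomic
#' gap stays at or below \code{maxGap} and the seed-protein coordinates
#' keep advancing; a colinearity reset (the next HSP restarting near the
#' start of the seed protein) opens a new locus, which is what separates
#' the members of a tandem array. Loci found by different seeds that
#' overlap reciprocally by at least half of both spans are redundant
#' sightings of one gene: only the highest-scoring locus is kept. The
#' number of non-overlapping HSP blocks after overlap-collapsing stands in
#' for the exon count: loci with fewer than \code{minBlocks} blocks are
#' flagged \code{excluded_few_exons} but kept, so filter accounting stays
#' reconstructible. Chaining is independent of the input order of HSPs.
#'
#' @param hsps \code{GRanges} from [seedAndExtend()].
#' @param maxGap maximum intra-locus gap, bp.
#' @param minBlocks minimum number of collapsed HSP blocks.
#' @param resetTol residues of backward seed-coordinate rewind tolerated
#'   before a colinearity reset is called; rewinds smaller than this
#'   (overlapping exon hits, frame splits) stay within one locus.
#' @return \code{GRanges} of loci with metadata columns
#'   \code{block_count}, \code{score}, \code{best_seed},
#'   \code{excluded_few_exons} and \code{hsp} (an \code{IntegerList} of
#'   indices into the sorted HSP input, which is returned as attribute
#'   \code{"hsps"}).
#' @export
mergeHitsToLoci <- function(hsps, maxGap = 10000L, minBlocks = 3L,
                            resetTol = 50L) {
  hsps <- hsps[order(as.integer(seqnames(hsps)), start(hsps), end(hsps),
                     hsps$seed_id)]
  if (!length(hsps)) {
    loci <- GRanges(seqinfo = seqinfo(hsps))
    mcols(loci) <- S4Vectors::DataFrame(block_count = integer(),
      score = numeric(), best_seed = character(),
      excluded_few_exons = logical(), hsp = IRanges::IntegerList())
    attr(loci, "hsps") <- hsps
    return(loci)
  }
  key <- paste(as.character(seqnames(hsps)), as.character(strand(hsps)),
               hsps$seed_id)
  groups <- base::split(seq_along(hsps), key)
  rows <- list()
  for (ii in groups) {
    minus <- as.character(strand(hsps))[ii[1]] == "-"
    ii <- ii[order(if (minus) -start(hsps)[ii] else start(hsps)[ii])]
    n <- length(ii)
    newLocus <- logical(n); newLocus[1] <- TRUE
    if (n > 1L) {
      maxSeedEnd <- hsps$seed_end[ii[1]]
      for (j in 2:n) {
        gap <- if (minus)
          start(hsps)[ii[j - 1L]] - end(hsps)[ii[j]]
        else start(hsps)[ii[j]] - end(hsps)[ii[j - 1L]]
        reset <- hsps$seed_start[ii[j]] < maxSeedEnd - resetTol &&
          hsps$seed_end[ii[j]] <= maxSeedEnd
        newLocus[j] <- gap > maxGap || reset
        maxSeedEnd <- if (newLocus[j]) hsps$seed_end[ii[j]]
                      else max(maxSeedEnd, hsps$seed_end[ii[j]])
      }
    }
    cid <- cumsum(newLocus)
    for (cc in base::split(ii, cid)) {
      sub <- hsps[cc]
      blocks <- reduce(ranges(sub))
      # locus score: per collapsed block, the best member HSP score
      ol <- findOverlaps(ranges(sub), blocks)
      blockBest <- tapply(sub$score[queryHits(ol)], subjectHits(ol), max)
      rows[[length(rows) + 1L]] <- list(
        scaffold = as.character(seqnames(sub))[1],
        start = min(start(sub)), end = max(end(sub)),
        strand = as.character(strand(sub))[1],
        block_count = length(blocks), score = sum(blockBest),
        best_seed = sub$seed_id[1], hsp = cc)
    }
  }
  loci <- GRanges(
    vapply(rows, `[[`, character(1), "scaffold"),
    IRanges(vapply(rows, `[[`, numeric(1), "start"),
            vapply(rows, `[[`, numeric(1), "end")),
    strand = vapply(rows, `[[`, character(1), "strand"),
    block_count = as.integer(vapply(rows, `[[`, numeric(1),
                                    "block_count")),
    score = vapply(rows, `[[`, numeric(1), "score"),
    best_seed = vapply(rows, `[[`, character(1), "best_seed"),
    seqinfo = seqinfo(hsps))
  loci$excluded_few_exons <- loci$block_count < minBlocks
  loci$hsp <- IRanges::IntegerList(lapply(rows, `[[`, "hsp"))

  # redundancy removal: reciprocal overlap >= 50% keeps the best locus
  keep <- rep(TRUE, length(loci))
  ol <- findOverlaps(loci, loci, ignore.strand = TRUE)
  ol <- ol[queryHits(ol) < subjectHits(ol)]
  if (length(ol)) {
    q <- queryHits(ol); s <- subjectHits(ol)
    ov <- width(pintersect(ranges(loci)[q], ranges(loci)[s]))
    recip <- ov >= 0.5 * width(loci)[q] & ov >= 0.5 * width(loci)[s]
    for (j in which(recip)) {
      drop <- if (loci$score[q[j]] >= loci$score[s[j]]) s[j] else q[j]
      keep[drop] <- FALSE
    }
  }
  loci <- loci[keep]
  loci <- loci[order(as.integer(seqnames(loci)), start(loci))]
  attr(loci, "hsps") <- hsps
  loci
}

#' Confirm a candidate locus by reverse search
#'
#' Reconstructs a peptide from the locus's HSP blocks (best block per
#' collapsed region, translated in its own frame, concatenated in
#' transcript order) and aligns it against every seed and every decoy
#' protein. The locus is confirmed iff its best hit is a seed with percent
#' identity at or above \code{minIdentity}, beating every decoy.
#'
#' @param locus one element of the \code{GRanges} from
#'   [mergeHitsToLoci()] (carrying the \code{hsp} index column).
#' @param hsps the HSP \code{GRanges} the loci were built from (attribute
#'   \code{"hsps"} of the locus set).
#' @param genome \code{DNAStringSet}.
#' @param seeds seed proteins (same forms as [seedAndExtend()]).
#' @param decoys optional decoy proteins, same forms; may be empty.
#' @param minIdentity percent identity threshold for confirmation.
#' @return list with elements \code{confirmed}, \code{best_id},
#'   \code{best_identity}, \code{is_seed}.
#' @export
reverseConfirm <- function(locus, hsps, genome, seeds, decoys = NULL,
                           minIdentity = 30) {
  seeds <- asSeedProteins(seeds)
  if (!length(seeds)) stop("seed set is empty")
  decoys <- if (is.null(decoys)) character() else asSeedProteins(decoys)
  pep <- locusPeptide(locus, hsps, genome)
  if (!nchar(pep))
    return(list(confirmed = FALSE, best_id = NA_character_,
                best_identity = 0, is_seed = FALSE))
  cand <- c(seeds, decoys)
  ids <- vapply(names(cand), function(id) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pep), Biostrings::AAString(cand[[id]]),
      substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
      type = "global-local")
    Biostrings::pid(aln, type = "PID1")
  }, numeric(1))
  best <- names(ids)[which.max(ids)]
  isSeed <- best %in% names(seeds)
  list(confirmed = isSeed && ids[[best]] >= minIdentity,
       best_id = best, best_identity = unname(ids[[best]]),
       is_seed = isSeed)
}

# Concatenated translation of the locus's non-redundant HSP blocks in
# transcript order.
locusPeptide <- function(locus, hsps, genome) {
  ii <- unlist(locus$hsp)
  sub <- hsps[ii]
  if (!length(sub)) return("")
  blocks <- reduce(ranges(sub))
  ol <- findOverlaps(ranges(sub), blocks)
  pick <- tapply(seq_along(sub)[queryHits(ol)], subjectHits(ol),
                 function(v) v[which.max(sub$score[v])])
  sel <- sub[as.integer(pick)]
  minus <- as.character(strand(locus)) == "-"
  sel <- sel[order(if (minus) -start(sel) else start(sel))]
  chrSeq <- genome[[as.character(seqnames(locus))]]
  chunks <- vapply(seq_along(sel), function(j) {
    s <- Biostrings::subseq(chrSeq, start(sel)[j], end(sel)[j])
    if (minus) s <- Biostrings::reverseComplement(s)
    translateCds(as.character(s))
  }, character(1))
  paste(chunks, collapse = "")
}
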