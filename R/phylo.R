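# Protein alignment, distances, neighbor-joining trees with bootstrap,
# and similarity-based subfamily assignment.

#' Align a set of proteins
#'
#' Progressive multiple alignment. Pairs are aligned exactly by global
#' dynamic programming (BLOSUM62, affine gaps); larger sets go through the
#' mafft progressive aligner (FFT-NS-2, no iterative refinement), which is
#' deterministic for a fixed input. A single sequence returns the trivial
#' alignment.
#'
#' @param proteins named character vector or \code{AAStringSet}.
#' @return \code{AAStringSet} of equal-width gapped rows, input order
#'   preserved.
#' @export
alignProteins <- function(proteins) {
  if (methods::is(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  stopifnot(length(proteins) >= 1L, !is.null(names(proteins)))
  if (length(proteins) == 1L)
    return(Biostrings::AAStringSet(proteins))
  if (length(proteins) == 2L) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(proteins[[1]]), Biostrings::AAString(proteins[[2]]),
      substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
      type = "global")
    out <- Biostrings::AAStringSet(c(
      as.character(Biostrings::alignedPattern(aln)),
      as.character(Biostrings::alignedSubject(aln))))
    names(out) <- names(proteins)
    return(out)
  }
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)))
  # temporary ids guard against mafft header munging
  tmpIds <- sprintf("s%06d", seq_along(proteins))
  writeFasta(setNames(proteins, tmpIds), fin)
  status <- system2("mafft",
                    c("--retree", "2", "--maxiterate", "0", "--amino",
                      "--quiet", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0L) stop("mafft failed with status ", status)
  aln <- Biostrings::readAAStringSet(fout)
  ids <- sub("\\s.*", "", names(aln))
  aln <- Biostrings::AAStringSet(toupper(as.character(aln)))
  names(aln) <- names(proteins)[match(ids, tmpIds)]
  aln[names(proteins)]
}

ungapRow <- function(x) gsub("-", "", x)

#' Truncate an alignment at the reference exon-2 midpoint
#'
#' The N-terminal region (all of exon 1 and the start of exon 2) is highly
#' variable across subfamilies, partly because of chloroplast transit
#' peptides, and is removed before tree building. Columns 5' of the
#' midpoint of the reference row's second exon are dropped. When no
#' exon-boundary map is available the rule falls back to dropping
#' N-terminal-third columns that are mostly gaps. Idempotent: a truncated
#' alignment passes through unchanged.
#'
#' @param aln \code{AAStringSet} alignment.
#' @param refId id of the reference row carrying the exon map.
#' @param exonLengths exon-length chain (nt) of the reference row's
#'   template, e.g. \code{exonLengths(template)}; \code{NULL} triggers the
#'   gap-fraction fallback.
#' @return truncated \code{AAStringSet} (metadata records the cut).
#' @export
truncateAlignment <- function(aln, refId = NULL, exonLengths = NULL) {
  if (isTRUE(S4Vectors::metadata(aln)$truncated)) return(aln)
  W <- unique(Biostrings::width(aln))
  stopifnot(length(W) == 1L)
  if (!is.null(refId) && !is.null(exonLengths)) {
    stopifnot(refId %in% names(aln), length(exonLengths) >= 2L)
    aaEnds <- ceiling(cumsum(as.numeric(exonLengths)) / 3)
    cutResidue <- ceiling((aaEnds[1] + aaEnds[2]) / 2)
    row <- strsplit(as.character(aln[[refId]]), "")[[1]]
    cumRes <- cumsum(row != "-")
    col <- which(cumRes >= cutResidue)[1]
    if (is.na(col)) col <- W + 1L
    keep <- seq_len(W) >= col
  } else {
    message("no exon map; dropping gappy columns in the N-terminal third")
    third <- floor(W / 3)
    mat <- do.call(rbind, strsplit(as.character(aln), ""))
    gapFrac <- colMeans(mat == "-")
    keep <- rep(TRUE, W)
    keep[seq_len(third)] <- gapFrac[seq_len(third)] <= 0.5
  }
  out <- Biostrings::AAStringSet(vapply(as.character(aln), function(r)
    paste(strsplit(r, "")[[1]][keep], collapse = ""), character(1)))
  names(out) <- names(aln)
  S4Vectors::metadata(out)$truncated <- TRUE
  out
}

#' Protein distance matrix from an alignment
#'
#' Pairwise p-distances over shared non-gap columns, corrected with the
#' Kimura protein formula \eqn{d = -\ln(1 - p - 0.2 p^2)}. The correction
#' is undefined for very divergent pairs; at \eqn{p \ge 0.85} the raw
#' p-distance is used instead (noted via message).
#'
#' @param aln \code{AAStringSet} alignment.
#' @param correction \code{"kimura"} or \code{"p"}.
#' @return symmetric distance matrix with row/column names.
#' @export
proteinDistance <- function(aln, correction = c("kimura", "p")) {
  correction <- match.arg(correction)
  mat <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(mat) <- names(aln)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  fellBack <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    p <- if (!any(ok)) 0 else mean(mat[i, ok] != mat[j, ok])
    v <- p
    if (correction == "kimura") {
      arg <- 1 - p - 0.2 * p^2
      if (p < 0.85 && arg > 0) v <- -log(arg) else fellBack <- TRUE
    }
    d[i, j] <- d[j, i] <- v
  }
  if (fellBack)
    message("Kimura correction undefined for some pairs; p-distance used")
  d
}

#' Neighbor-joining tree with optional bootstrap
#'
#' Canonical NJ agglomeration (via \pkg{ape}) on a distance matrix or an
#' alignment. Negative branch lengths are clamped to zero. With
#' \code{bootstrap > 0} an alignment is required: columns are resampled
#' with replacement, distances and trees recomputed, and each internal
#' edge is labelled with the percentage of replicates containing its
#' bipartition.
#'
#' @param x symmetric distance matrix (or \code{dist}), or an
#'   \code{AAStringSet} alignment.
#' @param bootstrap number of bootstrap replicates (0 = none).
#' @param seed RNG seed for the resampling.
#' @param correction distance correction, see [proteinDistance()].
#' @return an \pkg{ape} \code{phylo}; bootstrap percentages, when
#'   computed, are in \code{node.label}.
#' @export
njTree <- function(x, bootstrap = 0L, seed = 1L,
                   correction = "kimura") {
  fromAln <- methods::is(x, "AAStringSet")
  if (fromAln) {
    aln <- x
    d <- proteinDistance(aln, correction)
  } else {
    d <- as.matrix(x)
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop("distance matrix must be symmetric")
  }
  stopifnot(nrow(as.matrix(d)) >= 3L)
  tree <- ape::nj(as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  if (bootstrap > 0L) {
    if (!fromAln)
      stop("bootstrap requires an alignment, not a bare distance matrix")
    W <- unique(Biostrings::width(aln))
    reps <- withSeed(seed, {
      lapply(seq_len(bootstrap), function(b) {
        cols <- sample.int(W, W, replace = TRUE)
        mat <- do.call(rbind, strsplit(as.character(aln), ""))
        sub <- Biostrings::AAStringSet(apply(mat[, cols, drop = FALSE], 1L,
                                             paste, collapse = ""))
        names(sub) <- names(aln)
        t <- ape::nj(as.dist(suppressMessages(
          proteinDistance(sub, correction))))
        t$edge.length[t$edge.length < 0] <- 0
        t
      })
    })
    counts <- ape::prop.clades(tree, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tree$node.label <- as.character(roundHalfUp(100 * counts / bootstrap))
  }
  tree
}

#' Assign subfamilies by similarity to labelled exemplars
#'
#' Each query gets the label of its highest global-alignment-identity
#' exemplar. The margin is the identity gap to the best exemplar of any
#' other label; queries with margin under \code{ambiguousMargin} identity
#' points are flagged ambiguous (chimeric or deeply diverged sequences).
#'
#' @param proteins named character vector or \code{AAStringSet} of query
#'   proteins.
#' @param exemplars named character vector or \code{AAStringSet} of
#'   labelled reference proteins.
#' @param labels named character vector mapping exemplar ids to subfamily
#'   labels.
#' @param ambiguousMargin identity-point margin below which the call is
#'   flagged.
#' @return \code{DataFrame}: \code{gene_id}, \code{subfamily},
#'   \code{identity}, \code{margin}, \code{ambiguous}.
#' @export
assignSubfamily <- function(proteins, exemplars, labels,
                            ambiguousMargin = 5) {
  if (methods::is(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  if (methods::is(exemplars, "AAStringSet"))
    exemplars <- setNames(as.character(exemplars), names(exemplars))
  stopifnot(length(exemplars) >= 1L,
            all(names(exemplars) %in% names(labels)))
  rows <- lapply(names(proteins), function(id) {
    ids <- vapply(exemplars, function(e)
      proteinIdentity(proteins[[id]], e), numeric(1))
    best <- which.max(ids)
    lab <- unname(labels[names(exemplars)[best]])
    others <- ids[labels[names(exemplars)] != lab]
    margin <- if (length(others)) ids[best] - max(others) else Inf
    S4Vectors::DataFrame(gene_id = id, subfamily = lab,
                         identity = unname(ids[best]),
                         margin = unname(margin),
                         ambiguous = margin < ambiguousMargin)
  })
  do.call(rbind, rows)
}
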