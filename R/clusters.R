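# Tandem gene arrays: same-subfamily runs along a scaffold, pseudogenes
# included by default because array statistics in this family count genes
# and pseudogenes alike.

#' Detect tandem gene clusters
#'
#' Per scaffold and subfamily, genes sorted by start coordinate are chained
#' while the stop-codon-to-start-codon distance (model end to next model
#' start) does not exceed \code{window}. Runs of two or more genes become
#' clusters; singletons are excluded from the cluster list but counted in
#' the returned attribute \code{"n_singletons"}.
#'
#' @param genes \code{GRanges} of gene spans, with gene ids as names.
#' @param subfamilies named character vector mapping gene ids to
#'   subfamilies; unlabelled genes are skipped with a warning.
#' @param categories optional named category vector (from
#'   [classifyLoci()]); needed only when \code{includePseudogenes} is
#'   \code{FALSE}.
#' @param window maximum gap between consecutive members, bp.
#' @param includePseudogenes keep category-iv members in clusters
#'   (default, matching gene-and-pseudogene array counts).
#' @return \code{DataFrame} of clusters: \code{scaffold},
#'   \code{subfamily}, \code{members} (comma-joined ids in coordinate
#'   order), \code{n_members}, \code{span_bp} (end of last minus start of
#'   first member), \code{kb_per_gene}, \code{max_gap_bp}.
#' @export
detectClusters <- function(genes, subfamilies, categories = NULL,
                           window = 100000L, includePseudogenes = TRUE) {
  ids <- names(genes)
  if (is.null(ids)) stop("genes must be a named GRanges")
  sf <- unname(subfamilies[ids])
  if (any(is.na(sf))) {
    warning(sum(is.na(sf)), " unlabelled gene(s) skipped")
    genes <- genes[!is.na(sf)]; ids <- names(genes); sf <- sf[!is.na(sf)]
  }
  if (!includePseudogenes && !is.null(categories)) {
    keep <- unname(categories[ids]) != "iv"
    genes <- genes[keep]; ids <- ids[keep]; sf <- sf[keep]
  }
  rows <- list()
  nSingle <- 0L
  for (grp in base::split(seq_along(genes),
                          paste(as.character(seqnames(genes)), sf))) {
    o <- grp[order(start(genes)[grp])]
    if (length(o) == 1L) { nSingle <- nSingle + 1L; next }
    gaps <- start(genes)[o][-1] - end(genes)[o][-length(o)]
    cid <- cumsum(c(1L, gaps > window))
    for (run in split(seq_along(o), cid)) {
      m <- o[run]
      if (length(m) < 2L) { nSingle <- nSingle + 1L; next }
      span <- max(end(genes)[m]) - min(start(genes)[m])
      memberGaps <- start(genes)[m][-1] - end(genes)[m][-length(m)]
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = as.character(seqnames(genes))[m[1]],
        subfamily = sf[m[1]],
        members = paste(ids[m], collapse = ","),
        n_members = length(m),
        span_bp = span,
        kb_per_gene = clusterDensity(span, length(m)),
        max_gap_bp = max(memberGaps))
    }
  }
  out <- if (length(rows)) S4Vectors::DataFrame(do.call(rbind, rows))
         else S4Vectors::DataFrame(scaffold = character(),
                                   subfamily = character(),
                                   members = character(),
                                   n_members = integer(),
                                   span_bp = numeric(),
                                   kb_per_gene = numeric(),
                                   max_gap_bp = numeric())
  attr(out, "n_singletons") <- nSingle
  attr(out, "window") <- window
  out
}

#' Cluster gene density in kb per gene
#'
#' Span in kilobases divided by the member count (span over n, not n-1:
#' a 317,000 bp run of 17 genes is one gene every 18.6 kb), reported to
#' one decimal with conventional half-up rounding.
#'
#' @param spanBp cluster span in bp.
#' @param nMembers member count (> 0).
#' @return kb per gene, one decimal.
#' @examples
#' clusterDensity(317000, 17)  # 18.6
#' clusterDensity(107000, 8)   # 13.4
#' @export
clusterDensity <- function(spanBp, nMembers) {
  if (any(nMembers <= 0)) stop("cluster density undefined for 0 members")
  roundHalfUp((spanBp / 1000) / nMembers, 1)
}

#' Within-cluster versus subfamily-wide similarity
#'
#' Mean pairwise global-alignment percent identity among cluster members,
#' divided by the mean over all pairs of the whole subfamily. Tandem
#' arrays of recent duplicates score well above 1. Members without a
#' translatable protein are excluded with a message.
#'
#' @param clusterIds gene ids of the cluster members (>= 2 usable).
#' @param proteins named character vector (or \code{AAStringSet}) of all
#'   subfamily proteins (>= 3).
#' @return list with \code{ratio}, \code{cluster_mean},
#'   \code{subfamily_mean}.
#' @export
clusterSimilarityRatio <- function(clusterIds, proteins) {
  if (methods::is(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  usable <- clusterIds[clusterIds %in% names(proteins) &
                         nchar(proteins[clusterIds]) > 0]
  if (length(usable) < length(clusterIds))
    message(length(clusterIds) - length(usable),
            " cluster member(s) without translatable protein excluded")
  stopifnot(length(usable) >= 2L, length(proteins) >= 3L)
  meanPid <- function(ids) {
    prs <- utils::combn(ids, 2L)
    mean(vapply(seq_len(ncol(prs)), function(j)
      proteinIdentity(proteins[[prs[1, j]]], proteins[[prs[2, j]]]),
      numeric(1)))
  }
  cm <- meanPid(usable)
  sm <- meanPid(names(proteins))
  list(ratio = cm / sm, cluster_mean = cm, subfamily_mean = sm)
}
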