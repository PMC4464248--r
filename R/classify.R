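# Five-category functional/pseudogene rubric.
#
# (i)   full-length, expressed, no defects
# (ii)  full-length, expressed, 1-2 defects
# (iii) full-length, not expressed, no defects
# (iv)  more than two defects (frameshifts + premature stops combined);
#       also full-length unexpressed loci with 1-2 defects (conservative)
# (v)   partial genes
#
# Categories i-iii are putatively functional. A locus is full-length when
# its template coverage reaches `fullLengthCoverage` or it is truncated by
# the scaffold edge / an assembly gap (missing sequence is not evidence of
# pseudogenization).

#' Classify loci into the five-category rubric
#'
#' Applies, in order: more than two defects gives category iv; loci that
#' are not full length give category v; then expression and defect count
#' split the full-length loci into i, ii and iii. Full-length unexpressed
#' loci carrying 1-2 defects fall to category iv (the rubric leaves this
#' cell open; without expression support a damaged locus is not promoted).
#' The fired rule is recorded in \code{rationale}.
#'
#' @param stats a \code{data.frame}/\code{DataFrame} with one row per locus
#'   and columns \code{gene_id}, \code{n_frameshifts},
#'   \code{n_premature_stops}, \code{coverage}, \code{edge_truncated},
#'   \code{expressed} (NA treated as not expressed).
#' @param maxDefects defect count above which a locus is a pseudogene.
#' @param fullLengthCoverage template coverage needed to call a locus full
#'   length (edge-truncated loci are exempt).
#' @return \code{DataFrame} of \code{gene_id}, \code{category},
#'   \code{functional}, \code{n_defects}, \code{rationale}.
#' @examples
#' stats <- data.frame(gene_id = c("g1", "g2"),
#'                     n_frameshifts = c(0, 3), n_premature_stops = 0,
#'                     coverage = 1, edge_truncated = FALSE,
#'                     expressed = TRUE)
#' classifyLoci(stats)
#' @export
classifyLoci <- function(stats, maxDefects = 2L, fullLengthCoverage = 0.9) {
  stats <- as.data.frame(stats)
  need <- c("gene_id", "n_frameshifts", "n_premature_stops", "coverage",
            "edge_truncated", "expressed")
  miss <- setdiff(need, names(stats))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  nDef <- stats$n_frameshifts + stats$n_premature_stops
  expressed <- !is.na(stats$expressed) & stats$expressed
  fullLen <- stats$coverage >= fullLengthCoverage | stats$edge_truncated

  category <- character(nrow(stats))
  rationale <- character(nrow(stats))
  for (i in seq_len(nrow(stats))) {
    if (nDef[i] > maxDefects) {
      category[i] <- "iv"
      rationale[i] <- sprintf("%d defects > %d", nDef[i], maxDefects)
    } else if (!fullLen[i]) {
      category[i] <- "v"
      rationale[i] <- sprintf("partial: coverage %.2f", stats$coverage[i])
    } else if (expressed[i] && nDef[i] == 0L) {
      category[i] <- "i"
      rationale[i] <- "full length, expressed, no defects"
    } else if (expressed[i]) {
      category[i] <- "ii"
      rationale[i] <- sprintf("full length, expressed, %d defects", nDef[i])
    } else if (nDef[i] == 0L) {
      category[i] <- "iii"
      rationale[i] <- "full length, not expressed, no defects"
    } else {
      category[i] <- "iv"
      rationale[i] <- sprintf(
        "full length, not expressed, %d defects (conservative)", nDef[i])
    }
  }
  S4Vectors::DataFrame(gene_id = stats$gene_id, category = category,
                       functional = category %in% c("i", "ii", "iii"),
                       n_defects = as.integer(nDef), rationale = rationale)
}

#' Per-subfamily summary of classified loci
#'
#' @param records output of [classifyLoci()].
#' @param subfamilies named character vector mapping gene ids to TPS
#'   subfamilies; unmapped genes count as \code{"unassigned"}.
#' @return list with \code{by_subfamily} (functional and pseudogene counts
#'   per subfamily), \code{by_category} (locus counts per category) and
#'   scalar totals \code{n_functional}, \code{n_pseudogene},
#'   \code{n_partial}, \code{n_total}.
#' @export
summarizeFamily <- function(records, subfamilies = NULL) {
  records <- as.data.frame(records)
  sf <- if (is.null(subfamilies)) rep("unassigned", nrow(records))
        else {
          v <- unname(subfamilies[records$gene_id])
          ifelse(is.na(v), "unassigned", v)
        }
  lv <- c("i", "ii", "iii", "iv", "v")
  byCat <- table(factor(records$category, levels = lv))
  sfl <- sort(unique(sf))
  bySf <- S4Vectors::DataFrame(
    subfamily = sfl,
    n_functional = vapply(sfl, function(s)
      sum(records$functional[sf == s]), integer(1)),
    n_pseudogene = vapply(sfl, function(s)
      sum(records$category[sf == s] == "iv"), integer(1)),
    n_partial = vapply(sfl, function(s)
      sum(records$category[sf == s] == "v"), integer(1)))
  list(by_subfamily = bySf,
       by_category = as.integer(byCat) |> setNames(lv),
       n_functional = sum(records$functional),
       n_pseudogene = sum(records$category == "iv"),
       n_partial = sum(records$category == "v"),
       n_total = nrow(records))
}
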