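# Diagnostic TPS motifs and the four-symbol quality grading:
#   "+" perfect match, "•" one constrained residue changed, ">" two
#   changed, "-" no window with at most two mismatches.

#' Built-in motif definitions
#'
#' Four diagnostic TPS motifs. Mismatches are counted only at constrained
#' positions (wildcards are free): RR(x)8W over R, R, W; RLLR over all
#' four; DDxxD over the three D positions; NSE/DTE over the five
#' constrained positions of (N/D)-D-x-x-(S/T)-x-x-x-E. The N-terminal
#' motifs are searched in windows starting within the first 60 residues;
#' the metal-binding motifs in the C-terminal half.
#'
#' @return named list of motif definitions (\code{name}, \code{pattern} as
#'   a list of allowed-residue vectors with \code{NULL} wildcards,
#'   \code{window} as \code{"nterm"} or \code{"cterm"}).
#' @export
tpsMotifs <- function() {
  list(
    "RRx8W" = list(name = "RRx8W",
                   pattern = c(list("R", "R"), rep(list(NULL), 8), list("W")),
                   window = "nterm"),
    "RLLR" = list(name = "RLLR",
                  pattern = list("R", "L", "L", "R"), window = "nterm"),
    "DDxxD" = list(name = "DDxxD",
                   pattern = list("D", "D", NULL, NULL, "D"),
                   window = "cterm"),
    "NSE/DTE" = list(name = "NSE/DTE",
                     pattern = list(c("N", "D"), "D", NULL, NULL,
                                    c("S", "T"), NULL, NULL, NULL, "E"),
                     window = "cterm"))
}

motifStartRange <- function(window, protLen, patLen, ntermWidth = 60L) {
  lastStart <- protLen - patLen + 1L
  if (lastStart < 1L) return(integer())
  if (window == "nterm") seq_len(min(ntermWidth, lastStart))
  else {
    from <- max(1L, floor(protLen / 2) + 1L)
    if (from > lastStart) integer() else from:lastStart
  }
}

#' Scan a protein for a diagnostic motif
#'
#' Slides the motif over its search window, counts mismatches at the
#' constrained positions of every placement, and keeps the placement with
#' the fewest mismatches (leftmost on ties). Quality maps the mismatch
#' count: 0 is \code{"+"}, 1 is \code{"•"}, 2 is \code{">"}; when no
#' placement has two or fewer mismatches the motif is absent (\code{"-"},
#' position \code{NA}). Proteins shorter than the motif report absence,
#' not an error.
#'
#' @param protein amino-acid string.
#' @param definition one element of [tpsMotifs()] (or a compatible list).
#' @param ntermWidth width of the N-terminal search window, residues.
#' @return \code{DataFrame} row: \code{motif}, \code{position},
#'   \code{mismatches}, \code{quality}.
#' @export
scanMotif <- function(protein, definition, ntermWidth = 60L) {
  pat <- definition$pattern
  pl <- length(pat)
  L <- nchar(protein)
  starts <- motifStartRange(definition$window, L, pl, ntermWidth)
  if (!length(starts))
    return(S4Vectors::DataFrame(motif = definition$name,
                                position = NA_integer_,
                                mismatches = NA_integer_, quality = "-"))
  aa <- strsplit(protein, "")[[1]]
  constrained <- which(!vapply(pat, is.null, logical(1)))
  mism <- integer(length(starts))
  for (k in constrained) {
    ok <- aa[starts + k - 1L] %in% pat[[k]]
    mism <- mism + !ok
  }
  best <- which.min(mism)  # leftmost minimum
  m <- mism[best]
  if (m > 2L)
    return(S4Vectors::DataFrame(motif = definition$name,
                                position = NA_integer_,
                                mismatches = NA_integer_, quality = "-"))
  S4Vectors::DataFrame(motif = definition$name,
                       position = starts[best],
                       mismatches = m,
                       quality = c("+", "•", ">")[m + 1L])
}

#' Locate the DDxxD metal-binding motif
#'
#' Returns the leftmost exact D-D-x-x-D in the C-terminal half; failing
#' that, the best placement with at most two mismatches; failing that,
#' \code{NA} with quality \code{"-"}.
#'
#' @param protein amino-acid string.
#' @return list with \code{position} (1-based protein coordinate or NA)
#'   and \code{quality}.
#' @export
locateDdxxd <- function(protein) {
  L <- nchar(protein)
  starts <- motifStartRange("cterm", L, 5L)
  if (length(starts)) {
    aa <- strsplit(protein, "")[[1]]
    exact <- starts[aa[starts] == "D" & aa[starts + 1L] == "D" &
                      aa[starts + 4L] == "D"]
    if (length(exact))
      return(list(position = exact[1L], quality = "+"))
  }
  rep <- scanMotif(protein, tpsMotifs()[["DDxxD"]])
  list(position = if (is.na(rep$position)) NA_integer_ else rep$position,
       quality = rep$quality)
}

#' Motif report table for a set of proteins
#'
#' @param proteins named character vector or \code{AAStringSet}.
#' @param definitions motif definitions, default [tpsMotifs()].
#' @param ascii replace the UTF-8 bullet with \code{"o"} for plain-ASCII
#'   output.
#' @return \code{DataFrame} with one row per protein x motif.
#' @export
motifTable <- function(proteins, definitions = tpsMotifs(), ascii = FALSE) {
  if (methods::is(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  rows <- list()
  for (id in names(proteins)) {
    for (def in definitions) {
      r <- scanMotif(proteins[[id]], def)
      r$gene_id <- id
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("gene_id", "motif", "position", "mismatches", "quality")]
  if (ascii) out$quality <- sub("•", "o", out$quality, fixed = TRUE)
  out
}
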