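# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
          rm(".Random.seed", envir = .GlobalEnv)
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Round half away from zero (printed percentages like 46 and 43 use
# conventional rounding, not banker's rounding).
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Codons per amino acid, from the standard genetic code.
codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

randomDna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

randomProtein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Substitute each residue independently with probability `rate`, always to a
# different residue. Never introduces stops.
mutateProtein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  aa <- strsplit(protein, "")[[1]]
  hit <- which(runif(length(aa)) < rate)
  for (i in hit) {
    aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
  }
  paste(aa, collapse = "")
}

# Back-translate a protein given a reference CDS: unchanged residues keep the
# reference codon, substituted residues get a uniformly drawn codon.
backTranslate <- function(protein, refProtein = NULL, refCds = NULL) {
  ct <- codonTable()
  aa <- strsplit(protein, "")[[1]]
  cods <- character(length(aa))
  refAa <- if (!is.null(refProtein)) strsplit(refProtein, "")[[1]] else NULL
  for (i in seq_along(aa)) {
    if (!is.null(refAa) && i <= length(refAa) && refAa[i] == aa[i]) {
      cods[i] <- substr(refCds, 3 * i - 2, 3 * i)
    } else {
      opts <- ct[[aa[i]]]
      cods[i] <- if (length(opts) == 1L) opts else sample(opts, 1L)
    }
  }
  paste(cods, collapse = "")
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Percent identity between two proteins under global alignment with BLOSUM62.
proteinIdentity <- function(a, b, type = "global") {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = type)
  Biostrings::pid(aln, type = "PID1")
}

translateCds <- function(cds) {
  n <- 3L * (nchar(cds) %/% 3L)
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(cds, 1L, n)),
                                     if.fuzzy.codon = "solve"))
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stopCodons <- c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a
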