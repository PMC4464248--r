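# Shared fixtures, built once per test run.

fixtureEnv <- new.env()

# A small forged genome with a mixture of truth categories, shared by the
# search/model/classification unit tests.
smallForge <- function() {
  if (is.null(fixtureEnv$small)) {
    fixtureEnv$small <- forgeGenome(list(
      seed = 11, nScaffolds = 3, scaffoldLength = 250000,
      geneCounts = c("TPS-a" = 5, "TPS-b1" = 4, "TPS-c" = 2,
                     "TPS-g" = 4),
      categoryProbs = c(i = 0.3, ii = 0.3, iii = 0.05, iv = 0.25,
                        v = 0.1)))
  }
  fixtureEnv$small
}

smallSearch <- function() {
  if (is.null(fixtureEnv$smallSearch)) {
    f <- smallForge()
    hsps <- seedAndExtend(f$genome, f$templates)
    loci <- mergeHitsToLoci(hsps)
    fixtureEnv$smallSearch <- list(loci = loci, hsps = attr(loci, "hsps"))
  }
  fixtureEnv$smallSearch
}

templateFor <- function(f, seedId) {
  sf <- paste0("TPS-", sub("tpl_", "", seedId))
  f$templates[[sf]]
}

# Truth row overlapping a locus (NULL when none).
truthAt <- function(f, locus) {
  g <- as.data.frame(ledgerGenes(f$ledger))
  ov <- GenomicRanges::findOverlaps(locus, ledgerRanges(f$ledger),
                                    ignore.strand = TRUE)
  if (!length(ov)) return(NULL)
  g[S4Vectors::subjectHits(ov)[1], , drop = FALSE]
}
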