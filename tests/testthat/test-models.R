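test_that("defect-free genes model at ledger coordinates with full coverage", {
  f <- smallForge(); s <- smallSearch()
  g <- as.data.frame(ledgerGenes(f$ledger))
  clean <- g$gene_id[g$truth_category == "i"]
  lr <- ledgerRanges(f$ledger)
  for (id in clean) {
    ov <- GenomicRanges::findOverlaps(lr[id], s$loci,
                                      ignore.strand = TRUE)
    li <- S4Vectors::subjectHits(ov)[1]
    m <- buildGeneModel(s$loci[li], s$hsps,
                        templateFor(f, s$loci$best_seed[li]), f$genome)
    truth <- g[g$gene_id == id, ]
    nEx <- length(strsplit(truth$exon_starts, ",")[[1]])
    expect_identical(length(modelExons(m)), nEx)
    expect_gte(modelCoverage(m), 0.99)
    es <- sort(GenomicRanges::start(modelExons(m)))
    expect_identical(es, as.integer(strsplit(truth$exon_starts, ",")[[1]]))
    ee <- sort(GenomicRanges::end(modelExons(m)))
    expect_identical(ee, as.integer(strsplit(truth$exon_ends, ",")[[1]]))
    d <- countDefects(m, templateFor(f, s$loci$best_seed[li]))
    expect_identical(c(d$n_frameshifts, d$n_premature_stops), c(0L, 0L))
    # translation consistency: protein is the translated CDS
    expect_identical(modelProtein(m),
                     as.character(Biostrings::translate(
                       Biostrings::DNAString(modelCds(m)))))
  }
})

test_that("truncated genes give partial coverage", {
  f <- smallForge(); s <- smallSearch()
  g <- as.data.frame(ledgerGenes(f$ledger))
  partial <- g$gene_id[g$truth_category == "v"]
  lr <- ledgerRanges(f$ledger)
  for (id in partial) {
    ov <- GenomicRanges::findOverlaps(lr[id], s$loci,
                                      ignore.strand = TRUE)
    li <- S4Vectors::subjectHits(ov)[1]
    m <- buildGeneModel(s$loci[li], s$hsps,
                        templateFor(f, s$loci$best_seed[li]), f$genome)
    expect_lt(modelCoverage(m), 0.9)
    expect_gt(modelCoverage(m), 0.2)
  }
})

test_that("defect counts recover the injected tallies", {
  f <- smallForge(); s <- smallSearch()
  g <- as.data.frame(ledgerGenes(f$ledger))
  ok <- 0L; n <- 0L
  for (i in which(!s$loci$excluded_few_exons)) {
    truth <- truthAt(f, s$loci[i])
    if (is.null(truth)) next
    m <- buildGeneModel(s$loci[i], s$hsps,
                        templateFor(f, s$loci$best_seed[i]), f$genome)
    d <- countDefects(m, templateFor(f, s$loci$best_seed[i]))
    n <- n + 1L
    if (d$n_frameshifts == truth$injected_frameshifts &&
        d$n_premature_stops == truth$injected_stops) ok <- ok + 1L
    expect_identical(d$n_defects, d$n_frameshifts + d$n_premature_stops)
  }
  expect_identical(n, nrow(g))
  expect_gte(ok / n, 0.9)
})

test_that("strand is immaterial: a flipped scaffold gives the same protein", {
  f <- forgeGenome(list(seed = 41, nScaffolds = 1,
                        scaffoldLength = 100000,
                        geneCounts = c("TPS-g" = 1L),
                        categoryProbs = c(i = 1)))
  flipped <- Biostrings::reverseComplement(f$genome)
  names(flipped) <- names(f$genome)
  modelOn <- function(genome) {
    hsps <- seedAndExtend(genome, f$templates)
    loci <- mergeHitsToLoci(hsps)
    hsps <- attr(loci, "hsps")
    i <- which(!loci$excluded_few_exons)[1]
    buildGeneModel(loci[i], hsps, templateFor(f, loci$best_seed[i]),
                   genome)
  }
  m1 <- modelOn(f$genome)
  m2 <- modelOn(flipped)
  expect_identical(modelProtein(m1), modelProtein(m2))
  tpl <- f$templates[["TPS-g"]]
  expect_identical(countDefects(m1, tpl)[1:3], countDefects(m2, tpl)[1:3])
})

test_that("models at scaffold ends are flagged edge-truncated", {
  f <- forgeGenome(list(seed = 43, nScaffolds = 1,
                        scaffoldLength = 100000,
                        geneCounts = c("TPS-b1" = 1L),
                        categoryProbs = c(i = 1)))
  g <- as.data.frame(ledgerGenes(f$ledger))
  # rebuild the scaffold so the gene's final exon ends at the sequence end
  chrSeq <- as.character(f$genome[[1]])
  cut <- substr(chrSeq, 1, g$end[1])
  genome <- Biostrings::DNAStringSet(c(scaffold_1 = cut))
  hsps <- seedAndExtend(genome, f$templates)
  loci <- mergeHitsToLoci(hsps)
  hsps <- attr(loci, "hsps")
  i <- which(!loci$excluded_few_exons)[1]
  m <- buildGeneModel(loci[i], hsps, templateFor(f, loci$best_seed[i]),
                      genome)
  expect_true(edgeTruncated(m))
})

test_that("exon structure summary reports modal exon counts", {
  f <- smallForge(); s <- smallSearch()
  models <- list()
  for (i in which(!s$loci$excluded_few_exons)) {
    truth <- truthAt(f, s$loci[i])
    if (is.null(truth) || truth$truth_category == "v") next
    m <- buildGeneModel(s$loci[i], s$hsps,
                        templateFor(f, s$loci$best_seed[i]), f$genome,
                        geneId = truth$gene_id)
    models[[truth$gene_id]] <- m
  }
  g <- as.data.frame(ledgerGenes(f$ledger))
  sf <- setNames(g$subfamily, g$gene_id)
  es <- exonStructureSummary(models, sf)
  modal <- setNames(es$modal$modal_exons, es$modal$subfamily)
  expect_identical(unname(modal["TPS-a"]), 7L)
  expect_identical(unname(modal["TPS-c"]), 14L)
  expect_true(all(es$introns$length > 0))
})
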