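test_that("an exact planted seed segment is recovered at full identity", {
  set.seed(21)
  tpl <- tpsTemplates()[["TPS-a"]]
  seg <- substr(templateCds(tpl), 1, 300)  # first 100 residues, in frame
  genome <- Biostrings::DNAStringSet(c(
    s1 = paste0(strrep("ACGT", 500), seg, strrep("TGCA", 500))))
  hsps <- seedAndExtend(genome, list(tpl))
  expect_gte(length(hsps), 1L)
  best <- hsps[which.max(hsps$score)]
  expect_lte(GenomicRanges::start(best), 2001L + 3L)
  expect_gte(GenomicRanges::end(best), 2300L - 3L)
  expect_identical(best$seed_id, "tpl_a")
})

test_that("a random genome yields no HSPs at the default score floor", {
  set.seed(22)
  genome <- Biostrings::DNAStringSet(c(
    rand = paste(sample(c("A", "C", "G", "T"), 10000, TRUE),
                 collapse = "")))
  hsps <- seedAndExtend(genome, tpsTemplates())
  expect_identical(length(hsps), 0L)
})

test_that("k larger than the shortest seed is a parameter error", {
  genome <- Biostrings::DNAStringSet(c(s = strrep("ACGT", 100)))
  expect_error(seedAndExtend(genome, c(tiny = "MKL"), k = 5),
               "shortest seed")
})

test_that("planted multi-exon genes produce one block per exon", {
  f <- smallForge(); s <- smallSearch()
  g <- as.data.frame(ledgerGenes(f$ledger))
  kept <- s$loci[!s$loci$excluded_few_exons]
  ov <- GenomicRanges::findOverlaps(kept, ledgerRanges(f$ledger),
                                    ignore.strand = TRUE)
  expect_identical(length(ov), nrow(g))  # every gene found, no doubles
  for (j in seq_along(ov)) {
    truth <- g[S4Vectors::subjectHits(ov)[j], ]
    nEx <- length(strsplit(truth$exon_starts, ",")[[1]])
    expect_gte(kept$block_count[S4Vectors::queryHits(ov)[j]],
               min(nEx, 3L))
  }
})

test_that("few-block loci are flagged excluded, not deleted", {
  hsps <- smallSearch()$hsps
  # two colinear HSPs 500 bp apart on one strand: one locus, two blocks
  a <- hsps[1]
  b <- GenomicRanges::shift(a, GenomicRanges::width(a) + 500L)
  b$seed_start <- a$seed_end + 10L
  b$seed_end <- b$seed_start + (a$seed_end - a$seed_start)
  loci <- mergeHitsToLoci(c(a, b))
  expect_identical(length(loci), 1L)
  expect_identical(loci$block_count, 2L)
  expect_true(loci$excluded_few_exons)
})

test_that("locus chaining is independent of HSP input order", {
  s <- smallSearch()
  set.seed(30)
  perm <- sample(length(s$hsps))
  l2 <- mergeHitsToLoci(s$hsps[perm])
  expect_identical(as.data.frame(s$loci)[, 1:8], as.data.frame(l2)[, 1:8])
})

test_that("raising the HSP score floor never increases the locus count", {
  f <- smallForge()
  counts <- vapply(c(50, 150, 400, 900), function(ms) {
    length(mergeHitsToLoci(seedAndExtend(f$genome, f$templates,
                                         minScore = ms)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("reverse confirmation accepts TPS loci and rejects controls", {
  f <- smallForge(); s <- smallSearch()
  i <- which(!s$loci$excluded_few_exons)[1]
  rc <- reverseConfirm(s$loci[i], s$hsps, f$genome, f$templates)
  expect_true(rc$confirmed)
  # an impossible identity threshold always fails
  rc2 <- reverseConfirm(s$loci[i], s$hsps, f$genome, f$templates,
                        minIdentity = 101)
  expect_false(rc2$confirmed)
  expect_error(reverseConfirm(s$loci[i], s$hsps, f$genome, list()),
               "empty")
})

test_that("a planted decoy gene is found but not confirmed as TPS", {
  fd <- forgeGenome(list(seed = 13, nScaffolds = 2,
                         scaffoldLength = 150000,
                         geneCounts = c("TPS-a" = 1L), nDecoys = 1L))
  dec <- decoyTemplate()
  withDecoySeed <- c(fd$templates[setdiff(names(fd$templates), "decoy")],
                     list(decoy = dec))
  hsps <- seedAndExtend(fd$genome, withDecoySeed)
  loci <- mergeHitsToLoci(hsps)
  hsps <- attr(loci, "hsps")
  tpsSeeds <- fd$templates[setdiff(names(fd$templates), "decoy")]
  verdicts <- vapply(seq_along(loci), function(i)
    reverseConfirm(loci[i], hsps, fd$genome, tpsSeeds,
                   decoys = list(dec))$confirmed, logical(1))
  isDecoy <- loci$best_seed == "tpl_decoy"
  expect_true(any(isDecoy))
  expect_false(any(verdicts[isDecoy]))
  expect_true(all(verdicts[!isDecoy & !loci$excluded_few_exons]))
})

test_that("a seedless 100 kb random genome yields zero confirmed loci", {
  set.seed(33)
  genome <- Biostrings::DNAStringSet(c(
    r1 = paste(sample(c("A", "C", "G", "T"), 100000, TRUE),
               collapse = "")))
  tpl <- tpsTemplates()
  hsps <- seedAndExtend(genome, tpl)
  loci <- mergeHitsToLoci(hsps)
  hsps <- attr(loci, "hsps")
  keep <- which(!loci$excluded_few_exons)
  confirmed <- vapply(keep, function(i)
    reverseConfirm(loci[i], hsps, genome, tpl)$confirmed, logical(1))
  expect_identical(sum(confirmed), 0L)
})
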