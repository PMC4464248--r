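test_that("an empty gene request yields pure intergenic scaffolds", {
  f <- forgeGenome(list(seed = 1, geneCounts = c("TPS-a" = 0L)))
  expect_identical(nrow(ledgerGenes(f$ledger)), 0L)
  expect_identical(length(f$genome), 4L)
})

test_that("a single planted category-i gene has zero injected defects", {
  f <- forgeGenome(list(seed = 2, nScaffolds = 1,
                        scaffoldLength = 100000,
                        geneCounts = c("TPS-b1" = 1L),
                        categoryProbs = c(i = 1)))
  g <- as.data.frame(ledgerGenes(f$ledger))
  expect_identical(nrow(g), 1L)
  expect_identical(g$truth_category, "i")
  expect_identical(g$injected_frameshifts + g$injected_stops, 0L)
})

test_that("forge is deterministic: same config and seed, same output", {
  cfg <- list(seed = 3, nScaffolds = 2, scaffoldLength = 150000,
              geneCounts = c("TPS-a" = 3L, "TPS-g" = 2L))
  a <- forgeGenome(cfg); b <- forgeGenome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.data.frame(ledgerGenes(a$ledger)),
                   as.data.frame(ledgerGenes(b$ledger)))
})

test_that("planted genes round-trip: ledger exons splice to the planted CDS", {
  f <- smallForge()
  g <- as.data.frame(ledgerGenes(f$ledger))
  for (i in seq_len(nrow(g))) {
    seqs <- ledgerGeneSequence(f$ledger, f$genome, g$gene_id[i])
    prot <- seqs$protein
    # terminal stop present for non-truncated genes
    if (g$truth_category[i] %in% c("i", "iii"))
      expect_identical(lengths(regmatches(
        prot, gregexpr("[*]", prot))), 1L)  # only the terminal stop
    # injected stop count shows up in the translation
    if (g$truth_category[i] %in% c("ii", "iv") &&
        g$injected_frameshifts[i] == 0L)
      expect_identical(
        lengths(regmatches(sub("[*]$", "", prot),
                           gregexpr("[*]", sub("[*]$", "", prot)))),
        g$injected_stops[i])
  }
})

test_that("introns are canonical GT..AG", {
  f <- smallForge()
  g <- as.data.frame(ledgerGenes(f$ledger))
  for (i in seq_len(nrow(g))) {
    es <- as.integer(strsplit(g$exon_starts[i], ",")[[1]])
    ee <- as.integer(strsplit(g$exon_ends[i], ",")[[1]])
    if (length(es) < 2) next
    chrSeq <- f$genome[[g$scaffold[i]]]
    for (j in seq_len(length(es) - 1)) {
      intron <- as.character(Biostrings::subseq(chrSeq, ee[j] + 1,
                                                es[j + 1] - 1))
      if (g$strand[i] == "-")
        intron <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(intron)))
      expect_identical(substr(intron, 1, 2), "GT")
      expect_identical(substr(intron, nchar(intron) - 1,
                              nchar(intron)), "AG")
    }
  }
})

test_that("truth categories respect the defect-count invariants", {
  f <- smallForge()
  g <- as.data.frame(ledgerGenes(f$ledger))
  nd <- g$injected_frameshifts + g$injected_stops
  expect_true(all(nd[g$truth_category == "iv"] > 2))
  expect_true(all(nd[g$truth_category %in% c("i", "iii", "v")] == 0))
  expect_true(all(nd[g$truth_category == "ii"] %in% 1:2))
})

test_that("oversized requests fail with a sizing error naming the scaffold", {
  expect_error(
    forgeGenome(list(seed = 1, nScaffolds = 1, scaffoldLength = 8000,
                     geneCounts = c("TPS-a" = 3L))),
    "scaffold")
})

test_that("explicit cluster geometry is honoured exactly", {
  f <- forgeGenome(list(seed = 7, nScaffolds = 1,
                        scaffoldLength = 400000,
                        geneCounts = c("TPS-a" = 0L),
                        clusters = data.frame(subfamily = "TPS-a",
                                              n = 17,
                                              span_bp = 317000)))
  cl <- as.data.frame(ledgerClusters(f$ledger))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_members, 17L)
  expect_identical(cl$span_bp, 317000L)
})

test_that("pseudogenize injects exactly the requested defects", {
  tpl <- tpsTemplates()[["TPS-a"]]
  cds <- templateCds(tpl)
  withr::with_seed(4, {
    m1 <- pseudogenize(cds, 0, 1)
    expect_identical(nchar(m1$cds), nchar(cds))  # substitution only
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(m1$cds, 1, nchar(m1$cds) - 3))))
    expect_identical(lengths(regmatches(prot, gregexpr("[*]", prot))), 1L)

    m2 <- pseudogenize(cds, 3, 0, exonLengths = exonLengths(tpl))
    expect_identical(nchar(m2$cds), nchar(cds) - 3L)
    expect_identical(sum(m2$exonLengths), nchar(m2$cds))
    expect_identical(length(m2$frameshift_pos), 3L)
    expect_true(all(diff(sort(c(m2$frameshift_pos))) > 30))
  })
  expect_error(pseudogenize(cds, 0, 0), "injection")
  expect_error(pseudogenize(substr(cds, 1, 120), 5, 5), "short")
})

test_that("ledger round-trips losslessly through TSV", {
  f <- smallForge()
  d <- withr::local_tempdir()
  writeTruthLedger(f$ledger, d)
  l2 <- readTruthLedger(d)
  expect_identical(as.data.frame(ledgerGenes(f$ledger)),
                   as.data.frame(ledgerGenes(l2)))
  expect_identical(as.data.frame(ledgerClusters(f$ledger)),
                   as.data.frame(ledgerClusters(l2)))
  expect_identical(l2@seed, f$ledger@seed)
})
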