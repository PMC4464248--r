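test_that("pairwise alignment matches a dynamic-programming oracle", {
  aln <- alignProteins(c(a = "ACDE", b = "ACE"))
  expect_identical(unique(Biostrings::width(aln)), 4L)
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  expect_identical(sum(colSums(m == "-") > 0), 1L)  # one gap column
  # the NW oracle agrees on the gap count
  o <- bruteNW("ACDE", "ACE")
  expect_identical(sum(strsplit(o[2], "")[[1]] == "-"), 1L)
})

test_that("identical sequences align without gaps; rows ungap to inputs", {
  tpl <- tpsTemplates()
  p <- templateProtein(tpl[["TPS-a"]])
  aln <- alignProteins(c(x = p, y = p))
  expect_false(any(grepl("-", as.character(aln), fixed = TRUE)))

  prots <- c(a = templateProtein(tpl[["TPS-a"]]),
             b = sub("W", "F", templateProtein(tpl[["TPS-a"]])),
             c = templateProtein(tpl[["TPS-g"]]))
  aln3 <- alignProteins(prots)
  expect_identical(length(unique(Biostrings::width(aln3))), 1L)
  for (id in names(prots))
    expect_identical(gsub("-", "", as.character(aln3[[id]])),
                     unname(prots[id]))
})

test_that("alignment truncation drops the variable N-terminal region", {
  tpl <- tpsTemplates()[["TPS-b1"]]
  p <- templateProtein(tpl)
  aln <- alignProteins(c(ref = p, other = sub("L", "V", p)))
  tr <- truncateAlignment(aln, "ref", exonLengths(tpl))
  aaEnds <- ceiling(cumsum(as.numeric(exonLengths(tpl))) / 3)
  cutRes <- ceiling((aaEnds[1] + aaEnds[2]) / 2)
  expect_identical(unique(Biostrings::width(tr)),
                   as.integer(nchar(p) - cutRes + 1))
  # idempotent
  tr2 <- truncateAlignment(tr, "ref", exonLengths(tpl))
  expect_identical(as.character(tr2), as.character(tr))
  # fallback without a map drops gappy N-terminal-third columns only
  expect_message(trF <- truncateAlignment(aln), "no exon map")
  expect_identical(unique(Biostrings::width(trF)), nchar(p))
})

test_that("NJ recovers additive topologies and the 3-taxon closed form", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    d <- stats::cophenetic(tr)
    got <- njTree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(got))), 0)
  }
  # three taxa: branch lengths solve the three-point formulas
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- njTree(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
  # duplicate taxon gives a zero-length cherry
  d4 <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6, 0), 3,
               dimnames = list(c("x1", "x2", "y"), c("x1", "x2", "y")))
  t4 <- njTree(d4)
  bl4 <- setNames(t4$edge.length, t4$tip.label[t4$edge[, 2]])
  expect_equal(unname(bl4[c("x1", "x2")]), c(0, 0))
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2)), "symmetric|3")
})

test_that("a zero-noise planted split gets 100% bootstrap support", {
  blockSeq <- function(ch1, ch2) paste0(strrep(ch1, 60), strrep(ch2, 60))
  aln <- Biostrings::AAStringSet(c(p1 = blockSeq("A", "C"),
                                   p2 = blockSeq("A", "C"),
                                   q1 = blockSeq("G", "C"),
                                   q2 = blockSeq("G", "C")))
  tr <- njTree(aln, bootstrap = 100, seed = 5)
  expect_true("100" %in% tr$node.label)
  expect_false(any(tr$edge.length < 0))
})

test_that("Kimura correction grows with divergence and falls back sanely", {
  aln <- Biostrings::AAStringSet(c(a = strrep("A", 100),
                                   b = paste0(strrep("A", 90),
                                              strrep("C", 10)),
                                   c = strrep("C", 100)))
  d <- suppressMessages(proteinDistance(aln))
  expect_gt(d["a", "c"], d["a", "b"])
  p <- proteinDistance(aln, correction = "p")
  expect_equal(p["a", "b"], 0.1)
  expect_equal(p["a", "c"], 1)  # p >= 0.85 would be undefined, kimura
  expect_message(proteinDistance(aln), "p-distance")
})

test_that("subfamily assignment follows the nearest labelled exemplar", {
  tpl <- tpsTemplates()
  ex <- vapply(tpl, templateProtein, character(1))
  names(ex) <- vapply(tpl, templateId, character(1))
  labels <- setNames(vapply(tpl, subfamily, character(1)), names(ex))
  # an exemplar queries to its own label
  r <- assignSubfamily(c(q = ex[["tpl_b2"]]), ex, labels)
  expect_identical(r$subfamily, "TPS-b2")
  expect_false(r$ambiguous)
  # forged gene from a template keeps the template's subfamily
  f <- smallForge()
  g <- as.data.frame(ledgerGenes(f$ledger))
  id <- g$gene_id[g$truth_category == "i"][1]
  prot <- sub("[*]$", "", ledgerGeneSequence(f$ledger, f$genome, id)$protein)
  r2 <- assignSubfamily(setNames(prot, id), ex, labels)
  expect_identical(r2$subfamily, g$subfamily[match(id, g$gene_id)])
  # half-and-half chimera is ambiguous
  pa <- ex[["tpl_a"]]; pg <- ex[["tpl_g"]]
  chim <- paste0(substr(pa, 1, 270), substr(pg, 271, nchar(pg)))
  r3 <- assignSubfamily(c(ch = chim), ex[c("tpl_a", "tpl_g")],
                        labels[c("tpl_a", "tpl_g")])
  expect_true(r3$ambiguous)
  expect_error(assignSubfamily(c(q = "MKL"), character(), labels),
               "exemplar|>= 1")
})
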