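tplProts <- function() {
  tpl <- tpsTemplates()
  vapply(tpl, templateProtein, character(1))
}

test_that("identical single-gene sets give one reciprocal pair at 100%", {
  p <- tplProts()[["TPS-a"]]
  pairs <- reciprocalBestPairs(c(a1 = p), c(b1 = p),
                               c(a1 = "TPS-a"), c(b1 = "TPS-a"))
  expect_identical(nrow(pairs), 1L)
  expect_equal(pairs$identity, 100)
  expect_true(pairs$reciprocal)
})

test_that("mutual-best structure is recovered from engineered identities", {
  set.seed(81)
  base <- tplProts()[["TPS-g"]]
  v1 <- tpsminer:::mutateProtein(base, 0.15)
  v2 <- tpsminer:::mutateProtein(base, 0.15)
  a <- c(a1 = tpsminer:::mutateProtein(v1, 0.02),
         a2 = tpsminer:::mutateProtein(v2, 0.02))
  b <- c(b1 = tpsminer:::mutateProtein(v1, 0.02),
         b2 = tpsminer:::mutateProtein(v2, 0.02))
  sf <- function(x) setNames(rep("TPS-g", length(x)), names(x))
  pairs <- as.data.frame(reciprocalBestPairs(a, b, sf(a), sf(b)))
  expect_identical(nrow(pairs), 2L)
  expect_setequal(paste(pairs$gene_a, pairs$gene_b),
                  c("a1 b1", "a2 b2"))
})

test_that("genes below the identity floor stay unpaired and call a loss", {
  set.seed(82)
  p <- tplProts()[["TPS-f"]]
  lone <- randomAa(nchar(p))  # unrelated protein labelled into the family
  a <- c(a1 = p, a2 = lone)
  b <- c(b1 = p)
  sfA <- c(a1 = "TPS-f", a2 = "TPS-f"); sfB <- c(b1 = "TPS-f")
  pairs <- reciprocalBestPairs(a, b, sfA, sfB)
  expect_identical(as.data.frame(pairs)$gene_a, "a1")
  orth <- summarizeOrthology(pairs, sfA, sfB)
  ev <- as.data.frame(orth$events)
  expect_true(any(ev$event == "loss" & ev$genes == "a2" &
                    ev$species == "B"))
})

test_that("pair percentages round half-up like printed proportions", {
  mkSet <- function(prefix, n, sf) {
    p <- tplProts()[[sf]]
    set.seed(83)
    out <- vapply(seq_len(n), function(i)
      tpsminer:::mutateProtein(p, 0.3), character(1))
    names(out) <- sprintf("%s%02d", prefix, seq_len(n))
    out
  }
  # direct arithmetic checks on the summary
  pairs <- S4Vectors::DataFrame(gene_a = sprintf("a%02d", 1:6),
                                gene_b = sprintf("b%02d", 1:6),
                                identity = 95, subfamily = "TPS-g",
                                reciprocal = TRUE)
  sfA <- setNames(rep("TPS-g", 13), sprintf("a%02d", 1:13))
  sfB <- setNames(rep("TPS-g", 10), sprintf("b%02d", 1:10))
  attr(pairs, "identities") <- list()
  s <- as.data.frame(summarizeOrthology(pairs, sfA, sfB)$summary)
  expect_identical(s$pct_in_pairs_A, 46)  # 6/13
  expect_identical(s$pct_in_pairs_B, 60)
})

test_that("swapping the species swaps the summary columns exactly", {
  set.seed(84)
  base <- tplProts()[["TPS-b1"]]
  a <- c(x1 = tpsminer:::mutateProtein(base, 0.05),
         x2 = tpsminer:::mutateProtein(base, 0.25))
  b <- c(y1 = tpsminer:::mutateProtein(base, 0.05))
  sfA <- setNames(rep("TPS-b1", 2), names(a))
  sfB <- setNames(rep("TPS-b1", 1), names(b))
  s1 <- as.data.frame(summarizeOrthology(
    reciprocalBestPairs(a, b, sfA, sfB), sfA, sfB)$summary)
  s2 <- as.data.frame(summarizeOrthology(
    reciprocalBestPairs(b, a, sfB, sfA), sfB, sfA)$summary)
  expect_identical(s1$n_genes_A, s2$n_genes_B)
  expect_identical(s1$n_pairs, s2$n_pairs)
  expect_identical(s1$pct_in_pairs_A, s2$pct_in_pairs_B)
})

test_that("tree topology corroborates duplications and losses", {
  # ((a1,a2),b1): same-species cherry = duplication
  t1 <- ape::read.tree(text = "((a1:1,a2:1):1,b1:2);")
  ev1 <- as.data.frame(callEvents(t1, c(a1 = "A", a2 = "A", b1 = "B")))
  expect_identical(ev1$event, "duplication")
  expect_identical(ev1$species, "A")
  # zero-divergence ortholog pair: no events
  t2 <- ape::read.tree(text = "(a1:0,b1:0);")
  expect_identical(nrow(callEvents(t2, c(a1 = "A", b1 = "B"))), 0L)
  # a leaf whose sister clade is pure own-species marks a loss
  t3 <- ape::read.tree(text = "(b1:1,(a1:1,(a2:1,a3:1):1):1);")
  ev3 <- as.data.frame(callEvents(t3, c(a1 = "A", a2 = "A", a3 = "A",
                                        b1 = "B")))
  expect_true(any(ev3$event == "loss" & ev3$genes == "a1" &
                    ev3$species == "B"))
  expect_error(callEvents(t3, c(a1 = "A")), "species map")
})

test_that("conservation: pairs plus unpaired genes equal the gene count", {
  set.seed(85)
  fp <- forgeSpeciesPair(list(seed = 5, ancestorCounts = c("TPS-e" = 3L),
                              lossProb = 0.2, duplicationProb = 0.2))
  g <- as.data.frame(ledgerGenes(fp$ledger))
  ga <- g[g$species == "A", ]; gb <- g[g$species == "B", ]
  pa <- setNames(vapply(ga$gene_id, function(id)
    sub("[*]$", "", ledgerGeneSequence(fp$ledger, fp$genomeA, id)$protein),
    character(1)), ga$gene_id)
  pb <- setNames(vapply(gb$gene_id, function(id)
    sub("[*]$", "", ledgerGeneSequence(fp$ledger, fp$genomeB, id)$protein),
    character(1)), gb$gene_id)
  sfA <- setNames(ga$subfamily, ga$gene_id)
  sfB <- setNames(gb$subfamily, gb$gene_id)
  pairs <- reciprocalBestPairs(pa, pb, sfA, sfB)
  s <- as.data.frame(summarizeOrthology(pairs, sfA, sfB)$summary)
  expect_true(all(s$n_pairs <= pmin(s$n_genes_A, s$n_genes_B)))
})
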