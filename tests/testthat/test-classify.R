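mkStats <- function(..., coverage = 1, edge = FALSE, expressed = TRUE,
                    fs = 0, stops = 0) {
  data.frame(gene_id = "g", n_frameshifts = fs, n_premature_stops = stops,
             coverage = coverage, edge_truncated = edge,
             expressed = expressed)
}

test_that("the five-category rubric fires in order", {
  expect_identical(classifyLoci(mkStats())$category, "i")
  expect_identical(classifyLoci(mkStats(fs = 1, stops = 1))$category, "ii")
  expect_identical(classifyLoci(mkStats(expressed = FALSE))$category,
                   "iii")
  expect_identical(classifyLoci(mkStats(fs = 3))$category, "iv")
  expect_identical(classifyLoci(mkStats(fs = 2, stops = 1))$category,
                   "iv")
  expect_identical(classifyLoci(mkStats(coverage = 0.4))$category, "v")
  # >2 defects wins over partial
  expect_identical(classifyLoci(mkStats(coverage = 0.4, fs = 5))$category,
                   "iv")
  # edge truncation exempts from the length rule
  expect_identical(classifyLoci(mkStats(coverage = 0.4,
                                        edge = TRUE))$category, "i")
  # unexpressed with 1-2 defects falls to iv (conservative cell)
  expect_identical(classifyLoci(mkStats(expressed = FALSE,
                                        fs = 1))$category, "iv")
  # unknown expression is treated as not expressed
  expect_identical(classifyLoci(mkStats(expressed = NA))$category, "iii")
  r <- classifyLoci(mkStats(fs = 2))
  expect_true(r$functional)
  expect_identical(classifyLoci(mkStats())$functional, TRUE)
  expect_false(classifyLoci(mkStats(fs = 3))$functional)
})

test_that("every locus receives exactly one category and counts add up", {
  set.seed(51)
  n <- 200
  stats <- data.frame(
    gene_id = sprintf("g%03d", 1:n),
    n_frameshifts = sample(0:4, n, TRUE),
    n_premature_stops = sample(0:3, n, TRUE),
    coverage = runif(n),
    edge_truncated = sample(c(TRUE, FALSE), n, TRUE, prob = c(.1, .9)),
    expressed = sample(c(TRUE, FALSE, NA), n, TRUE))
  rec <- classifyLoci(stats)
  expect_identical(nrow(rec), as.integer(n))
  expect_true(all(rec$category %in% c("i", "ii", "iii", "iv", "v")))
  fam <- summarizeFamily(rec)
  expect_identical(sum(fam$by_category), as.integer(n))
  expect_identical(fam$n_functional,
                   sum(rec$category %in% c("i", "ii", "iii")))
  # functional flag is exactly membership of i-iii
  expect_identical(rec$functional, rec$category %in% c("i", "ii", "iii"))
})

test_that("adding a defect never makes a locus more functional", {
  rank <- c(i = 1, ii = 2, iii = 3, iv = 5, v = 4)
  set.seed(52)
  for (rep in 1:50) {
    base <- data.frame(gene_id = "g",
                       n_frameshifts = sample(0:3, 1),
                       n_premature_stops = sample(0:2, 1),
                       coverage = runif(1, 0.3, 1),
                       edge_truncated = FALSE,
                       expressed = sample(c(TRUE, FALSE), 1))
    worse <- base
    worse$n_frameshifts <- worse$n_frameshifts + 1L
    c1 <- classifyLoci(base)$category
    c2 <- classifyLoci(worse)$category
    expect_gte(rank[c2], rank[c1])
  }
})

test_that("family summary reproduces printed-style totals", {
  mk <- function(cat, n) {
    fs <- switch(cat, i = 0, ii = 1, iii = 0, iv = 3, v = 0)
    data.frame(gene_id = sprintf("%s%03d", cat, seq_len(n)),
               n_frameshifts = fs, n_premature_stops = 0,
               coverage = if (cat == "v") 0.5 else 1,
               edge_truncated = FALSE,
               expressed = cat %in% c("i", "ii"))
  }
  stats <- do.call(rbind, Map(mk, c("i", "ii", "iii", "iv", "v"),
                              c(10, 4, 1, 6, 3)))
  rec <- classifyLoci(stats)
  fam <- summarizeFamily(rec)
  expect_identical(unname(fam$by_category),
                   c(10L, 4L, 1L, 6L, 3L))
  expect_identical(fam$n_functional, 15L)
  expect_identical(fam$n_pseudogene, 6L)

  # per-subfamily pseudogene split: 16 + 13 + 4 + 4 = 37
  n <- c("TPS-a" = 16, "TPS-b1" = 13, "TPS-f" = 4, "TPS-g" = 4)
  stats2 <- do.call(rbind, lapply(names(n), function(sf) {
    d <- mk("iv", n[[sf]])
    d$gene_id <- paste0(sf, "_", d$gene_id)
    d
  }))
  sf2 <- setNames(rep(names(n), n), stats2$gene_id)
  fam2 <- summarizeFamily(classifyLoci(stats2), sf2)
  expect_identical(fam2$n_pseudogene, 37L)
  expect_identical(
    setNames(fam2$by_subfamily$n_pseudogene,
             fam2$by_subfamily$subfamily)[names(n)],
    setNames(as.integer(n), names(n)))
})

test_that("missing defect columns are an input error", {
  expect_error(classifyLoci(data.frame(gene_id = "g")), "missing columns")
})
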