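# End-to-end orchestration: search -> loci -> reverse confirmation ->
# gene models -> defect counts -> expression evidence -> classification ->
# subfamily assignment -> clusters (-> orthology in two-species mode).

#' Run the full TPS mining pipeline
#'
#' Executes every stage in dependency order on one genome (optionally a
#' second genome for comparative mode) and returns all intermediate and
#' final tables. Stage-level counts (loci found, excluded by the exon
#' filter, confirmed, modelled) are recorded so filter accounting is
#' always reconstructible. With \code{outDir} set, stage artifacts are
#' written as TSV/GFF3/FASTA alongside a YAML echo of the effective
#' parameters.
#'
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param templates named list of [TpsTemplate-class] seeds (e.g.
#'   [tpsTemplates()]); their proteins are the search seeds and their
#'   CDS/exon chains guide modelling and defect counting.
#' @param fpkm optional \code{SummarizedExperiment} (or TSV path) of FPKM
#'   values; gene ids must match model ids (see \code{truthLedger} for
#'   forged data).
#' @param genomeB optional second-species genome for comparative mode.
#' @param truthLedger optional [TruthLedger-class]; when supplied, models
#'   overlapping a planted gene adopt its id (annotation transfer), which
#'   links forged FPKM rows to models and enables truth scoring.
#' @param truthLedgerB optional ledger for \code{genomeB}.
#' @param params named list of stage overrides: \code{k}, \code{xdrop},
#'   \code{minScore}, \code{maxGap}, \code{minBlocks},
#'   \code{minIdentity}, \code{expressionThreshold}, \code{maxDefects},
#'   \code{fullLengthCoverage}, \code{clusterWindow},
#'   \code{orthologyMinIdentity}.
#' @param outDir optional output directory.
#' @param decoys optional decoy proteins for reverse confirmation.
#' @return list with \code{loci}, \code{models}, \code{defects},
#'   \code{classification}, \code{subfamilies}, \code{motifs},
#'   \code{clusters}, \code{summary}, \code{expression}, \code{stageLog},
#'   and in comparative mode \code{orthology} plus the second species'
#'   tables under \code{B}.
#' @export
runTpsPipeline <- function(genome, templates, fpkm = NULL, genomeB = NULL,
                           truthLedger = NULL, truthLedgerB = NULL,
                           params = list(), outDir = NULL, decoys = NULL) {
  p <- modifyList(list(
    k = 5L, xdrop = 20, minScore = 50, maxGap = 10000L, minBlocks = 3L,
    minIdentity = 30, expressionThreshold = 1, maxDefects = 2L,
    fullLengthCoverage = 0.9, clusterWindow = 100000L,
    orthologyMinIdentity = 70), params)

  if (is.character(genome)) genome <- readGenome(genome)
  if (is.character(fpkm)) fpkm <- readFpkm(fpkm)

  resA <- mineOneGenome(genome, templates, p, decoys, truthLedger,
                        prefix = "locus")

  # expression evidence
  expr <- NULL
  evid <- rep(NA, nrow(resA$stats))
  if (!is.null(fpkm)) {
    expr <- callExpressed(fpkm, threshold = p$expressionThreshold)
    evid <- expr$expressed[match(resA$stats$gene_id, expr$gene_id)]
  }
  resA$stats$expressed <- evid
  classification <- classifyLoci(resA$stats, maxDefects = p$maxDefects,
                                 fullLengthCoverage = p$fullLengthCoverage)

  sfMap <- setNames(resA$subfamilies$subfamily,
                    resA$subfamilies$gene_id)
  fam <- summarizeFamily(classification, sfMap)

  spans <- do.call(c, unname(lapply(resA$models, modelRange)))
  clusters <- detectClusters(spans, sfMap,
                             categories = setNames(
                               classification$category,
                               classification$gene_id),
                             window = p$clusterWindow)

  prots <- vapply(resA$models, modelProtein, character(1))
  names(prots) <- vapply(resA$models, geneId, character(1))
  motifs <- motifTable(prots[nchar(prots) > 0])

  out <- list(loci = resA$loci, models = resA$models,
              defects = resA$defects, stats = resA$stats,
              classification = classification,
              subfamilies = resA$subfamilies, motifs = motifs,
              clusters = clusters, summary = fam, expression = expr,
              fpkm = fpkm, stageLog = resA$stageLog, params = p)

  if (!is.null(genomeB)) {
    if (is.character(genomeB)) genomeB <- readGenome(genomeB)
    resB <- mineOneGenome(genomeB, templates, p, decoys, truthLedgerB,
                          prefix = "locusB")
    resB$stats$expressed <- NA
    clB <- classifyLoci(resB$stats, maxDefects = p$maxDefects,
                        fullLengthCoverage = p$fullLengthCoverage)
    sfB <- setNames(resB$subfamilies$subfamily, resB$subfamilies$gene_id)
    protsB <- vapply(resB$models, modelProtein, character(1))
    names(protsB) <- vapply(resB$models, geneId, character(1))
    funcA <- classification$gene_id[classification$functional]
    funcB <- clB$gene_id[clB$functional]
    pairs <- reciprocalBestPairs(prots[intersect(funcA, names(prots))],
                                 protsB[intersect(funcB, names(protsB))],
                                 sfMap, sfB,
                                 minIdentity = p$orthologyMinIdentity)
    orth <- summarizeOrthology(pairs, sfMap[intersect(funcA, names(prots))],
                               sfB[intersect(funcB, names(protsB))],
                               minIdentity = p$orthologyMinIdentity)
    out$B <- list(models = resB$models, classification = clB,
                  subfamilies = resB$subfamilies, stageLog = resB$stageLog)
    out$orthology <- list(pairs = pairs, summary = orth$summary,
                          events = orth$events)
  }

  if (!is.null(outDir)) writePipelineOutputs(out, outDir)
  out
}

# Search, confirm and model one genome; returns per-locus stats.
mineOneGenome <- function(genome, templates, p, decoys, ledger, prefix) {
  hsps <- seedAndExtend(genome, templates, k = p$k, xdrop = p$xdrop,
                        minScore = p$minScore)
  loci <- mergeHitsToLoci(hsps, maxGap = p$maxGap,
                          minBlocks = p$minBlocks)
  hsps <- attr(loci, "hsps")
  loci$locus_id <- sprintf("%s_%03d", prefix, seq_along(loci))
  log <- list(n_hsps = length(hsps), n_loci = length(loci),
              n_excluded_few_exons = sum(loci$excluded_few_exons))

  keep <- !loci$excluded_few_exons
  confirmed <- logical(length(loci))
  for (i in which(keep)) {
    confirmed[i] <- reverseConfirm(loci[i], hsps, genome, templates,
                                   decoys = decoys,
                                   minIdentity = p$minIdentity)$confirmed
  }
  log$n_confirmed <- sum(confirmed)

  tplById <- setNames(templates,
                      vapply(templates, templateId, character(1)))
  models <- list(); defects <- list()
  for (i in which(confirmed)) {
    tpl <- tplById[[loci$best_seed[i]]]
    gid <- loci$locus_id[i]
    if (!is.null(ledger)) {
      ov <- findOverlaps(loci[i], ledgerRanges(ledger),
                         ignore.strand = TRUE)
      if (length(ov))
        gid <- names(ledgerRanges(ledger))[subjectHits(ov)[1]]
    }
    m <- buildGeneModel(loci[i], hsps, tpl, genome, geneId = gid)
    if (is.null(m)) next
    models[[gid]] <- m
    defects[[gid]] <- countDefects(m, tpl)
  }
  log$n_modelled <- length(models)

  stats <- S4Vectors::DataFrame(
    gene_id = names(models),
    n_frameshifts = vapply(defects, `[[`, integer(1), "n_frameshifts"),
    n_premature_stops = vapply(defects, `[[`, integer(1),
                               "n_premature_stops"),
    coverage = vapply(models, modelCoverage, numeric(1)),
    edge_truncated = vapply(models, edgeTruncated, logical(1)),
    expressed = NA)

  sfOfTpl <- setNames(vapply(templates, subfamily, character(1)),
                      vapply(templates, templateId, character(1)))
  subfams <- S4Vectors::DataFrame(
    gene_id = names(models),
    subfamily = unname(sfOfTpl[vapply(models, function(m) m@templateId,
                                      character(1))]))
  list(loci = loci, models = models, defects = defects, stats = stats,
       subfamilies = subfams, stageLog = log)
}

writePipelineOutputs <- function(out, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f)
    write.table(as.data.frame(df), file.path(outDir, f), sep = "\t",
                quote = FALSE, row.names = FALSE)
  lociDf <- as.data.frame(out$loci)[, c("seqnames", "start", "end",
                                        "strand", "block_count", "score",
                                        "best_seed",
                                        "excluded_few_exons", "locus_id")]
  wt(lociDf, "loci.tsv")
  wt(out$stats, "defects.tsv")
  wt(out$classification, "classification.tsv")
  wt(out$subfamilies, "subfamilies.tsv")
  wt(out$motifs, "motifs.tsv")
  wt(out$clusters, "clusters.tsv")
  wt(out$summary$by_subfamily, "summary.tsv")
  if (length(out$models)) {
    writeModelsGff3(out$models, file.path(outDir, "models.gff3"))
    prots <- vapply(out$models, modelProtein, character(1))
    writeFasta(Biostrings::AAStringSet(prots),
               file.path(outDir, "proteins.faa"))
  }
  if (!is.null(out$expression)) wt(out$expression, "expression.tsv")
  if (!is.null(out$fpkm) && nrow(out$fpkm) >= 2L) {
    bc <- biclusterExpression(out$fpkm)
    write.table(data.frame(gene_id = rownames(bc$matrix), bc$matrix,
                           check.names = FALSE),
                file.path(outDir, "heatmap_ordered.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(c(dendrogramNewick(bc$genes),
                 dendrogramNewick(bc$tissues)),
               file.path(outDir, "dendrograms.nwk"))
  }
  if (!is.null(out$orthology)) {
    wt(out$orthology$pairs, "ortholog_pairs.tsv")
    wt(out$orthology$summary, "orthology_summary.tsv")
    wt(out$orthology$events, "orthology_events.tsv")
  }
  write_yaml(out$params, file.path(outDir, "params.yaml"))
  invisible(outDir)
}
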