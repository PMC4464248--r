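# Synthetic-genome forge. Plants multi-exon TPS-like genes (GT..AG introns,
# subfamily-typical exon counts) on random-intergenic scaffolds, injects
# pseudogenizing defects, lays out tandem clusters, and emits a truth
# ledger against which every pipeline stage can be scored.

forgeDefaults <- function() {
  list(
    seed = 1L,
    nScaffolds = 4L,
    scaffoldLength = 200000L,
    geneCounts = c("TPS-a" = 6L, "TPS-b1" = 4L, "TPS-b2" = 2L,
                   "TPS-c" = 1L, "TPS-e" = 1L, "TPS-f" = 2L,
                   "TPS-g" = 3L),
    categoryProbs = c(i = 0.52, ii = 0.13, iii = 0.01, iv = 0.22,
                      v = 0.12),
    substitutionRate = 0.05,
    gc = 0.5,
    runSize = c(2L, 6L),
    withinClusterGap = c(500L, 8000L),
    betweenRunGap = c(20000L, 50000L),
    intronRange = c(70L, 300L),
    intron1Range = c(100L, 1500L),
    nDecoys = 0L,
    templates = NULL,
    clusters = NULL)
}

#' Forge a genome with planted TPS genes and a truth ledger
#'
#' Generates \code{nScaffolds} scaffolds of i.i.d. intergenic sequence
#' (GC configurable) and plants the requested number of genes per
#' subfamily. Genes are laid out in same-subfamily tandem runs; truth
#' categories are drawn from \code{categoryProbs}: category ii genes get
#' 1-2 injected defects, category iv genes more than two, category v
#' genes are planted with only a 5' subset of their exons. Introns are
#' canonical GT..AG. Every planted gene, cluster and injection is recorded
#' in the returned [TruthLedger-class]; the same config and seed always
#' reproduce the identical genome and ledger.
#'
#' Explicit cluster geometry can be requested through
#' \code{config$clusters}, a data frame with columns \code{subfamily},
#' \code{n} and \code{span_bp} (optionally \code{scaffold}): \code{n}
#' genes are placed so that the distance from the start of the first to
#' the end of the last equals \code{span_bp} exactly.
#'
#' @param config named list overriding the forge defaults (see
#'   \code{tpsminer:::forgeDefaults()}): \code{seed}, \code{nScaffolds},
#'   \code{scaffoldLength}, per-subfamily \code{geneCounts},
#'   \code{categoryProbs}, \code{substitutionRate}, \code{gc}, tandem-run
#'   geometry, intron length ranges, \code{nDecoys}, \code{templates},
#'   \code{clusters}.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{ledger}
#'   ([TruthLedger-class]) and \code{templates}.
#' @export
forgeGenome <- function(config = list()) {
  cfg <- modifyList(forgeDefaults(), config)
  unknown <- setdiff(names(config), names(forgeDefaults()))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  if (any(unlist(cfg$geneCounts) < 0)) stop("gene counts must be >= 0")
  withSeed(cfg$seed, forgeGenomeImpl(cfg))
}

forgeGenomeImpl <- function(cfg, genePrefix = "gene_",
                            fixedGenes = NULL) {
  templates <- cfg$templates %||% tpsTemplates()
  scLen <- rep(as.integer(cfg$scaffoldLength), length.out = cfg$nScaffolds)
  scNames <- sprintf("scaffold_%d", seq_len(cfg$nScaffolds))

  # ---- build the list of gene instances to place ----
  instances <- list()
  if (is.null(fixedGenes)) {
    for (sf in names(cfg$geneCounts)) {
      n <- as.integer(cfg$geneCounts[[sf]])
      if (n == 0L) next
      if (!sf %in% names(templates))
        stop("no template for requested subfamily ", sf)
      cats <- sample(names(cfg$categoryProbs), n, replace = TRUE,
                     prob = cfg$categoryProbs)
      for (i in seq_len(n))
        instances[[length(instances) + 1L]] <- list(
          subfamily = sf, category = cats[i], explicit = NA)
    }
    if (cfg$nDecoys > 0L) {
      for (i in seq_len(cfg$nDecoys))
        instances[[length(instances) + 1L]] <- list(
          subfamily = "decoy", category = "i", explicit = NA)
      templates[["decoy"]] <- decoyTemplate()
    }
    if (!is.null(cfg$clusters)) {
      cl <- as.data.frame(cfg$clusters)
      for (r in seq_len(nrow(cl))) {
        for (i in seq_len(cl$n[r]))
          instances[[length(instances) + 1L]] <- list(
            subfamily = cl$subfamily[r],
            category = sample(names(cfg$categoryProbs), 1L,
                              prob = cfg$categoryProbs),
            explicit = r)
      }
    }
  } else {
    instances <- fixedGenes  # pre-instantiated (species-pair forge)
  }

  # instantiate sequence content for every gene
  built <- lapply(instances, function(inst) {
    if (!is.null(inst$prebuilt)) return(inst)
    tpl <- templates[[inst$subfamily]]
    g <- instantiateGene(tpl, inst$category, cfg$substitutionRate,
                         cfg$intronRange, cfg$intron1Range)
    c(inst, g)
  })

  # ---- layout ----
  # explicit clusters first, then default tandem runs per subfamily
  cursors <- rep(1000L, cfg$nScaffolds)
  placements <- list()
  placeRun <- function(idx) {
    widths <- vapply(built[idx], function(b) nchar(b$seq), integer(1))
    leadGap <- sample(cfg$betweenRunGap[1]:cfg$betweenRunGap[2], 1L)
    gaps <- if (length(idx) > 1L)
      sample(cfg$withinClusterGap[1]:cfg$withinClusterGap[2],
             length(idx) - 1L, replace = TRUE) else integer()
    need <- leadGap + sum(widths) + sum(gaps) + 1000L
    fits <- which(cursors + need <= scLen)
    if (!length(fits))
      stop(sprintf("cannot place %d gene(s) on %s: scaffold too short",
                   length(idx), scNames[which.min(cursors)]))
    scaffold <- fits[which.min(cursors[fits])]
    st <- cursors[scaffold] + leadGap
    for (j in seq_along(idx)) {
      en <- st + widths[j] - 1L
      placements[[length(placements) + 1L]] <<- list(
        idx = idx[j], scaffold = scaffold, start = st, end = en)
      cursors[scaffold] <<- en
      if (j < length(idx)) st <- en + gaps[j] + 1L
    }
  }

  explicitIds <- vapply(built, function(b)
    if (is.null(b$explicit)) NA_integer_ else as.integer(b$explicit),
    integer(1))
  if (!is.null(cfg$clusters)) {
    cl <- as.data.frame(cfg$clusters)
    for (r in seq_len(nrow(cl))) {
      idx <- which(explicitIds == r)
      widths <- vapply(built[idx], function(b) nchar(b$seq), integer(1))
      span <- as.integer(cl$span_bp[r])
      slack <- span + 1L - sum(widths)
      nGaps <- length(idx) - 1L
      if (nGaps > 0L && slack < nGaps)
        stop("cluster span too small for ", length(idx), " genes")
      gaps <- if (nGaps > 0L) {
        g <- rep(slack %/% nGaps, nGaps)
        extra <- slack - sum(g)
        if (extra > 0L) g[seq_len(extra)] <- g[seq_len(extra)] + 1L
        g
      } else integer()
      scaffold <- if ("scaffold" %in% names(cl) && !is.na(cl$scaffold[r]))
        match(cl$scaffold[r], scNames) else which.min(cursors)
      if (is.na(scaffold)) stop("unknown scaffold in cluster spec")
      st <- cursors[scaffold] + 2000L
      for (j in seq_along(idx)) {
        en <- st + widths[j] - 1L
        if (en > scLen[scaffold] - 1000L)
          stop(sprintf("cannot place cluster on %s: scaffold too short",
                       scNames[scaffold]))
        placements[[length(placements) + 1L]] <- list(
          idx = idx[j], scaffold = scaffold, start = st, end = en)
        cursors[scaffold] <- en
        if (j <= length(gaps)) st <- en + gaps[j] + 1L
      }
    }
  }

  defaultIdx <- which(is.na(explicitIds))
  bySf <- split(defaultIdx,
                vapply(built[defaultIdx], `[[`, character(1), "subfamily"))
  for (sf in names(bySf)) {
    idx <- bySf[[sf]]
    # chunk into tandem runs
    while (length(idx)) {
      size <- min(length(idx), sample(cfg$runSize[1]:cfg$runSize[2], 1L))
      run <- idx[seq_len(size)]
      idx <- idx[-seq_len(size)]
      placeRun(run)
    }
  }

  # ---- assemble scaffolds ----
  seqs <- character(cfg$nScaffolds)
  for (s in seq_len(cfg$nScaffolds)) {
    pl <- Filter(function(p) p$scaffold == s, placements)
    pl <- pl[order(vapply(pl, `[[`, integer(1), "start"))]
    frags <- character(); pos <- 1L
    for (p in pl) {
      frags <- c(frags, randomDna(p$start - pos, cfg$gc),
                 built[[p$idx]]$seq)
      pos <- p$end + 1L
    }
    frags <- c(frags, randomDna(scLen[s] - pos + 1L, cfg$gc))
    seqs[s] <- paste(frags, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- scNames

  # ---- ledger ----
  ord <- order(vapply(placements, `[[`, integer(1), "scaffold"),
               vapply(placements, `[[`, integer(1), "start"))
  placements <- placements[ord]
  rows <- lapply(seq_along(placements), function(i) {
    p <- placements[[i]]
    b <- built[[p$idx]]
    exS <- p$start + b$exonStarts - 1L
    exE <- p$start + b$exonEnds - 1L
    if (b$strand == "-") {
      w <- nchar(b$seq)
      tmp <- p$start + (w - b$exonEnds)
      exE <- p$start + (w - b$exonStarts)
      exS <- tmp
      o <- order(exS); exS <- exS[o]; exE <- exE[o]
    }
    data.frame(
      gene_id = sprintf("%s%03d", genePrefix, i),
      scaffold = scNames[p$scaffold],
      start = p$start, end = p$end, strand = b$strand,
      subfamily = b$subfamily,
      template_id = templateId(templates[[b$subfamily]]),
      truth_category = b$category,
      injected_frameshifts = b$nFs, injected_stops = b$nStops,
      is_expressed_truth = b$expressed,
      ortholog_of = b$ortholog %||% NA_character_,
      species = b$species %||% NA_character_,
      exon_starts = paste(exS, collapse = ","),
      exon_ends = paste(exE, collapse = ","),
      stringsAsFactors = FALSE)
  })
  genes <- S4Vectors::DataFrame(do.call(rbind, rows))

  clusters <- ledgerClusterTable(genes)
  ledger <- new("TruthLedger", genes = genes, clusters = clusters,
                events = S4Vectors::DataFrame(event = character(),
                                              species = character(),
                                              genes = character(),
                                              subfamily = character()),
                seed = as.integer(cfg$seed))
  list(genome = genome, ledger = ledger, templates = templates,
       instanceIndex = vapply(placements, `[[`, integer(1), "idx"))
}

# tandem runs of >= 2 same-subfamily genes with gaps <= 100 kb
ledgerClusterTable <- function(genes, window = 100000L) {
  rows <- list()
  df <- as.data.frame(genes)
  df <- df[df$subfamily != "decoy", , drop = FALSE]
  for (grp in split(seq_len(nrow(df)),
                    paste(df$scaffold, df$subfamily))) {
    grp <- grp[order(df$start[grp])]
    if (length(grp) < 2L) next
    gaps <- df$start[grp][-1] - df$end[grp][-length(grp)]
    cid <- cumsum(c(1L, gaps > window))
    for (run in split(grp, cid)) {
      if (length(run) < 2L) next
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = df$scaffold[run[1]],
        subfamily = df$subfamily[run[1]],
        members = paste(df$gene_id[run], collapse = ","),
        n_members = length(run),
        span_bp = max(df$end[run]) - min(df$start[run]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) S4Vectors::DataFrame(do.call(rbind, rows))
  else S4Vectors::DataFrame(scaffold = character(),
                            subfamily = character(),
                            members = character(), n_members = integer(),
                            span_bp = numeric())
}

# Build one gene instance: mutated protein, back-translated CDS, injected
# defects, exon/intron layout, random strand.
instantiateGene <- function(template, category, substitutionRate,
                            intronRange, intron1Range,
                            protein = NULL) {
  tplProt <- templateProtein(template)
  tplCds <- templateCds(template)
  prot <- protein %||% mutateProtein(tplProt, substitutionRate)
  L3 <- 3L * nchar(prot)
  cds <- paste0(backTranslate(prot, tplProt, tplCds),
                substr(tplCds, L3 + 1L, L3 + 3L))
  exonLens <- exonLengths(template)

  nFs <- 0L; nStops <- 0L
  if (category == "v") {
    keep <- max(3L, floor(0.5 * length(exonLens)))
    exonLens <- exonLens[seq_len(keep)]
    newLen <- 3L * (sum(exonLens) %/% 3L)
    exonLens[keep] <- exonLens[keep] - (sum(exonLens) - newLen)
    cds <- substr(cds, 1L, newLen)
  } else if (category %in% c("ii", "iv")) {
    nDef <- if (category == "ii") sample(1:2, 1L) else sample(3:5, 1L)
    nFs <- sample(0:nDef, 1L)
    nStops <- nDef - nFs
    mut <- pseudogenize(cds, nFs, nStops, exonLengths = exonLens)
    cds <- mut$cds
    exonLens <- mut$exonLengths
  }

  nEx <- length(exonLens)
  introns <- character(max(0L, nEx - 1L))
  if (nEx > 1L) {
    for (j in seq_len(nEx - 1L)) {
      rng <- if (j == 1L) intron1Range else intronRange
      len <- sample(rng[1]:rng[2], 1L)
      introns[j] <- paste0("GT", randomDna(len - 4L), "AG")
    }
  }
  cum <- cumsum(exonLens)
  exCds <- substring(cds, c(1L, cum[-nEx] + 1L), cum)
  pieces <- character(0)
  exonStarts <- integer(nEx); exonEnds <- integer(nEx); pos <- 1L
  for (j in seq_len(nEx)) {
    exonStarts[j] <- pos
    exonEnds[j] <- pos + nchar(exCds[j]) - 1L
    pieces <- c(pieces, exCds[j])
    pos <- exonEnds[j] + 1L
    if (j < nEx) {
      pieces <- c(pieces, introns[j])
      pos <- pos + nchar(introns[j])
    }
  }
  seq <- paste(pieces, collapse = "")
  strand <- sample(c("+", "-"), 1L)
  if (strand == "-") seq <- revComp(seq)
  expressed <- switch(category,
                      i = TRUE, ii = TRUE, iii = FALSE,
                      runif(1) < 0.5)
  list(seq = seq, strand = strand, exonStarts = exonStarts,
       exonEnds = exonEnds, cds = cds, nFs = nFs, nStops = nStops,
       expressed = expressed, category = category)
}

#' Inject frameshifts and premature stop codons into a CDS
#'
#' Injects exactly \code{nFrameshifts} single-base deletions and
#' \code{nStops} in-frame stop-codon substitutions at uniformly drawn
#' positions within the central portion of the CDS, no two injections
#' within \code{minSeparation} bp of each other (so one event is never
#' counted twice downstream). Deletions are applied after substitutions,
#' from the 3' end, so all recorded positions refer to the original CDS.
#'
#' @param cds coding sequence (character scalar).
#' @param nFrameshifts number of 1-bp deletions.
#' @param nStops number of stop-codon substitutions.
#' @param exonLengths optional exon-length chain summing to
#'   \code{nchar(cds)}; returned adjusted for the deletions.
#' @param region fraction interval of the CDS eligible for injection.
#' @param minSeparation minimum pairwise distance between injections, bp.
#' @return list: \code{cds}, \code{exonLengths},
#'   \code{frameshift_pos}, \code{stop_pos} (original-CDS offsets).
#' @export
pseudogenize <- function(cds, nFrameshifts, nStops, exonLengths = NULL,
                         region = c(0.1, 0.85), minSeparation = 34L) {
  nFrameshifts <- as.integer(nFrameshifts); nStops <- as.integer(nStops)
  stopifnot(nFrameshifts >= 0L, nStops >= 0L)
  if (nFrameshifts + nStops < 1L)
    stop("at least one injection required")
  len <- nchar(cds)
  lo <- ceiling(region[1] * len); hi <- floor(region[2] * len)
  if (hi - lo < (nFrameshifts + nStops) * minSeparation)
    stop("CDS too short to host the requested injections")
  n <- nFrameshifts + nStops
  pos <- integer(0)
  for (tries in seq_len(2000L)) {
    cand <- sample(lo:hi, 1L)
    if (all(abs(cand - pos) > minSeparation)) pos <- c(pos, cand)
    if (length(pos) == n) break
  }
  if (length(pos) < n)
    stop("CDS too short to host the requested injections")
  pos <- sample(pos)  # random assignment to defect types
  stopPos <- sort(pos[seq_len(nStops)])
  fsPos <- sort(pos[seq_len(nFrameshifts) + nStops])

  chars <- strsplit(cds, "")[[1]]
  stopCodonPos <- integer(0)
  for (p in stopPos) {
    cidx <- (p - 1L) %/% 3L + 1L
    at <- 3L * cidx - 2L
    chars[at:(at + 2L)] <- strsplit(sample(stopCodons, 1L), "")[[1]]
    stopCodonPos <- c(stopCodonPos, at)
  }
  for (p in rev(fsPos)) chars <- chars[-p]
  out <- paste(chars, collapse = "")

  if (!is.null(exonLengths)) {
    stopifnot(sum(exonLengths) == len)
    cum <- cumsum(exonLengths)
    for (p in fsPos) {
      e <- which(cum >= p)[1]
      exonLengths[e] <- exonLengths[e] - 1L
    }
  }
  list(cds = out, exonLengths = exonLengths,
       frameshift_pos = fsPos, stop_pos = stopCodonPos)
}

#' Forge two genomes diverged from a common ancestor
#'
#' Draws an ancestral gene set (per-subfamily counts, each ancestor a
#' divergent copy of its subfamily template), then evolves two lineages:
#' each ancestor is lost in a lineage with probability \code{lossProb},
#' duplicated with probability \code{duplicationProb}, and accumulates
#' amino-acid substitutions at \code{lineageDivergence} per site
#' (duplicates get \code{duplicationDivergence} extra). Surviving
#' cross-lineage copies are linked as orthologs (symmetric
#' \code{ortholog_of}); duplications and losses are recorded as events.
#' Both gene sets are planted into genomes exactly as [forgeGenome()]
#' does.
#'
#' @param config list overriding defaults: \code{seed},
#'   \code{ancestorCounts}, \code{lossProb}, \code{duplicationProb},
#'   \code{ancestralDivergence}, \code{lineageDivergence},
#'   \code{duplicationDivergence}, plus [forgeGenome()] layout settings.
#' @return list with \code{genomeA}, \code{genomeB}, \code{ledger}
#'   (genes of both species, \code{species} column set), and
#'   \code{templates}.
#' @export
forgeSpeciesPair <- function(config = list()) {
  defaults <- modifyList(forgeDefaults(), list(
    nScaffolds = 3L, scaffoldLength = 400000L,
    ancestorCounts = c("TPS-a" = 8L, "TPS-b1" = 6L, "TPS-b2" = 3L,
                       "TPS-c" = 2L, "TPS-e" = 2L, "TPS-f" = 4L,
                       "TPS-g" = 4L),
    lossProb = 0.1, duplicationProb = 0.1,
    ancestralDivergence = 0.2, lineageDivergence = 0.03,
    duplicationDivergence = 0.01))
  cfg <- modifyList(defaults, config)
  if (!length(cfg$ancestorCounts) || sum(unlist(cfg$ancestorCounts)) == 0)
    stop("ancestor gene set is empty")
  withSeed(cfg$seed, {
    templates <- cfg$templates %||% tpsTemplates()
    cfg$templates <- templates

    perLineage <- list(A = list(), B = list())
    events <- list()
    anc <- 0L
    for (sf in names(cfg$ancestorCounts)) {
      tpl <- templates[[sf]]
      for (i in seq_len(cfg$ancestorCounts[[sf]])) {
        anc <- anc + 1L
        ancId <- sprintf("anc%03d", anc)
        ancProt <- mutateProtein(templateProtein(tpl),
                                 cfg$ancestralDivergence)
        copies <- list(A = NULL, B = NULL)
        for (sp in c("A", "B")) {
          if (runif(1) < cfg$lossProb) {
            events[[length(events) + 1L]] <- data.frame(
              event = "loss", species = sp, genes = ancId,
              subfamily = sf)
            next
          }
          base <- mutateProtein(ancProt, cfg$lineageDivergence)
          if (runif(1) < cfg$duplicationProb) {
            copies[[sp]] <- c(
              mutateProtein(base, cfg$duplicationDivergence),
              mutateProtein(base, cfg$duplicationDivergence))
          } else copies[[sp]] <- base
        }
        for (sp in c("A", "B")) {
          prots <- copies[[sp]]
          if (is.null(prots)) next
          if (length(prots) == 2L)
            events[[length(events) + 1L]] <- data.frame(
              event = "duplication", species = sp, genes = ancId,
              subfamily = sf)
          for (ci in seq_along(prots)) {
            perLineage[[sp]][[length(perLineage[[sp]]) + 1L]] <- list(
              subfamily = sf, category = "i", explicit = NA,
              ancestor = ancId, primary = ci == 1L,
              protein = prots[ci], species = sp)
          }
        }
      }
    }

    buildSide <- function(side, prefix) {
      insts <- lapply(perLineage[[side]], function(x) {
        g <- instantiateGene(templates[[x$subfamily]], "i",
                             substitutionRate = 0,
                             cfg$intronRange, cfg$intron1Range,
                             protein = x$protein)
        c(x, g, list(prebuilt = TRUE))
      })
      forgeGenomeImpl(modifyList(cfg, list(geneCounts = integer(),
                                           clusters = NULL)),
                      genePrefix = prefix, fixedGenes = insts)
    }
    A <- buildSide("A", "A_g")
    B <- buildSide("B", "B_g")

    gA <- A$ledger@genes; gA$species <- "A"
    gB <- B$ledger@genes; gB$species <- "B"
    # ortholog links: primary copy of each surviving ancestor, symmetric
    ancA <- vapply(perLineage$A, `[[`, character(1), "ancestor")
    priA <- vapply(perLineage$A, `[[`, logical(1), "primary")
    ancB <- vapply(perLineage$B, `[[`, character(1), "ancestor")
    priB <- vapply(perLineage$B, `[[`, logical(1), "primary")
    # gene rows are sorted by position; map back through placement order
    gA$ancestor <- ancA[A$instanceIndex]; gA$primary <- priA[A$instanceIndex]
    gB$ancestor <- ancB[B$instanceIndex]; gB$primary <- priB[B$instanceIndex]
    for (id in intersect(gA$ancestor[gA$primary], gB$ancestor[gB$primary])) {
      ia <- which(gA$ancestor == id & gA$primary)
      ib <- which(gB$ancestor == id & gB$primary)
      gA$ortholog_of[ia] <- gB$gene_id[ib]
      gB$ortholog_of[ib] <- gA$gene_id[ia]
    }
    genes <- rbind(gA, gB)
    ev <- if (length(events)) S4Vectors::DataFrame(do.call(rbind, events))
          else S4Vectors::DataFrame(event = character(),
                                    species = character(),
                                    genes = character(),
                                    subfamily = character())
    ledger <- new("TruthLedger", genes = genes,
                  clusters = rbind(A$ledger@clusters, B$ledger@clusters),
                  events = ev, seed = as.integer(cfg$seed))
    list(genomeA = A$genome, genomeB = B$genome, ledger = ledger,
         templates = templates)
  })
}

#' Forge a tissue FPKM matrix from a truth ledger
#'
#' Expressed genes are assigned an expression archetype (green-tissue
#' high, root high, wood high, constitutive, or uniformly low) and each
#' tissue-replicate value is the archetype mean scaled by log-normal
#' noise; replicate columns of one tissue share the archetype mean.
#' Genes whose truth says unexpressed draw uniform values strictly below
#' an FPKM of 0.5 in every column.
#'
#' @param ledger a [TruthLedger-class].
#' @param tissues tissue labels (default: the seven-tissue panel young
#'   leaf, shoot tip, mature leaf, flower, root, phloem, xylem).
#' @param replicates replicates per tissue.
#' @param archetypes named list of per-tissue mean FPKM vectors; defaults
#'   provided for the default tissue panel.
#' @param archetypeProbs sampling weights over the archetypes.
#' @param noiseSd log-normal noise standard deviation (natural log
#'   scale); must be non-negative.
#' @param seed RNG seed.
#' @return \code{SummarizedExperiment} with assay \code{fpkm}, colData
#'   \code{tissue}/\code{replicate} and rowData \code{archetype}.
#' @export
forgeFpkm <- function(ledger, tissues = c("YL", "ST", "ML", "Fl", "Rt",
                                          "Ph", "Xy"),
                      replicates = 3L, archetypes = NULL,
                      archetypeProbs = NULL, noiseSd = 0.25, seed = 1L) {
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  genes <- as.data.frame(ledgerGenes(ledger))
  if (is.null(archetypes)) {
    if (!identical(tissues, c("YL", "ST", "ML", "Fl", "Rt", "Ph", "Xy")))
      stop("custom tissues require explicit archetypes")
    archetypes <- list(
      green = c(YL = 60, ST = 40, ML = 60, Fl = 30, Rt = 2, Ph = 2,
                Xy = 2),
      root = c(YL = 2, ST = 2, ML = 2, Fl = 2, Rt = 80, Ph = 3, Xy = 3),
      wood = c(YL = 2, ST = 3, ML = 2, Fl = 2, Rt = 3, Ph = 40, Xy = 45),
      constitutive = c(YL = 30, ST = 30, ML = 30, Fl = 30, Rt = 30,
                       Ph = 30, Xy = 30),
      low = c(YL = 2, ST = 2, ML = 2, Fl = 2, Rt = 2, Ph = 2, Xy = 2))
  }
  bad <- vapply(archetypes, function(a) any(a < 0), logical(1))
  if (any(bad)) stop("archetype profiles must be non-negative")
  probs <- archetypeProbs %||%
    setNames(rep(1 / length(archetypes), length(archetypes)),
             names(archetypes))
  if (is.null(archetypeProbs) &&
      all(c("green", "root", "wood", "constitutive", "low") %in%
            names(archetypes)))
    probs <- c(green = 0.45, root = 0.2, wood = 0.15,
               constitutive = 0.05, low = 0.15)

  withSeed(seed, {
    nG <- nrow(genes)
    cols <- paste0(rep(tissues, each = replicates), "_",
                   rep(seq_len(replicates), length(tissues)))
    m <- matrix(0, nG, length(cols),
                dimnames = list(genes$gene_id, cols))
    arch <- character(nG)
    for (i in seq_len(nG)) {
      if (isTRUE(genes$is_expressed_truth[i])) {
        a <- sample(names(archetypes), 1L, prob = probs[names(archetypes)])
        arch[i] <- a
        mu <- archetypes[[a]][tissues]
        vals <- rep(mu, each = replicates) *
          exp(rnorm(length(cols), 0, noiseSd))
        m[i, ] <- vals
      } else {
        arch[i] <- "silent"
        m[i, ] <- runif(length(cols), 0, 0.5)
      }
    }
    se <- fpkmExperiment(m)
    rowData(se)$archetype <- arch
    se
  })
}
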