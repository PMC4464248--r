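# Two-species orthology: reciprocal best hits within subfamilies,
# per-subfamily pair proportions, and duplication/loss calls.

#' Reciprocal-best-hit ortholog pairs between two species
#'
#' All-vs-all global alignment identities are computed within each shared
#' subfamily; a pair (a, b) is kept iff b is a's best hit, a is b's best
#' hit, and the identity reaches \code{minIdentity}. Ties resolve to the
#' lexicographically smallest gene id, making output deterministic. An
#' empty gene set on either side yields an empty result, not an error.
#'
#' @param proteinsA,proteinsB named character vectors (or
#'   \code{AAStringSet}) of the two species' proteins.
#' @param subfamA,subfamB named character vectors mapping gene ids to
#'   subfamilies.
#' @param minIdentity percent-identity floor for a pair.
#' @return \code{DataFrame}: \code{gene_a}, \code{gene_b},
#'   \code{identity}, \code{subfamily}, \code{reciprocal}. The
#'   per-subfamily identity matrices are attached as attribute
#'   \code{"identities"} (lists \code{AB}, \code{AA}, \code{BB}) for
#'   downstream event calling.
#' @export
reciprocalBestPairs <- function(proteinsA, proteinsB, subfamA, subfamB,
                                minIdentity = 70) {
  proteinsA <- asProteinVector(proteinsA)
  proteinsB <- asProteinVector(proteinsB)
  rows <- list()
  idStore <- list()
  shared <- intersect(unique(subfamA), unique(subfamB))
  for (sf in sort(shared)) {
    a <- sort(names(proteinsA)[subfamA[names(proteinsA)] %in% sf])
    b <- sort(names(proteinsB)[subfamB[names(proteinsB)] %in% sf])
    if (!length(a) || !length(b)) next
    AB <- identityMatrix(proteinsA[a], proteinsB[b])
    AA <- identityMatrix(proteinsA[a], proteinsA[a])
    BB <- identityMatrix(proteinsB[b], proteinsB[b])
    idStore[[sf]] <- list(AB = AB, AA = AA, BB = BB)
    bestForA <- colnames(AB)[apply(AB, 1L, which.max)]
    bestForB <- rownames(AB)[apply(AB, 2L, which.max)]
    for (i in seq_along(a)) {
      bb <- bestForA[i]
      if (bestForB[match(bb, b)] == a[i] &&
          AB[a[i], bb] >= minIdentity) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = a[i], gene_b = bb,
          identity = AB[a[i], bb], subfamily = sf)
      }
    }
  }
  out <- if (length(rows)) S4Vectors::DataFrame(do.call(rbind, rows))
         else S4Vectors::DataFrame(gene_a = character(),
                                   gene_b = character(),
                                   identity = numeric(),
                                   subfamily = character())
  out$reciprocal <- rep(TRUE, nrow(out))
  attr(out, "identities") <- idStore
  out
}

asProteinVector <- function(x) {
  if (methods::is(x, "AAStringSet")) setNames(as.character(x), names(x))
  else x
}

# identity matrix with ties broken deterministically by lexicographic id
identityMatrix <- function(a, b) {
  m <- matrix(0, length(a), length(b), dimnames = list(names(a), names(b)))
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (identical(names(a)[i], names(b)[j])) { m[i, j] <- -Inf; next }
    m[i, j] <- proteinIdentity(a[[i]], b[[j]])
  }
  m
}

#' Per-subfamily orthology summary with duplication and loss calls
#'
#' For each subfamily: gene counts on both sides, reciprocal pair count,
#' and the percentage of each species' genes found in pairs (integer,
#' rounded half up, matching how such proportions are conventionally
#' printed). A duplication is called when two same-species genes are
#' mutual best hits within their species and both are closer to each other
#' than to any cross-species gene. A loss is called for every gene with no
#' cross-species hit at or above \code{minIdentity}.
#'
#' @param pairs output of [reciprocalBestPairs()] (carrying the identity
#'   matrices attribute).
#' @param subfamA,subfamB named subfamily maps for the two species' gene
#'   sets.
#' @param minIdentity identity floor used for loss calls.
#' @return list with \code{summary} (\code{DataFrame}, one row per
#'   subfamily) and \code{events} (\code{DataFrame} of duplication/loss
#'   calls).
#' @export
summarizeOrthology <- function(pairs, subfamA, subfamB, minIdentity = 70) {
  ids <- attr(pairs, "identities")
  pairs <- as.data.frame(pairs)
  sfl <- sort(union(unique(subfamA), unique(subfamB)))
  sumRows <- list(); evRows <- list()
  for (sf in sfl) {
    a <- sort(names(subfamA)[subfamA == sf])
    b <- sort(names(subfamB)[subfamB == sf])
    p <- pairs[pairs$subfamily == sf, , drop = FALSE]
    nP <- nrow(p)
    sumRows[[length(sumRows) + 1L]] <- data.frame(
      subfamily = sf, n_genes_A = length(a), n_genes_B = length(b),
      n_pairs = nP,
      pct_in_pairs_A = if (length(a)) roundHalfUp(100 * nP / length(a))
                       else NA_real_,
      pct_in_pairs_B = if (length(b)) roundHalfUp(100 * nP / length(b))
                       else NA_real_)
    im <- ids[[sf]]
    if (is.null(im)) {
      # subfamily absent on one side: every gene on the other is a loss
      for (g in a) evRows[[length(evRows) + 1L]] <-
          data.frame(event = "loss", species = "B", genes = g,
                     subfamily = sf)
      for (g in b) evRows[[length(evRows) + 1L]] <-
          data.frame(event = "loss", species = "A", genes = g,
                     subfamily = sf)
      next
    }
    # loss: no cross-species hit above threshold
    for (g in a) {
      if (all(im$AB[g, ] < minIdentity))
        evRows[[length(evRows) + 1L]] <- data.frame(
          event = "loss", species = "B", genes = g, subfamily = sf)
    }
    for (g in b) {
      if (all(im$AB[, g] < minIdentity))
        evRows[[length(evRows) + 1L]] <- data.frame(
          event = "loss", species = "A", genes = g, subfamily = sf)
    }
    # duplication: same-species mutual best hits beating all cross hits
    dupCalls <- function(W, cross, species, byRow) {
      if (nrow(W) < 2L) return()
      bestW <- colnames(W)[apply(W, 1L, which.max)]
      for (i in seq_len(nrow(W))) {
        g1 <- rownames(W)[i]; g2 <- bestW[i]
        if (g1 < g2 && bestW[match(g2, rownames(W))] == g1) {
          w <- W[g1, g2]
          crossMax <- if (byRow)
            max(cross[g1, ], cross[g2, ]) else max(cross[, g1], cross[, g2])
          if (w > crossMax)
            evRows[[length(evRows) + 1L]] <<- data.frame(
              event = "duplication", species = species,
              genes = paste(g1, g2, sep = ","), subfamily = sf)
        }
      }
    }
    if (ncol(im$AB) > 0L) dupCalls(im$AA, im$AB, "A", byRow = TRUE)
    if (nrow(im$AB) > 0L) dupCalls(im$BB, im$AB, "B", byRow = FALSE)
  }
  list(summary = S4Vectors::DataFrame(do.call(rbind, sumRows)),
       events = if (length(evRows))
         S4Vectors::DataFrame(do.call(rbind, evRows))
       else S4Vectors::DataFrame(event = character(),
                                 species = character(),
                                 genes = character(),
                                 subfamily = character()))
}

#' Call duplication and loss events from a gene tree
#'
#' Corroborates the identity-based calls of [summarizeOrthology()] with
#' tree topology: an internal node whose two children are leaves of the
#' same species is a post-speciation duplication; a leaf whose sister
#' clade consists entirely of leaves of its own species marks a candidate
#' loss in the other species. Bootstrap labels, when present on the tree,
#' are attached to each call.
#'
#' @param tree an \pkg{ape} \code{phylo} whose tip labels are gene ids.
#' @param species named character vector mapping every tip label to a
#'   species identifier (exactly two species expected).
#' @return \code{DataFrame} of events: \code{event}, \code{species} (the
#'   species the event is assigned to: where the duplication happened, or
#'   where the loss is inferred), \code{genes}, \code{support}.
#' @export
callEvents <- function(tree, species) {
  if (!all(tree$tip.label %in% names(species)))
    stop("species map must cover every tip label")
  sp <- species[tree$tip.label]
  spp <- sort(unique(sp))
  nt <- ape::Ntip(tree)
  rows <- list()
  supp <- function(node) {
    if (is.null(tree$node.label)) NA_character_
    else tree$node.label[node - nt]
  }
  children <- split(tree$edge[, 2], tree$edge[, 1])
  tipsUnder <- function(node) {
    if (node <= nt) return(node)
    unlist(lapply(children[[as.character(node)]], tipsUnder))
  }
  for (node in (nt + 1L):(nt + tree$Nnode)) {
    kids <- children[[as.character(node)]]
    if (length(kids) != 2L) next
    # duplication: two leaf children, same species
    if (all(kids <= nt) && sp[kids[1]] == sp[kids[2]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        event = "duplication", species = unname(sp[kids[1]]),
        genes = paste(sort(tree$tip.label[kids]), collapse = ","),
        support = supp(node))
      next
    }
    # candidate loss: a leaf whose sister clade is pure own-species
    for (k in seq_along(kids)) {
      if (kids[k] <= nt) {
        sister <- tipsUnder(kids[3 - k])
        sisterSp <- unique(sp[sister])
        if (length(sister) >= 1L && length(sisterSp) == 1L &&
            sisterSp == sp[kids[k]] && length(sister) > 1L) {
          other <- setdiff(spp, sp[kids[k]])
          rows[[length(rows) + 1L]] <- data.frame(
            event = "loss", species = if (length(other)) other else NA,
            genes = tree$tip.label[kids[k]], support = supp(node))
        }
      }
    }
  }
  if (length(rows)) S4Vectors::DataFrame(do.call(rbind, rows))
  else S4Vectors::DataFrame(event = character(), species = character(),
                            genes = character(), support = character())
}
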