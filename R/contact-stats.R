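#' Contact-distance profile of one cell
#'
#' Genomic distances of the cell's intra-chromosomal contacts and the
#' fraction spanning at least \code{threshold} (inclusive) -- the
#' ultra-long-range fraction at the default 10 Mb. Inter-chromosomal
#' contacts have no genomic distance and are excluded from the
#' denominator.
#'
#' @param cell a [ContactSet].
#' @param threshold distance threshold in bp (default 10 Mb).
#' @return list with \code{distances} (bp, intra contacts only),
#'   \code{fraction} (>= threshold; \code{NA} with a warning if the cell
#'   has no intra contacts), \code{nIntra} and \code{nInter}.
#' @export
distanceProfile <- function(cell, threshold = 1e7) {
  cc <- cell@contacts
  intra <- cc$chromA == cc$chromB
  d <- abs(cc$posB[intra] - cc$posA[intra])
  frac <- if (length(d)) mean(d >= threshold) else {
    warning("cell ", cell@cellId, " has no intra-chromosomal contacts")
    NA_real_
  }
  list(distances = d, fraction = frac,
       nIntra = sum(intra), nInter = sum(!intra))
}

#' Two-group comparison by the Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U test with descriptive mean +- s.d. per
#' group. Exact p-values are used for small untied samples (both
#' n <= 20); otherwise the normal approximation with continuity and tie
#' correction.
#'
#' @param a,b numeric vectors (each nonempty).
#' @return list with \code{U} (U statistic of \code{a} vs \code{b}),
#'   \code{p} (two-sided), \code{meanA}, \code{sdA}, \code{meanB},
#'   \code{sdB}, \code{nA}, \code{nB}.
#' @export
compareGroups <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  exact <- length(a) <= 20 && length(b) <= 20 &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       meanA = mean(a), sdA = sd(a), meanB = mean(b), sdB = sd(b),
       nA = length(a), nB = length(b))
}

#' Aggregated contact map over a group of cells
#'
#' Bins contacts at \code{binSize} and sums counts over cells within a
#' scope: a single chromosome (intra contacts, symmetric square matrix),
#' a chromosome pair (inter contacts, rectangular), or genome-wide
#' inter-chromosomal (all bins x all bins, inter contacts only,
#' symmetric). Off-diagonal entries of symmetric maps are mirrored, so
#' each off-diagonal contact is counted twice in the matrix total.
#'
#' @param cells list of [ContactSet]s.
#' @param genome a [Genome].
#' @param scope \code{list(type = "chrom", chrom = ...)},
#'   \code{list(type = "pair", chromA = ..., chromB = ...)}, or
#'   \code{list(type = "inter")}.
#' @param binSize map resolution in bp.
#' @param label group label stored with the map.
#' @return an \code{AggregateMap}: list with \code{counts} (matrix),
#'   \code{scope}, \code{binSize}, \code{label} and \code{nContacts}
#'   (in-scope contacts).
#' @export
aggregateMap <- function(cells, genome, scope, binSize = 1e6,
                         label = "all") {
  stopifnot(is.list(scope), !is.null(scope$type))
  allc <- do.call(rbind, lapply(cells, contacts))
  len <- chromLengths(genome)
  mkbins <- function(chrom) {
    if (binSize > len[chrom]) stop("bin size exceeds length of ", chrom)
    as.integer(ceiling(len[chrom] / binSize))
  }
  if (scope$type == "chrom") {
    ch <- scope$chrom
    stopifnot(ch %in% genome@chromNames)
    nb <- mkbins(ch)
    sel <- allc$chromA == ch & allc$chromB == ch
    i <- floor((allc$posA[sel] - 1) / binSize) + 1
    j <- floor((allc$posB[sel] - 1) / binSize) + 1
    tab <- unclass(table(factor(i, 1:nb), factor(j, 1:nb)))
    M <- tab + t(tab)
    diag(M) <- diag(tab)
    dimnames(M) <- NULL
  } else if (scope$type == "pair") {
    cA <- scope$chromA; cB <- scope$chromB
    stopifnot(all(c(cA, cB) %in% genome@chromNames), cA != cB)
    nbA <- mkbins(cA); nbB <- mkbins(cB)
    fwd <- allc$chromA == cA & allc$chromB == cB
    rev <- allc$chromA == cB & allc$chromB == cA
    pA <- c(allc$posA[fwd], allc$posB[rev])
    pB <- c(allc$posB[fwd], allc$posA[rev])
    i <- floor((pA - 1) / binSize) + 1
    j <- floor((pB - 1) / binSize) + 1
    M <- unclass(table(factor(i, 1:nbA), factor(j, 1:nbB)))
    dimnames(M) <- NULL
    sel <- fwd | rev
  } else if (scope$type == "inter") {
    bi <- makeBins(genome, binSize)
    nb <- totalBins(bi)
    sel <- allc$chromA != allc$chromB
    i <- assignBin(allc$chromA[sel], allc$posA[sel], bi)
    j <- assignBin(allc$chromB[sel], allc$posB[sel], bi)
    tab <- unclass(table(factor(i, 1:nb), factor(j, 1:nb)))
    M <- tab + t(tab)  # inter contacts never hit the diagonal bin pair
    dimnames(M) <- NULL
  } else stop("unknown scope type: ", scope$type)
  structure(list(counts = M, scope = scope, binSize = binSize,
                 label = label, nContacts = sum(sel)),
            class = "AggregateMap")
}

#' Write an aggregated contact map as a dense matrix
#'
#' Tab-separated dense matrix preceded by header lines naming the scope,
#' bin size, cell-group label and the symmetrization convention.
#'
#' @param map an \code{AggregateMap} from [aggregateMap()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMap <- function(map, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  sc <- map$scope
  scopeStr <- switch(sc$type,
    chrom = paste0("chrom=", sc$chrom),
    pair = paste0("pair=", sc$chromA, "/", sc$chromB),
    inter = "genome-wide-inter")
  writeLines(c(
    paste0("# aggregate contact map; scope: ", scopeStr),
    paste0("# binSize: ", map$binSize, "; group: ", map$label,
           "; contacts: ", map$nContacts),
    "# symmetric scopes mirror off-diagonal entries (counted twice)"),
    con)
  write.table(map$counts, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Inter-chromosomal contact enrichment and hub scores
#'
#' Observed inter-chromosomal contact counts per chromosome pair are
#' compared with a marginal-product null: with \eqn{m_i} chromosome i's
#' inter-contact endpoint count / 2 and T the total inter contacts,
#' expected(i,j) = \eqn{T m_i m_j / \sum_{k<l} m_k m_l}. Using contact
#' marginals rather than chromosome lengths keeps coverage differences
#' between chromosomes from masquerading as enrichment. The hub score of
#' a chromosome is its mean pairwise enrichment over all partners.
#'
#' @param cells list of [ContactSet]s with >= 1 inter contact in total.
#' @param genome a [Genome].
#' @return list with symmetric matrices \code{observed},
#'   \code{expected}, \code{enrichment} (observed/expected, \code{NA}
#'   where a chromosome has no inter contacts) and \code{hubScore}
#'   (named per chromosome).
#' @export
interchromEnrichment <- function(cells, genome) {
  cn <- genome@chromNames
  allc <- do.call(rbind, lapply(cells, contacts))
  inter <- allc[allc$chromA != allc$chromB, , drop = FALSE]
  if (nrow(inter) == 0L) stop("no inter-chromosomal contacts")
  obs <- matrix(0, length(cn), length(cn), dimnames = list(cn, cn))
  tab <- table(factor(inter$chromA, cn), factor(inter$chromB, cn))
  obs <- unclass(tab) + t(unclass(tab))
  Tn <- nrow(inter)
  m <- (rowSums(obs)) / 2  # endpoints/2 per chromosome
  denom <- (sum(m)^2 - sum(m^2)) / 2  # sum over pairs k<l of m_k m_l
  expd <- Tn * outer(m, m) / denom
  diag(expd) <- NA
  enr <- obs / expd
  dead <- m == 0
  enr[dead, ] <- NA; enr[, dead] <- NA
  diag(enr) <- NA
  hub <- rowMeans(enr, na.rm = TRUE)
  hub[dead] <- NA
  list(observed = obs, expected = expd, enrichment = enr, hubScore = hub)
}

#' Log2 change of inter-chromosomal enrichment between two cell groups
#'
#' @param cellsA,cellsB lists of [ContactSet]s (reference group A,
#'   contrast group B).
#' @param genome a [Genome].
#' @return symmetric matrix of log2(enrichment_B / enrichment_A), NA
#'   where either group's enrichment is undefined.
#' @export
enrichmentDelta <- function(cellsA, cellsB, genome) {
  eA <- interchromEnrichment(cellsA, genome)$enrichment
  eB <- interchromEnrichment(cellsB, genome)$enrichment
  log2(eB / eA)
}
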