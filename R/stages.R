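#' PCA embedding of scA/B profiles
#'
#' Centered principal-component analysis of the cells-by-bins scA/B
#' matrix. Components are ordered by explained variance. Signs are made
#' deterministic (largest-magnitude loading positive); if ages are
#' available, PC1's sign is additionally fixed so that it correlates
#' positively with log age.
#'
#' @param x a complete (imputed) [ScABMatrix], or a cells x bins numeric
#'   matrix without missing values.
#' @param nComponents number of components to keep (reduced with a
#'   warning when there are fewer cells).
#' @param ages optional per-cell ages in years (taken from
#'   \code{colData} when \code{x} is an [ScABMatrix]).
#' @param minBins QC gate: cells with fewer scored bins than this are
#'   excluded before embedding (only applies to an [ScABMatrix] carrying
#'   support counts; default 200).
#' @return list with \code{scores} (cells x components), \code{explained}
#'   (proportion of variance per component), \code{rotation} (bin
#'   loadings), and \code{ages} (possibly subset by the QC gate).
#' @export
embedScAB <- function(x, nComponents = 10, ages = NULL, minBins = 200) {
  if (is(x, "ScABMatrix")) {
    supp <- SummarizedExperiment::assay(x, "support")
    covered <- colSums(supp > 0)
    keep <- covered >= min(minBins, nrow(x))
    if (!all(keep)) {
      warning(sum(!keep), " cell(s) below the ", minBins,
              "-bin coverage gate excluded from embedding")
      x <- x[, keep]
    }
    if (is.null(ages)) ages <- SummarizedExperiment::colData(x)$age
    M <- t(SummarizedExperiment::assay(x, "scab"))
  } else {
    M <- as.matrix(x)
    if (!is.null(ages) && length(ages) != nrow(M))
      stop("ages must match the number of cells")
  }
  if (anyNA(M)) stop("matrix contains NA; run imputeMissing() first")
  if (nrow(M) < 2) stop("need at least 2 cells to embed")
  maxComp <- min(nrow(M) - 1, ncol(M))
  if (nComponents > maxComp) {
    warning("reducing nComponents from ", nComponents, " to ", maxComp)
    nComponents <- maxComp
  }
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  k <- seq_len(nComponents)
  scores <- pc$x[, k, drop = FALSE]
  rot <- pc$rotation[, k, drop = FALSE]
  ## deterministic sign: largest-|loading| positive per component
  for (j in k) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  if (!is.null(ages) && any(is.finite(ages) & ages > 0)) {
    ok <- is.finite(ages) & ages > 0
    if (sum(ok) >= 3 && sd(scores[ok, 1]) > 0) {
      r <- suppressWarnings(stats::cor(scores[ok, 1], log10(ages[ok])))
      if (is.finite(r) && r < 0) {
        scores[, 1] <- -scores[, 1]; rot[, 1] <- -rot[, 1]
      }
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, explained = ev[k], rotation = rot, ages = ages)
}

#' Cluster cells into structure types
#'
#' Agglomerative (Ward) clustering on the top principal components.
#' Deterministic: no random initialization is involved.
#'
#' @param embedding result of [embedScAB()], or a cells x components
#'   score matrix.
#' @param k number of clusters (>= 1).
#' @param nPCs number of leading components used (default 10, or all
#'   available if fewer).
#' @return integer cluster ids (1..k) named by cell.
#' @export
clusterStages <- function(embedding, k, nPCs = 10) {
  scores <- if (is.list(embedding)) embedding$scores else embedding
  if (k > nrow(scores)) stop("k exceeds the number of cells")
  if (k < 1) stop("k must be >= 1")
  p <- min(nPCs, ncol(scores))
  hc <- hclust(dist(scores[, seq_len(p), drop = FALSE]), method = "ward.D2")
  cutree(hc, k = k)
}

#' Order clusters into age-ranked stages S1..Sk
#'
#' Relabels cluster ids as stages S1..Sk by ascending median donor age
#' (ties broken by cluster id). Clusters with no aged cells are ordered
#' last and flagged.
#'
#' @param clusters integer cluster ids per cell (named).
#' @param ages per-cell ages in years (NA allowed).
#' @return list with \code{assignment} (data.frame: cell, cluster,
#'   stage, age) and \code{stageAges} (data.frame: stage, cluster,
#'   medianAge, n, flagged).
#' @export
orderStagesByAge <- function(clusters, ages) {
  stopifnot(length(clusters) == length(ages))
  ids <- sort(unique(clusters))
  med <- vapply(ids, function(cl)
    median(ages[clusters == cl], na.rm = TRUE), 0)
  flagged <- !is.finite(med)
  ord <- order(flagged, med, ids)  # ageless clusters last; ties by id
  stageOf <- setNames(paste0("S", seq_along(ids)), ids[ord])
  if (any(flagged))
    warning("cluster(s) without aged cells ordered last: ",
            paste(ids[flagged], collapse = ", "))
  assignment <- data.frame(
    cell = if (is.null(names(clusters))) seq_along(clusters)
           else names(clusters),
    cluster = as.integer(clusters),
    stage = unname(stageOf[as.character(clusters)]),
    age = ages, stringsAsFactors = FALSE)
  stageAges <- data.frame(
    stage = unname(stageOf[as.character(ids[ord])]),
    cluster = ids[ord], medianAge = med[ord],
    n = as.integer(table(clusters)[as.character(ids[ord])]),
    flagged = flagged[ord], stringsAsFactors = FALSE)
  list(assignment = assignment, stageAges = stageAges)
}

#' Pearson correlation of a per-cell value with log age
#'
#' Computes Pearson's r (and two-sided p-value) between a per-cell
#' quantity (e.g. a PC score) and log10 of donor age in years.
#'
#' @param values per-cell numeric values.
#' @param ages per-cell ages in years (must be > 0 where used).
#' @return list with \code{r}, \code{p} and \code{n} (cells used). Both
#'   are \code{NA} (with a warning) when either variable has zero
#'   variance.
#' @export
ageCorrelation <- function(values, ages) {
  stopifnot(length(values) == length(ages))
  ok <- is.finite(values) & is.finite(ages) & ages > 0
  if (sum(ok) < 3) stop("need >= 3 cells with positive age")
  x <- values[ok]; y <- log10(ages[ok])
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
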