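#' Mean scA/B per bin per stage
#'
#' Averages unmasked scA/B values over the cells of each stage. A bin is
#' eligible for dynamic-region analysis only if it is observed in every
#' stage with at least \code{minSupport} contributing cells (stage means
#' from sparse support are unstable).
#'
#' @param scab an [ScABMatrix].
#' @param stages per-cell stage labels (named by cell or in column
#'   order); every cell must be labeled and every stage must have >= 1
#'   cell.
#' @param minSupport minimum cells per (bin, stage) for eligibility.
#' @return list with \code{means} (bins x stages, stages in label sort
#'   order), \code{support} (cell counts per entry), \code{eligible}
#'   (logical per bin) and \code{bins} (global bin ids).
#' @export
stageMeanScAB <- function(scab, stages, minSupport = 10L) {
  stopifnot(is(scab, "ScABMatrix"))
  v <- SummarizedExperiment::assay(scab, "scab")
  if (!is.null(names(stages))) stages <- stages[colnames(v)]
  if (length(stages) != ncol(v) || anyNA(stages))
    stop("every cell needs a stage label")
  lev <- sort(unique(stages))
  if (any(table(factor(stages, lev)) == 0L)) stop("stage with zero cells")
  means <- vapply(lev, function(s)
    rowMeans(v[, stages == s, drop = FALSE], na.rm = TRUE),
    numeric(nrow(v)))
  support <- vapply(lev, function(s)
    rowSums(!is.na(v[, stages == s, drop = FALSE])), numeric(nrow(v)))
  means[support == 0] <- NA
  eligible <- rowSums(support >= minSupport) == length(lev)
  list(means = means, support = support, eligible = eligible,
       bins = SummarizedExperiment::rowData(scab)$bin)
}

#' Select the top dynamic compartment regions
#'
#' Scores every eligible bin by its scA/B change across stages (default:
#' range, max - min of the stage means) and selects the top
#' \code{round(topFrac * nEligible)} bins, ranked by descending score
#' with ties broken by bin id (deterministic).
#'
#' @param stageMeans result of [stageMeanScAB()].
#' @param topFrac fraction of eligible bins to select, in (0, 1]
#'   (default 0.20).
#' @param score \code{"range"} (default) or \code{"variance"} across
#'   stage means.
#' @return list with \code{bins} (selected global bin ids), \code{score}
#'   (per selected bin), \code{means} (stage means of the selected bins)
#'   and \code{nEligible}.
#' @export
dynamicRegions <- function(stageMeans, topFrac = 0.20,
                           score = c("range", "variance")) {
  score <- match.arg(score)
  if (topFrac <= 0 || topFrac > 1) stop("topFrac must be in (0, 1]")
  el <- which(stageMeans$eligible)
  if (length(el) < 5) stop("need >= 5 eligible bins")
  m <- stageMeans$means[el, , drop = FALSE]
  s <- if (score == "range")
    apply(m, 1, max) - apply(m, 1, min)
  else apply(m, 1, stats::var)
  nSel <- round(topFrac * length(el))
  ord <- order(-s, stageMeans$bins[el])
  take <- ord[seq_len(nSel)]
  list(bins = stageMeans$bins[el][take], score = s[take],
       means = m[take, , drop = FALSE], nEligible = length(el))
}

#' Cluster dynamic-region trajectories into increasing/decreasing sets
#'
#' Hierarchically clusters (Ward) the row-centered stage-mean profiles of
#' the selected bins and names each cluster by the sign of its mean
#' last-stage-minus-first-stage change ("increasing" or "decreasing";
#' numbered suffixes disambiguate same-sign clusters when k > 2).
#'
#' @param means bins x stages matrix of stage means (selected bins).
#' @param k number of clusters (default 2).
#' @return character labels per bin; integer cluster ids in attribute
#'   \code{"cluster"}.
#' @export
clusterTrajectories <- function(means, k = 2) {
  if (k > nrow(means)) stop("k exceeds the number of selected bins")
  if (k == 1) {
    cl <- rep(1L, nrow(means))
  } else {
    centered <- means - rowMeans(means)
    hc <- hclust(dist(centered), method = "ward.D2")
    cl <- cutree(hc, k = k)
  }
  delta <- means[, ncol(means)] - means[, 1]
  meanDelta <- vapply(seq_len(k), function(g) mean(delta[cl == g]), 0)
  base <- ifelse(meanDelta >= 0, "increasing", "decreasing")
  lab <- base
  for (nm in unique(base[duplicated(base)]))
    lab[base == nm] <- paste0(nm, seq_len(sum(base == nm)))
  out <- lab[cl]
  names(out) <- rownames(means)
  attr(out, "cluster") <- cl
  out
}

#' Gene-set (marker-gene region) scA/B trajectory across stages
#'
#' For each cell, the mean scA/B over a bin set (e.g. the 1-Mb bins
#' harboring marker genes); per stage, a distribution summary; and
#' two-sided Mann-Whitney U tests between consecutive stages.
#'
#' @param scab an [ScABMatrix].
#' @param stages per-cell stage labels (as in [stageMeanScAB()]).
#' @param bins global bin ids of the gene set (nonempty).
#' @return list with \code{cellValues} (per-cell mean, NA when all bins
#'   masked for a cell), \code{summary} (data.frame per stage: n, mean,
#'   sd, median) and \code{tests} (data.frame per consecutive stage
#'   pair: U, p, means).
#' @export
genesetTrajectory <- function(scab, stages, bins) {
  stopifnot(length(bins) >= 1)
  v <- SummarizedExperiment::assay(scab, "scab")
  rows <- match(bins, SummarizedExperiment::rowData(scab)$bin)
  if (anyNA(rows)) stop("bin set contains bins absent from the matrix")
  if (!is.null(names(stages))) stages <- stages[colnames(v)]
  sub <- v[rows, , drop = FALSE]
  if (all(is.na(sub))) stop("bin set fully masked")
  cellValues <- colMeans(sub, na.rm = TRUE)
  cellValues[colSums(!is.na(sub)) == 0L] <- NA
  lev <- sort(unique(stages))
  summ <- do.call(rbind, lapply(lev, function(s) {
    x <- cellValues[stages == s & !is.na(cellValues)]
    data.frame(stage = s, n = length(x), mean = mean(x), sd = sd(x),
               median = median(x), stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (length(lev) >= 2) {
    tests <- do.call(rbind, lapply(seq_len(length(lev) - 1), function(i) {
      xa <- cellValues[stages == lev[i] & !is.na(cellValues)]
      xb <- cellValues[stages == lev[i + 1] & !is.na(cellValues)]
      cg <- compareGroups(xa, xb)
      data.frame(stageA = lev[i], stageB = lev[i + 1], U = cg$U,
                 p = cg$p, meanA = cg$meanA, meanB = cg$meanB,
                 stringsAsFactors = FALSE)
    }))
  }
  list(cellValues = cellValues, summary = summ, tests = tests)
}

#' Map gene intervals to the bins they overlap
#'
#' Genes are supplied as a BED-like table (chrom, start, end, name;
#' 0-based half-open coordinates) or a path to one (tab-separated, no
#' header). A gene spanning a bin boundary contributes every bin it
#' overlaps. Genes on chromosomes absent from the bin index are skipped
#' with a warning.
#'
#' @param genes data.frame or file path.
#' @param binIndex a [BinIndex].
#' @return sorted unique global bin ids overlapped by any gene.
#' @export
mapGenesToBins <- function(genes, binIndex) {
  if (is.character(genes)) {
    genes <- read.table(genes, header = FALSE, sep = "\t",
                        stringsAsFactors = FALSE)
    names(genes)[1:3] <- c("chrom", "start", "end")
    if (ncol(genes) >= 4) names(genes)[4] <- "name"
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(genes)))
  known <- genes$chrom %in% chromNames(binIndex)
  if (any(!known)) {
    warning(sum(!known), " gene(s) on unknown chromosome(s) skipped")
    genes <- genes[known, , drop = FALSE]
  }
  if (nrow(genes) == 0L) return(integer(0))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end))
  hits <- GenomicRanges::findOverlaps(gr, binGRanges(binIndex))
  sort(unique(S4Vectors::subjectHits(hits)))
}
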