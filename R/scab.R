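#' Single-cell A/B score of every bin for one cell
#'
#' For each 1-Mb (or \code{binSize}) bin b, the scA/B value is the mean
#' reference compartment value of the partner bins over all of the cell's
#' contacts with one endpoint in b. Contacts whose two endpoints fall
#' within the same region (same bin, extended by \code{exclusionRadius}
#' bins) are excluded, so the score primarily reports long-range
#' interactions. Each contact contributes to both of its endpoint bins.
#' Bins with fewer than \code{minContacts} contributing partners are
#' masked (\code{NA}).
#'
#' @param cell a [ContactSet].
#' @param track a [CompartmentTrack] (its [BinIndex] defines the bins).
#' @param exclusionRadius extra bins around the endpoint bin inside which
#'   contacts are treated as within-region (default 0: same bin only).
#' @param minContacts minimum partner count for a bin to be scored.
#' @param rankNormalize if TRUE, replace the cell's scored values by
#'   their fractional ranks in [0, 1].
#' @return list with \code{values} (numeric per global bin, NA where
#'   masked) and \code{support} (integer partner counts per bin).
#' @export
computeScAB <- function(cell, track, exclusionRadius = 0L,
                        minContacts = 5L, rankNormalize = FALSE) {
  stopifnot(is(cell, "ContactSet"), is(track, "CompartmentTrack"))
  bi <- track@binIndex
  nb <- totalBins(bi)
  cc <- cell@contacts
  binA <- assignBin(cc$chromA, cc$posA, bi)
  binB <- assignBin(cc$chromB, cc$posB, bi)
  within <- cc$chromA == cc$chromB & abs(binA - binB) <= exclusionRadius
  keep <- !within
  tv <- track@values
  ## partner track value feeding each endpoint bin; NA partners drop out
  bins <- c(binA[keep], binB[keep])
  partner <- c(tv[binB[keep]], tv[binA[keep]])
  use <- !is.na(partner)
  support <- tabulate(bins[use], nbins = nb)
  sums <- rep(0, nb)
  if (any(use)) {
    agg <- rowsum(partner[use], group = bins[use])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  values <- ifelse(support >= minContacts, sums / pmax(support, 1L),
                   NA_real_)
  if (rankNormalize) {
    ok <- !is.na(values)
    values[ok] <- (rank(values[ok]) - 0.5) / sum(ok)
  }
  list(values = values, support = as.integer(support))
}

#' scA/B matrix over a set of cells
#'
#' Applies [computeScAB()] to every cell and assembles an [ScABMatrix]
#' (bins x cells \code{SummarizedExperiment} with assays \code{scab} and
#' \code{support}); cell metadata (donor, age in years, sex, truth
#' labels) goes into \code{colData}, bin coordinates into \code{rowData}.
#'
#' @param cells list of [ContactSet]s (>= 1).
#' @inheritParams computeScAB
#' @return an [ScABMatrix].
#' @export
scabMatrix <- function(cells, track, exclusionRadius = 0L,
                       minContacts = 5L, rankNormalize = FALSE) {
  stopifnot(length(cells) >= 1)
  per <- lapply(cells, computeScAB, track = track,
                exclusionRadius = exclusionRadius,
                minContacts = minContacts, rankNormalize = rankNormalize)
  vals <- vapply(per, `[[`, numeric(totalBins(track@binIndex)), "values")
  supp <- vapply(per, `[[`, integer(totalBins(track@binIndex)), "support")
  ids <- vapply(cells, cellId, "")
  colnames(vals) <- colnames(supp) <- ids
  bt <- binTable(track@binIndex)
  cd <- S4Vectors::DataFrame(
    cell = ids,
    donor = vapply(cells, function(x) x@donor, ""),
    age = vapply(cells, ageYears, 0),
    sex = vapply(cells, function(x) x@sex, ""),
    stage = vapply(cells, function(x)
      as.character(x@truth$stage %||% NA_character_), ""),
    row.names = ids)
  covered <- colSums(!is.na(vals))
  message("scA/B matrix: ", length(ids), " cells x ", nrow(vals),
          " bins; median covered bins per cell: ", median(covered))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(scab = vals, support = supp),
    rowData = S4Vectors::DataFrame(bt, row.names = bt$bin),
    colData = cd)
  new("ScABMatrix", se)
}

#' Impute masked scA/B entries
#'
#' Completes the matrix for PCA: missing entries are replaced by the bin
#' mean (default) or the cell mean; bins with no observed value in any
#' cell cannot be imputed and are dropped (their global ids are recorded
#' in \code{metadata(x)$droppedBins}).
#'
#' @param x an [ScABMatrix].
#' @param strategy \code{"bin"} or \code{"cell"} mean imputation.
#' @return an [ScABMatrix] with a complete \code{scab} assay.
#' @export
imputeMissing <- function(x, strategy = c("bin", "cell")) {
  strategy <- match.arg(strategy)
  stopifnot(is(x, "ScABMatrix"), ncol(x) >= 1)
  v <- SummarizedExperiment::assay(x, "scab")
  allMissing <- rowSums(!is.na(v)) == 0L
  dropped <- SummarizedExperiment::rowData(x)$bin[allMissing]
  if (any(allMissing)) {
    message("dropping ", sum(allMissing), " bin(s) with no observed value")
    x <- x[!allMissing, ]
    v <- v[!allMissing, , drop = FALSE]
  }
  miss <- is.na(v)
  if (any(miss)) {
    if (strategy == "bin") {
      fill <- rowMeans(v, na.rm = TRUE)
      v[miss] <- fill[row(v)[miss]]
    } else {
      fill <- colMeans(v, na.rm = TRUE)
      v[miss] <- fill[col(v)[miss]]
    }
  }
  SummarizedExperiment::assay(x, "scab") <- v
  S4Vectors::metadata(x)$droppedBins <- as.integer(dropped)
  x
}
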