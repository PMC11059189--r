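#' @import methods
#' @importFrom stats median prcomp hclust cutree dist cor cor.test
#'   wilcox.test rbinom rnbinom rnorm runif rpois sd setNames quantile var
#' @importFrom graphics hist
#' @importFrom utils read.table write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata mcols
NULL

#' Genome model for contact analysis
#'
#' Holds the ordered chromosome set of one genome assembly: names, lengths
#' in bp, which chromosomes are autosomes, and which is the X chromosome.
#' All downstream binning and sex-dosage logic is driven by this object.
#'
#' @slot species species tag, e.g. \code{"human"} or \code{"mouse"}.
#' @slot chromNames ordered chromosome names.
#' @slot chromLengths chromosome lengths in bp, parallel to
#'   \code{chromNames}.
#' @slot autosomes names of the autosomal chromosomes.
#' @slot xChrom name of the X chromosome (\code{NA} if absent).
#'
#' @seealso [readChromSizes()]
#' @export
setClass("Genome",
  slots = c(
    species      = "character",
    chromNames   = "character",
    chromLengths = "numeric",
    autosomes    = "character",
    xChrom       = "character"
  )
)

setValidity("Genome", function(object) {
  msg <- NULL
  if (length(object@chromNames) == 0L)
    msg <- c(msg, "genome must contain at least one chromosome")
  if (anyDuplicated(object@chromNames))
    msg <- c(msg, "chromosome names must be unique")
  if (length(object@chromLengths) != length(object@chromNames))
    msg <- c(msg, "chromNames and chromLengths differ in length")
  if (any(!is.finite(object@chromLengths)) || any(object@chromLengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (!all(object@autosomes %in% object@chromNames))
    msg <- c(msg, "autosomes must be a subset of chromNames")
  if (!is.na(object@xChrom) && object@xChrom %in% object@autosomes)
    msg <- c(msg, "X chromosome cannot be listed among the autosomes")
  if (is.null(msg)) TRUE else msg
})

#' Bin index: fixed-width genomic bins with a global bin id
#'
#' Partitions every chromosome of a [Genome] into consecutive bins of
#' \code{binSize} bp (the last bin of each chromosome may be short) and
#' defines an invertible mapping between (chromosome, 0-based bin ordinal)
#' and a 1-based global bin id. Bins are 0-based half-open internally;
#' genomic positions entering via [assignBin()] are 1-based.
#'
#' @slot genome the underlying [Genome].
#' @slot binSize bin width in bp.
#' @slot chromBins number of bins per chromosome (named integer).
#' @slot offsets 0-based global offset of each chromosome's first bin
#'   (named; global id = offset + ordinal + 1).
#'
#' @seealso [makeBins()], [assignBin()], [binTable()]
#' @export
setClass("BinIndex",
  slots = c(
    genome    = "Genome",
    binSize   = "numeric",
    chromBins = "integer",
    offsets   = "numeric"
  )
)

setValidity("BinIndex", function(object) {
  g <- object@genome
  want <- as.integer(ceiling(g@chromLengths / object@binSize))
  if (object@binSize <= 0) return("binSize must be positive")
  if (!identical(unname(object@chromBins), want))
    return("chromBins inconsistent with genome lengths and binSize")
  if (!identical(unname(object@offsets),
                 cumsum(c(0, as.numeric(want[-length(want)])))))
    return("offsets inconsistent with chromBins")
  TRUE
})

#' Reference A/B compartment track
#'
#' Per-bin reference compartment value in [0, 1] (A-like high, B-like low),
#' on the bins of a [BinIndex]. For synthetic cohorts the generator's own
#' track is the reference and carries ground-truth block labels plus the
#' designated dynamic ("drift-up"/"drift-down") bins whose effective
#' compartment shifts across stage presets.
#'
#' @slot binIndex the [BinIndex] the track is defined on.
#' @slot values per-global-bin value in [0, 1]; \code{NA} where missing.
#' @slot truth ground-truth block label per bin ("A"/"B"), or \code{NA}
#'   for tracks without truth.
#' @slot dynamicUp global bin ids designated to drift toward A.
#' @slot dynamicDown global bin ids designated to drift toward B.
#'
#' @seealso [makeCompartmentTrack()], [readTrack()]
#' @export
setClass("CompartmentTrack",
  slots = c(
    binIndex    = "BinIndex",
    values      = "numeric",
    truth       = "character",
    dynamicUp   = "integer",
    dynamicDown = "integer"
  )
)

setValidity("CompartmentTrack", function(object) {
  nb <- totalBins(object@binIndex)
  v <- object@values
  msg <- NULL
  if (length(v) != nb)
    msg <- c(msg, "values must have one entry per global bin")
  if (any(v < 0 | v > 1, na.rm = TRUE))
    msg <- c(msg, "track values must lie in [0, 1]")
  if (length(object@truth) != nb)
    msg <- c(msg, "truth must have one entry per global bin")
  if (any(object@dynamicUp < 1L | object@dynamicUp > nb) ||
      any(object@dynamicDown < 1L | object@dynamicDown > nb))
    msg <- c(msg, "dynamic bin ids out of range")
  if (is.null(msg)) TRUE else msg
})

#' One cell's chromatin contacts plus metadata
#'
#' A single cell of a contact atlas: its canonicalized contact list (each
#' contact a pair of genomic loci captured in spatial proximity) and the
#' cell-level metadata needed downstream (donor, age, sex, species). For
#' synthetic cells the generating truth (stage preset, donor, sex) travels
#' in \code{truth}.
#'
#' Contacts are stored canonically: chromA <= chromB in genome order, and
#' posA <= posB for intra-chromosomal contacts.
#'
#' @slot cellId cell identifier.
#' @slot donor donor identifier (\code{NA} if unknown).
#' @slot age age value (\code{NA} if unknown).
#' @slot ageUnit \code{"years"} or \code{"days"} (postnatal days).
#' @slot sex \code{"F"}, \code{"M"} or \code{NA}.
#' @slot species species tag.
#' @slot contacts data.frame with columns chromA, posA, chromB, posB.
#' @slot truth named list of ground-truth labels (may be empty).
#'
#' @seealso [readPairs()], [writePairs()], [simulateCell()]
#' @export
setClass("ContactSet",
  slots = c(
    cellId   = "character",
    donor    = "character",
    age      = "numeric",
    ageUnit  = "character",
    sex      = "character",
    species  = "character",
    contacts = "data.frame",
    truth    = "list"
  )
)

setValidity("ContactSet", function(object) {
  cc <- object@contacts
  need <- c("chromA", "posA", "chromB", "posB")
  if (!all(need %in% names(cc)))
    return("contacts must have columns chromA, posA, chromB, posB")
  if (nrow(cc) < 1L)
    return("a ContactSet must contain at least one contact")
  intra <- cc$chromA == cc$chromB
  if (any(cc$posA[intra] > cc$posB[intra]))
    return("intra-chromosomal contacts must satisfy posA <= posB")
  TRUE
})

#' Structure-stage preset for the synthetic contact generator
#'
#' Encodes the contact statistics of one cell state: the target fraction
#' \code{fUltra} of intra-chromosomal contacts spanning >= 10 Mb, the
#' short-range power-law slope \code{alpha}, the inter-chromosomal
#' fraction \code{fInter}, a chromosome hub (set of chromosomes whose
#' pairwise inter-chromosomal weight is multiplied by \code{hubWeight}),
#' the same-compartment contact preference \code{rho}, and the compartment
#' drift applied to designated dynamic bins at this stage.
#'
#' @slot name preset name, e.g. \code{"human-S5"}.
#' @slot species species tag the preset belongs to.
#' @slot fUltra target fraction of intra contacts >= 10 Mb, in [0, 1].
#' @slot alpha power-law slope of the short-range distance component.
#' @slot fInter fraction of contacts that are inter-chromosomal.
#' @slot rho same-compartment preference in [0, 1].
#' @slot drift signed compartment shift applied to dynamic bins
#'   (+drift for drift-up bins, -drift for drift-down bins).
#' @slot hubChroms chromosomes forming the inter-chromosomal hub.
#' @slot hubWeight weight multiplier for hub chromosome pairs (>= 0).
#'
#' @seealso [stagePreset()], [listStagePresets()], [hubWeightMatrix()]
#' @export
setClass("StagePreset",
  slots = c(
    name      = "character",
    species   = "character",
    fUltra    = "numeric",
    alpha     = "numeric",
    fInter    = "numeric",
    rho       = "numeric",
    drift     = "numeric",
    hubChroms = "character",
    hubWeight = "numeric"
  )
)

setValidity("StagePreset", function(object) {
  in01 <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  msg <- NULL
  if (!in01(object@fUltra)) msg <- c(msg, "fUltra must be in [0, 1]")
  if (!in01(object@fInter)) msg <- c(msg, "fInter must be in [0, 1]")
  if (!in01(object@rho))    msg <- c(msg, "rho must be in [0, 1]")
  if (object@hubWeight < 0) msg <- c(msg, "hubWeight must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' Cells-by-bins matrix of single-cell A/B scores
#'
#' A \linkS4class{SummarizedExperiment} with bins as rows and cells as
#' columns. Assay \code{"scab"} holds the scA/B value (\code{NA} where the
#' bin is masked for that cell), assay \code{"support"} the number of
#' contact partners that contributed. \code{rowData} carries bin
#' coordinates; \code{colData} the cell metadata.
#'
#' @seealso [scabMatrix()], [computeScAB()], [imputeMissing()]
#' @export
setClass("ScABMatrix", contains = "SummarizedExperiment")

setValidity("ScABMatrix", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("scab", "support") %in% a))
    return("ScABMatrix needs assays 'scab' and 'support'")
  v <- SummarizedExperiment::assay(object, "scab")
  if (any(v < 0 | v > 1, na.rm = TRUE))
    return("scA/B values must lie in [0, 1]")
  TRUE
})
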