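#' @rdname Genome-class
#' @param x a Genome, BinIndex or other scContacts object
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname Genome-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname Genome-class
#' @export
setGeneric("autosomes", function(x) standardGeneric("autosomes"))

#' @rdname Genome-class
#' @export
setGeneric("xChromosome", function(x) standardGeneric("xChromosome"))

#' @rdname BinIndex-class
#' @param x a BinIndex or object carrying one
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname BinIndex-class
#' @export
setGeneric("totalBins", function(x) standardGeneric("totalBins"))

#' @rdname ContactSet-class
#' @param x a ContactSet
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' @rdname ContactSet-class
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname ContactSet-class
#' @export
setGeneric("ageYears", function(x) standardGeneric("ageYears"))

#' @rdname CompartmentTrack-class
#' @param x a CompartmentTrack
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname CompartmentTrack-class
#' @export
setGeneric("dynamicBins", function(x) standardGeneric("dynamicBins"))

## ---- Genome accessors -------------------------------------------------

#' @rdname Genome-class
#' @export
setMethod("chromNames", "Genome", function(x) x@chromNames)

#' @rdname Genome-class
#' @export
setMethod("chromLengths", "Genome",
  function(x) setNames(x@chromLengths, x@chromNames))

#' @rdname Genome-class
#' @export
setMethod("autosomes", "Genome", function(x) x@autosomes)

#' @rdname Genome-class
#' @export
setMethod("xChromosome", "Genome", function(x) x@xChrom)

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome (%s): %d chromosomes, %d autosomes, X = %s\n",
              object@species, length(object@chromNames),
              length(object@autosomes),
              ifelse(is.na(object@xChrom), "<none>", object@xChrom)))
  cat(sprintf("  total length: %.1f Mb\n", sum(object@chromLengths) / 1e6))
})

## ---- BinIndex accessors -----------------------------------------------

#' @rdname BinIndex-class
#' @export
setMethod("binSize", "BinIndex", function(x) x@binSize)

#' @rdname BinIndex-class
#' @export
setMethod("totalBins", "BinIndex", function(x) sum(as.numeric(x@chromBins)))

#' @rdname BinIndex-class
#' @export
setMethod("chromNames", "BinIndex", function(x) x@genome@chromNames)

setMethod("show", "BinIndex", function(object) {
  cat(sprintf("BinIndex: %d bins of %.3g bp over %d chromosomes\n",
              totalBins(object), object@binSize,
              length(object@genome@chromNames)))
})

## ---- CompartmentTrack accessors ---------------------------------------

#' @rdname CompartmentTrack-class
#' @export
setMethod("trackValues", "CompartmentTrack", function(x) x@values)

#' @rdname CompartmentTrack-class
#' @export
setMethod("binSize", "CompartmentTrack", function(x) x@binIndex@binSize)

#' @describeIn CompartmentTrack-class designated dynamic bins as a list
#'   with elements \code{up} and \code{down} (global bin ids).
#' @export
setMethod("dynamicBins", "CompartmentTrack",
  function(x) list(up = x@dynamicUp, down = x@dynamicDown))

setMethod("show", "CompartmentTrack", function(object) {
  v <- object@values
  cat(sprintf(
    "CompartmentTrack: %d bins (%d missing), %d drift-up / %d drift-down\n",
    length(v), sum(is.na(v)),
    length(object@dynamicUp), length(object@dynamicDown)))
})

## ---- ContactSet accessors ---------------------------------------------

#' @rdname ContactSet-class
#' @export
setMethod("contacts", "ContactSet", function(x) x@contacts)

#' @rdname ContactSet-class
#' @export
setMethod("cellId", "ContactSet", function(x) x@cellId)

#' @describeIn ContactSet-class age converted to years
#'   (1 postnatal day = 1/365 year).
#' @export
setMethod("ageYears", "ContactSet", function(x) {
  if (is.na(x@age)) return(NA_real_)
  if (identical(x@ageUnit, "days")) x@age / 365 else x@age
})

#' @rdname ContactSet-class
#' @param object a ContactSet
#' @export
setMethod("length", "ContactSet", function(x) nrow(x@contacts))

setMethod("show", "ContactSet", function(object) {
  cc <- object@contacts
  intra <- sum(cc$chromA == cc$chromB)
  cat(sprintf("ContactSet '%s' (%s): %d contacts (%d intra, %d inter)\n",
              object@cellId, object@species, nrow(cc), intra,
              nrow(cc) - intra))
  cat(sprintf("  donor=%s age=%s%s sex=%s\n", object@donor,
              format(object@age),
              ifelse(identical(object@ageUnit, "days"), "d", "y"),
              object@sex))
})

setMethod("show", "StagePreset", function(object) {
  cat(sprintf(
    "StagePreset '%s' (%s): fUltra=%.3f alpha=%.2f fInter=%.3f rho=%.2f drift=%+.3f\n",
    object@name, object@species, object@fUltra, object@alpha,
    object@fInter, object@rho, object@drift))
  if (length(object@hubChroms))
    cat(sprintf("  hub (x%.2f): %s\n", object@hubWeight,
                paste(object@hubChroms, collapse = ", ")))
})
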