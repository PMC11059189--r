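#' Construct a Genome from chromosome names and lengths
#'
#' @param chromNames ordered chromosome names.
#' @param chromLengths lengths in bp, parallel to \code{chromNames}.
#' @param species species tag (default \code{"unknown"}).
#' @param xChrom name of the X chromosome; by default auto-detected as
#'   \code{"chrX"} or \code{"X"} if present.
#' @return a [Genome] object. All chromosomes except X are treated as
#'   autosomes.
#' @examples
#' g <- Genome(c("chr1", "chrX"), c(1e7, 5e6))
#' autosomes(g)
#' @export
Genome <- function(chromNames, chromLengths, species = "unknown",
                   xChrom = NULL) {
  if (is.null(xChrom)) {
    hit <- chromNames[chromNames %in% c("chrX", "X")]
    xChrom <- if (length(hit)) hit[1] else NA_character_
  }
  new("Genome",
      species      = species,
      chromNames   = as.character(chromNames),
      chromLengths = as.numeric(chromLengths),
      autosomes    = setdiff(chromNames, xChrom),
      xChrom       = xChrom)
}

#' Read a chromosome-sizes table
#'
#' Parses a two-column whitespace-separated file (chromosome name, length
#' in bp), the usual \code{chrom.sizes} format. Order in the file defines
#' genome order. The X chromosome is identified by name ("chrX" or "X").
#'
#' @param path path to the chrom.sizes file.
#' @inheritParams Genome
#' @return a [Genome].
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1 10000000", "chrX 5000000"), f)
#' readChromSizes(f)
#' @export
readChromSizes <- function(path, species = "unknown") {
  tab <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               col.names = c("chrom", "length"),
               colClasses = c("character", "numeric")),
    error = function(e) stop("cannot parse chrom.sizes file '", path,
                             "': ", conditionMessage(e)))
  if (nrow(tab) == 0L) stop("empty chrom.sizes file: ", path)
  if (anyDuplicated(tab$chrom))
    stop("duplicate chromosome name in ", path, ": ",
         tab$chrom[duplicated(tab$chrom)][1])
  if (any(!is.finite(tab$length)) || any(tab$length <= 0))
    stop("non-positive chromosome length in ", path)
  Genome(tab$chrom, tab$length, species = species)
}

#' Path to a packaged chromosome-sizes fixture
#'
#' The package ships main-chromosome sizes for a human-like (hg38-style,
#' chr1-22 + chrX) and a mouse-like (mm10-style, chr1-19 + chrX) genome.
#'
#' @param species \code{"human"} or \code{"mouse"}.
#' @return file path to the packaged chrom.sizes table.
#' @export
packagedChromSizes <- function(species = c("human", "mouse")) {
  species <- match.arg(species)
  fn <- c(human = "human.chrom.sizes", mouse = "mouse.chrom.sizes")[species]
  system.file("extdata", fn, package = "scContacts", mustWork = TRUE)
}

#' Load a packaged genome
#'
#' @inheritParams packagedChromSizes
#' @return a [Genome] built from the packaged chrom.sizes fixture.
#' @export
packagedGenome <- function(species = c("human", "mouse")) {
  species <- match.arg(species)
  readChromSizes(packagedChromSizes(species), species = species)
}

#' Build a bin index over a genome
#'
#' Partitions each chromosome into \code{ceiling(length / binSize)}
#' consecutive bins; the last bin of a chromosome may be short.
#'
#' @param genome a [Genome].
#' @param binSize bin width in bp (default 1 Mb, the resolution at which
#'   scA/B is scored).
#' @return a [BinIndex].
#' @examples
#' g <- Genome(c("chr1", "chr2"), c(1.05e7, 3e6))
#' totalBins(makeBins(g, 1e6))  # 11 + 3
#' @export
makeBins <- function(genome, binSize = 1e6) {
  stopifnot(is(genome, "Genome"), binSize > 0)
  nb <- as.integer(ceiling(genome@chromLengths / binSize))
  names(nb) <- genome@chromNames
  off <- cumsum(c(0, as.numeric(nb[-length(nb)])))
  names(off) <- genome@chromNames
  new("BinIndex", genome = genome, binSize = as.numeric(binSize),
      chromBins = nb, offsets = off)
}

#' Map genomic positions to global bin ids
#'
#' Positions are 1-based; the bin ordinal within a chromosome is
#' \code{floor((pos - 1) / binSize)} (bins are 0-based half-open), and the
#' global id is 1-based across chromosomes in genome order.
#'
#' @param chrom chromosome name(s), recycled against \code{pos}.
#' @param pos 1-based genomic position(s).
#' @param binIndex a [BinIndex].
#' @return integer vector of global bin ids.
#' @examples
#' g <- Genome("chr1", 1e7); bi <- makeBins(g, 1e6)
#' assignBin("chr1", c(1, 1e6, 1e6 + 1), bi)  # 1, 1, 2
#' @export
assignBin <- function(chrom, pos, binIndex) {
  stopifnot(is(binIndex, "BinIndex"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  len <- chromLengths(binIndex@genome)[chrom]
  if (anyNA(len))
    stop("unknown chromosome: ", paste(unique(chrom[is.na(len)]),
                                       collapse = ", "))
  if (any(pos < 1 | pos > len))
    stop("position out of chromosome range")
  ordinal <- floor((pos - 1) / binIndex@binSize)
  as.integer(binIndex@offsets[chrom] + ordinal + 1)
}

#' Tabulate all bins of a BinIndex
#'
#' @param binIndex a [BinIndex].
#' @return data.frame with one row per global bin: \code{bin} (global id),
#'   \code{chrom}, \code{start}, \code{end} (1-based, end clipped to the
#'   chromosome length).
#' @export
binTable <- function(binIndex) {
  g <- binIndex@genome
  nb <- binIndex@chromBins
  chrom <- rep(g@chromNames, nb)
  ordinal <- unlist(lapply(nb, function(k) seq_len(k) - 1L), use.names = FALSE)
  start <- ordinal * binIndex@binSize + 1
  end <- pmin(start + binIndex@binSize - 1, chromLengths(g)[chrom])
  data.frame(bin = seq_along(chrom), chrom = chrom, start = start,
             end = unname(end), stringsAsFactors = FALSE)
}

#' Bins of a BinIndex as a GRanges
#'
#' @param binIndex a [BinIndex].
#' @return a \code{GRanges} with one range per global bin, in global bin
#'   order, with metadata column \code{bin}.
#' @export
binGRanges <- function(binIndex) {
  bt <- binTable(binIndex)
  gr <- GenomicRanges::GRanges(
    seqnames = bt$chrom,
    ranges = IRanges::IRanges(start = bt$start, end = bt$end))
  S4Vectors::mcols(gr)$bin <- bt$bin
  gr
}
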