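#' Canonicalize a contact table
#'
#' Orders each contact so that chromA precedes chromB in genome order and,
#' for intra-chromosomal contacts, posA <= posB. Idempotent.
#'
#' @param df data.frame with columns chromA, posA, chromB, posB.
#' @param genome a [Genome] defining chromosome order.
#' @return the canonicalized data.frame.
#' @export
canonicalizeContacts <- function(df, genome) {
  ord <- setNames(seq_along(genome@chromNames), genome@chromNames)
  swap <- ord[df$chromA] > ord[df$chromB] |
    (df$chromA == df$chromB & df$posA > df$posB)
  swap[is.na(swap)] <- FALSE
  if (any(swap)) {
    tmpc <- df$chromA[swap]; tmpp <- df$posA[swap]
    df$chromA[swap] <- df$chromB[swap]; df$posA[swap] <- df$posB[swap]
    df$chromB[swap] <- tmpc; df$posB[swap] <- tmpp
  }
  df
}

#' Read a per-cell contact (pairs) file
#'
#' Reads one cell's chromatin contacts from a pairs-dialect text file:
#' header lines start with \code{#} (metadata as \code{#key: value}); each
#' body line holds at least \code{chrom1 pos1 chrom2 pos2}
#' (whitespace-separated; extra columns ignored). Positions are 1-based.
#' Records on chromosomes absent from \code{genome} are skipped with a
#' warning; records with out-of-range positions are rejected with a
#' warning reporting the count. Reading is gzip-transparent.
#'
#' @param path path to the pairs file.
#' @param genome a [Genome].
#' @param cellId cell identifier; defaults to the header's \code{cellId}
#'   or the file name.
#' @return a [ContactSet] with canonicalized contacts and metadata parsed
#'   from header keys (\code{donor}, \code{age}, \code{ageUnit},
#'   \code{sex}, \code{species}, \code{truth.*}).
#' @seealso [writePairs()]
#' @export
readPairs <- function(path, genome, cellId = NULL) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^#([A-Za-z0-9_.]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  body <- lines[!hdr]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("no contact records in ", path)
  tok <- strsplit(trimws(body), "[ \t]+")
  nfield <- lengths(tok)
  if (any(nfield < 4L))
    stop("unparseable contact line in ", path, " (fewer than 4 fields): '",
         body[which(nfield < 4L)[1]], "'")
  tok <- matrix(unlist(lapply(tok, `[`, 1:4)), ncol = 4, byrow = TRUE)
  posA <- suppressWarnings(as.numeric(tok[, 2]))
  posB <- suppressWarnings(as.numeric(tok[, 4]))
  if (anyNA(posA) || anyNA(posB))
    stop("unparseable position in ", path, " at line '",
         body[which(is.na(posA) | is.na(posB))[1]], "'")
  df <- data.frame(chromA = tok[, 1], posA = posA,
                   chromB = tok[, 3], posB = posB,
                   stringsAsFactors = FALSE)

  known <- df$chromA %in% genome@chromNames & df$chromB %in% genome@chromNames
  if (any(!known)) {
    warning(sum(!known), " contact(s) on unknown chromosome(s) skipped in ",
            basename(path))
    df <- df[known, , drop = FALSE]
  }
  len <- chromLengths(genome)
  inrange <- df$posA >= 1 & df$posA <= len[df$chromA] &
    df$posB >= 1 & df$posB <= len[df$chromB]
  if (any(!inrange)) {
    warning(sum(!inrange), " out-of-range contact(s) rejected in ",
            basename(path))
    df <- df[inrange, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid contacts left in ", path)
  df <- canonicalizeContacts(df, genome)
  rownames(df) <- NULL

  truthKeys <- grep("^truth\\.", names(meta), value = TRUE)
  truth <- lapply(meta[truthKeys], identity)
  names(truth) <- sub("^truth\\.", "", truthKeys)
  if (is.null(cellId))
    cellId <- meta$cellId %||% sub("\\.pairs(\\.gz)?$", "", basename(path))
  new("ContactSet",
      cellId = cellId,
      donor = meta$donor %||% NA_character_,
      age = as.numeric(meta$age %||% NA),
      ageUnit = meta$ageUnit %||% "years",
      sex = meta$sex %||% NA_character_,
      species = meta$species %||% genome@species,
      contacts = df,
      truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-cell contact files
#'
#' Writes each [ContactSet] to \code{<dir>/<cellId>.pairs} with metadata
#' in \code{#key: value} header lines and contacts in deterministic
#' (sorted canonical) order, so a write/read round trip reproduces the
#' input exactly.
#'
#' @param cells a [ContactSet] or list of ContactSets.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writePairs <- function(cells, dir) {
  if (is(cells, "ContactSet")) cells <- list(cells)
  if (length(cells) == 0L) stop("no cells to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cells, function(cell) {
    stopifnot(is(cell, "ContactSet"))
    path <- file.path(dir, paste0(cell@cellId, ".pairs"))
    meta <- c(cellId = cell@cellId, donor = cell@donor,
              age = if (is.na(cell@age)) NA else sprintf("%.17g", cell@age),
              ageUnit = cell@ageUnit,
              sex = cell@sex, species = cell@species)
    if (length(cell@truth))
      meta <- c(meta, setNames(vapply(cell@truth, as.character, ""),
                               paste0("truth.", names(cell@truth))))
    meta <- meta[!is.na(meta)]
    df <- cell@contacts
    df <- df[order(df$chromA, df$posA, df$chromB, df$posB), , drop = FALSE]
    con <- file(path, "wt")
    on.exit(close(con), add = TRUE)
    writeLines(c("## pairs-dialect text, 1-based positions",
                 paste0("#", names(meta), ": ", meta)), con)
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' Read a reference compartment track table
#'
#' Tab-separated table with a header and columns \code{chrom},
#' \code{start} (1-based bin start) and \code{value} in [0, 1]; bins not
#' listed are missing (\code{NA}).
#'
#' @param path path to the track table.
#' @param binIndex a [BinIndex] with the track's bin size.
#' @return a [CompartmentTrack].
#' @export
readTrack <- function(path, binIndex) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "value") %in% names(tab)))
  vals <- rep(NA_real_, totalBins(binIndex))
  ids <- assignBin(tab$chrom, tab$start, binIndex)
  vals[ids] <- tab$value
  new("CompartmentTrack", binIndex = binIndex, values = vals,
      truth = rep(NA_character_, length(vals)),
      dynamicUp = integer(0), dynamicDown = integer(0))
}

#' Write a compartment track table
#'
#' @param track a [CompartmentTrack].
#' @param path output path (tab-separated; columns chrom, start, value;
#'   missing bins omitted).
#' @return invisibly, \code{path}.
#' @export
writeTrack <- function(track, path) {
  bt <- binTable(track@binIndex)
  keep <- !is.na(track@values)
  out <- data.frame(chrom = bt$chrom[keep], start = bt$start[keep],
                    value = track@values[keep])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
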