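#' SNP genotype panel of pooled donors
#'
#' @slot snps data.frame with columns id, chrom, pos, ref, alt.
#' @slot donors donor identifiers.
#' @slot dosage donor x SNP matrix of alt-allele dosages (0/1/2, NA for
#'   missing genotypes).
#'
#' @seealso [readGenotypePanel()], [simulatePool()]
#' @export
setClass("GenotypePanel",
  slots = c(snps = "data.frame", donors = "character", dosage = "matrix"))

setValidity("GenotypePanel", function(object) {
  msg <- NULL
  if (!all(c("id", "chrom", "pos", "ref", "alt") %in% names(object@snps)))
    msg <- c(msg, "snps needs columns id, chrom, pos, ref, alt")
  if (anyDuplicated(paste(object@snps$chrom, object@snps$pos)))
    msg <- c(msg, "SNP positions must be unique per chromosome")
  d <- object@dosage
  if (nrow(d) != length(object@donors) || ncol(d) != nrow(object@snps))
    msg <- c(msg, "dosage must be donors x SNPs")
  if (!all(d %in% c(0, 1, 2) | is.na(d)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel: %d donors x %d SNPs (%.1f%% missing)\n",
              length(object@donors), nrow(object@snps),
              100 * mean(is.na(object@dosage))))
})

#' Sparse per-cell allele observations
#'
#' @slot obs named list (one element per cell) of data.frames with
#'   columns snp, allele ("ref"/"alt") and count (>= 1).
#' @export
setClass("AlleleObservations", slots = c(obs = "list"))

setMethod("show", "AlleleObservations", function(object) {
  n <- vapply(object@obs, nrow, 0L)
  cat(sprintf(
    "AlleleObservations: %d cells, median %d observed SNPs per cell\n",
    length(n), as.integer(median(n))))
})

#' Read a VCF-like genotype panel table
#'
#' Tab-separated with header: columns CHROM, POS, REF, ALT, then one
#' alt-dosage column (0/1/2, NA allowed) per donor.
#'
#' @param path path to the panel table.
#' @return a [GenotypePanel].
#' @export
readGenotypePanel <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("CHROM", "POS", "REF", "ALT")
  stopifnot(all(need %in% names(tab)))
  donors <- setdiff(names(tab), need)
  snps <- data.frame(id = paste0("snp", seq_len(nrow(tab))),
                     chrom = tab$CHROM, pos = tab$POS, ref = tab$REF,
                     alt = tab$ALT, stringsAsFactors = FALSE)
  dosage <- t(as.matrix(tab[donors]))
  colnames(dosage) <- snps$id
  new("GenotypePanel", snps = snps, donors = donors, dosage = dosage)
}

#' Write a genotype panel table
#'
#' @param panel a [GenotypePanel].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGenotypePanel <- function(panel, path) {
  out <- data.frame(CHROM = panel@snps$chrom, POS = panel@snps$pos,
                    REF = panel@snps$ref, ALT = panel@snps$alt,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(t(panel@dosage), check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-donor genotype log-likelihoods for pooled cells
#'
#' For each cell and donor, sums read-level log-probabilities over the
#' cell's allele observations under a binomial error model: a read is alt
#' with probability \code{epsilon} for dosage 0, 0.5 for dosage 1, and
#' 1 - \code{epsilon} for dosage 2; missing genotypes contribute log 0.5
#' per read; observation counts multiply the per-read term.
#'
#' @param obs an [AlleleObservations].
#' @param panel a [GenotypePanel].
#' @param epsilon allele error rate in (0, 0.5).
#' @return cells x donors matrix of log-likelihoods. Cells with zero
#'   observations get a uniform (all-zero) row; their names are in
#'   attribute \code{"uninformative"}.
#' @export
genotypeLogLik <- function(obs, panel, epsilon = 0.01) {
  stopifnot(is(obs, "AlleleObservations"), is(panel, "GenotypePanel"))
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must be in (0, 0.5)")
  pAlt <- c(epsilon, 0.5, 1 - epsilon)  # by dosage 0/1/2
  cells <- names(obs@obs)
  ll <- matrix(0, length(cells), length(panel@donors),
               dimnames = list(cells, panel@donors))
  snpIndex <- setNames(seq_len(nrow(panel@snps)), panel@snps$id)
  for (i in seq_along(cells)) {
    o <- obs@obs[[i]]
    if (nrow(o) == 0L) next
    j <- snpIndex[o$snp]
    if (anyNA(j)) stop("observation references SNP absent from panel")
    isAlt <- o$allele == "alt"
    dos <- panel@dosage[, j, drop = FALSE]  # donors x obs
    p <- matrix(pAlt[dos + 1L], nrow = nrow(dos))
    p[is.na(dos)] <- 0.5
    pRead <- p
    pRead[, !isAlt] <- 1 - p[, !isAlt]
    ll[i, ] <- as.numeric(log(pRead) %*% o$count)
  }
  empty <- cells[vapply(obs@obs, nrow, 0L) == 0L]
  attr(ll, "uninformative") <- empty
  ll
}

#' Assign pooled cells to donors from genotype log-likelihoods
#'
#' Posterior over donors is the softmax of log-likelihood plus log-prior
#' (uniform by default); each cell is assigned its maximum-posterior donor
#' (ties broken deterministically by donor order and flagged ambiguous).
#'
#' @param loglik cells x donors log-likelihood matrix from
#'   [genotypeLogLik()].
#' @param prior prior probability per donor (default uniform).
#' @param ambiguityThreshold flag a cell ambiguous when its top posterior
#'   falls below this value (default 0.95).
#' @return data.frame with one row per cell: \code{cell}, \code{donor},
#'   \code{posterior} (of the assigned donor), \code{ambiguous}. The full
#'   posterior matrix is in attribute \code{"posterior"}.
#' @export
assignDonors <- function(loglik, prior = NULL, ambiguityThreshold = 0.95) {
  nd <- ncol(loglik)
  if (is.null(prior)) prior <- rep(1 / nd, nd)
  stopifnot(length(prior) == nd, all(prior > 0))
  lp <- sweep(loglik, 2, log(prior), "+")
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp) / rowSums(exp(lp))
  top <- apply(post, 1, which.max)  # first max: deterministic tie-break
  topP <- post[cbind(seq_len(nrow(post)), top)]
  ties <- apply(lp, 1, function(r) sum(r == max(r)) > 1L)
  res <- data.frame(cell = rownames(loglik),
                    donor = colnames(loglik)[top],
                    posterior = topP,
                    ambiguous = topP < ambiguityThreshold | ties,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "posterior") <- post
  res
}

#' X-to-autosome contact-density ratio of one cell
#'
#' Each contact contributes two endpoints; the ratio is the X endpoint
#' density (endpoints per bp of X) over the autosomal endpoint density.
#' Expected ~1 for female (XX) and ~0.5 for male (XY) cells.
#'
#' @param cell a [ContactSet].
#' @param genome a [Genome] with an X chromosome.
#' @return the normalized X ratio; 0 when the cell has no X endpoints;
#'   \code{NA} (with a warning) when it has no autosomal endpoints.
#' @export
sexRatio <- function(cell, genome) {
  if (is.na(genome@xChrom)) stop("genome has no X chromosome")
  ep <- c(cell@contacts$chromA, cell@contacts$chromB)
  nX <- sum(ep == genome@xChrom)
  nAuto <- sum(ep %in% genome@autosomes)
  if (nAuto == 0L) {
    warning("cell ", cell@cellId, " has no autosomal endpoints")
    return(NA_real_)
  }
  lenX <- unname(chromLengths(genome)[genome@xChrom])
  lenAuto <- sum(chromLengths(genome)[genome@autosomes])
  (nX / lenX) / (nAuto / lenAuto)
}

#' Demultiplex cells by sex from the X/autosome ratio
#'
#' Applies a fixed cut (default 0.75, the midpoint of the analytic
#' expectations 0.5 for XY and 1.0 for XX) to each cell's [sexRatio()].
#'
#' @param cells list of [ContactSet]s.
#' @param genome a [Genome].
#' @param cut ratio above which a cell is called female.
#' @return data.frame with \code{cell}, \code{ratio}, \code{sex}
#'   ("F"/"M", NA where the ratio is undefined); a ratio histogram (10
#'   equal bins over the observed range) is in attribute
#'   \code{"histogram"} for QC.
#' @export
sexDemux <- function(cells, genome, cut = 0.75) {
  ratio <- vapply(cells, sexRatio, 0, genome = genome)
  res <- data.frame(cell = vapply(cells, cellId, ""),
                    ratio = ratio,
                    sex = ifelse(is.na(ratio), NA_character_,
                                 ifelse(ratio > cut, "F", "M")),
                    stringsAsFactors = FALSE)
  ok <- ratio[!is.na(ratio)]
  if (length(ok))
    attr(res, "histogram") <- graphics::hist(ok, breaks = 10, plot = FALSE)
  res
}
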