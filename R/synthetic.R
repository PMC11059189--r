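## Synthetic single-cell contact generator.
##
## Distances follow a two-component mixture: a truncated power law
## p(s) ~ s^-alpha on [1e4, 1e7) bp for short-range contacts and a
## log-uniform "ultra" tail on [1e7, chromLength] whose mixture weight is
## calibrated so the realized fraction of intra-chromosomal contacts
## >= 10 Mb matches the preset's fUltra.

ULTRA_BP <- 1e7
SHORT_MIN_BP <- 1e4

#' List packaged stage presets
#'
#' @return character vector of preset names shipped with the package.
#' @seealso [stagePreset()]
#' @export
listStagePresets <- function() {
  vapply(.presetLibrary(), function(p) p$name, character(1))
}

#' Load a packaged stage preset
#'
#' Presets encode the contact statistics of granule-cell structure stages
#' S1-S5 (human and mouse) and of reference cell types (forebrain
#' neurons, Purkinje cells, microglia, oligodendrocytes). Ultra-long-range
#' fractions are calibrated to the published per-cell-type values (e.g.
#' human granule S1 0.19, S5 0.33; mouse S5 0.34; mature human forebrain
#' neuron 0.16; adult Purkinje 0.10; microglia 0.34).
#'
#' @param name preset name (see [listStagePresets()]).
#' @return a [StagePreset].
#' @export
stagePreset <- function(name) {
  lib <- .presetLibrary()
  nm <- vapply(lib, function(p) p$name, character(1))
  if (!name %in% nm)
    stop("unknown preset '", name, "'; see listStagePresets()")
  p <- lib[[match(name, nm)]]
  new("StagePreset",
      name = p$name, species = p$species,
      fUltra = p$fUltra, alpha = p$alpha %||% 1.0,
      fInter = p$fInter %||% 0.10, rho = p$rho %||% 0.7,
      drift = p$drift %||% 0,
      hubChroms = as.character(p$hubChroms %||% character(0)),
      hubWeight = p$hubWeight %||% 1.0)
}

.presetLibrary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "stage_presets.yaml",
                          package = "scContacts", mustWork = TRUE)
      cache <<- yaml::read_yaml(path)$presets
    }
    cache
  }
})

#' Chromosome-pair hub weight matrix of a preset
#'
#' Builds the symmetric inter-chromosomal weight matrix: hub-pair entries
#' (both chromosomes in the preset's hub set) carry the preset's hub
#' weight, all other pairs 1, then the off-diagonal entries are normalized
#' to mean 1. The diagonal is zero (unused: intra-chromosomal contacts are
#' sampled separately).
#'
#' @param preset a [StagePreset].
#' @param genome a [Genome].
#' @return symmetric numeric matrix (chromosomes x chromosomes).
#' @export
hubWeightMatrix <- function(preset, genome) {
  cn <- genome@chromNames
  M <- matrix(1, length(cn), length(cn), dimnames = list(cn, cn))
  hub <- intersect(preset@hubChroms, cn)
  if (length(hub) >= 2) M[hub, hub] <- preset@hubWeight
  diag(M) <- 0
  off <- upper.tri(M)
  M[off] <- M[off] / mean(M[off])
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

#' Generate a block-structured reference compartment track with truth
#'
#' Lays alternating A/B blocks along each chromosome (block lengths in
#' bins drawn around \code{blockBinsA}/\code{blockBinsB}), assigns A bins
#' high reference values (uniform 0.6-1.0) and B bins low values (uniform
#' 0.0-0.4), and designates \code{nDynamic} dynamic bins: half "drift-up"
#' bins (picked from B blocks, drifting toward A across stages) and half
#' "drift-down" bins (picked from A blocks). Dynamic bins are re-based
#' into 0.36-0.64 so that, under the stage presets' drift sequence, their
#' effective A/B class flips at transitions spread across all stages,
#' giving graded monotone scA/B trajectories.
#'
#' @param genome a [Genome].
#' @param binSize bin width in bp (default 1 Mb).
#' @param blockBinsA,blockBinsB mean block length in bins for A and B
#'   blocks (Poisson-distributed, minimum 1).
#' @param nDynamic number of dynamic bins to designate (0 for none).
#' @param seed RNG seed.
#' @return a [CompartmentTrack] with truth labels and dynamic-bin sets.
#' @export
makeCompartmentTrack <- function(genome, binSize = 1e6, blockBinsA = 5,
                                 blockBinsB = 5, nDynamic = 0, seed = 1) {
  bi <- makeBins(genome, binSize)
  nb <- totalBins(bi)
  if (nb < 2) stop("genome too small: need at least 2 bins")
  set.seed(seed)
  truth <- character(0)
  for (k in bi@chromBins) {
    lab <- character(0)
    state <- sample(c("A", "B"), 1)
    while (length(lab) < k) {
      mu <- if (state == "A") blockBinsA else blockBinsB
      len <- max(1L, rpois(1, mu))
      lab <- c(lab, rep(state, len))
      state <- if (state == "A") "B" else "A"
    }
    truth <- c(truth, lab[seq_len(k)])
  }
  vals <- ifelse(truth == "A", runif(nb, 0.6, 1.0), runif(nb, 0.0, 0.4))
  up <- down <- integer(0)
  if (nDynamic > 0) {
    nUp <- ceiling(nDynamic / 2); nDown <- nDynamic - nUp
    bIdx <- which(truth == "B"); aIdx <- which(truth == "A")
    if (length(bIdx) < nUp || length(aIdx) < nDown)
      stop("not enough A/B bins to designate ", nDynamic, " dynamic bins")
    up <- sort(sample(bIdx, nUp))
    down <- sort(sample(aIdx, nDown))
    vals[up] <- runif(nUp, 0.36, 0.64)
    vals[down] <- runif(nDown, 0.36, 0.64)
  }
  new("CompartmentTrack", binIndex = bi, values = vals, truth = truth,
      dynamicUp = as.integer(up), dynamicDown = as.integer(down))
}

#' Effective per-bin compartment values under a stage preset
#'
#' Applies the preset's drift to the track's designated dynamic bins
#' (+drift for drift-up bins, -drift for drift-down bins), clamped to
#' [0, 1]. Non-dynamic bins are unchanged.
#'
#' @param track a [CompartmentTrack].
#' @param preset a [StagePreset] (or \code{NULL} for no drift).
#' @return numeric vector of effective values per global bin.
#' @export
effectiveTrack <- function(track, preset = NULL) {
  v <- track@values
  if (!is.null(preset) && preset@drift != 0) {
    v[track@dynamicUp] <- v[track@dynamicUp] + preset@drift
    v[track@dynamicDown] <- v[track@dynamicDown] - preset@drift
    v <- pmin(1, pmax(0, v))
  }
  v
}

## inverse-CDF draw from truncated power law p(s) ~ s^-alpha on [a, b];
## b may be a vector (per-draw upper bound)
.sampleShortDistance <- function(n, alpha, b, a = SHORT_MIN_BP) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-9) {
    exp(log(a) + u * (log(b) - log(a)))
  } else {
    e <- 1 - alpha
    (u * (b^e - a^e) + a^e)^(1 / e)
  }
}

#' Sample intra-chromosomal contact distances for one chromosome
#'
#' Draws from the preset's two-component distance mixture: with
#' probability \code{fUltra} a log-uniform "ultra" distance on
#' [10 Mb, chromLength], otherwise a truncated power-law distance
#' \eqn{p(s) \propto s^{-\alpha}} on [10 kb, 10 Mb). Chromosomes of
#' 10 Mb or less draw only the short component.
#'
#' @param preset a [StagePreset].
#' @param chromLength chromosome length in bp.
#' @param n number of draws.
#' @param fUltra override for the ultra mixture weight (used internally
#'   when correcting for short chromosomes; default the preset's value).
#' @param seed optional RNG seed.
#' @return numeric vector of \code{n} distances in bp.
#' @export
sampleIntraDistance <- function(preset, chromLength, n = 1, fUltra = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fUltra)) fUltra <- preset@fUltra
  d <- numeric(n)
  ultra <- chromLength > ULTRA_BP & runif(n) < fUltra
  if (any(ultra))
    d[ultra] <- exp(log(ULTRA_BP) +
                    runif(sum(ultra)) * (log(chromLength) - log(ULTRA_BP)))
  if (any(!ultra)) {
    b <- min(ULTRA_BP, chromLength) - 1
    d[!ultra] <- .sampleShortDistance(sum(!ultra), preset@alpha, b)
  }
  pmin(round(d), chromLength - 1)
}

## mixture weight per chromosome after correcting for chromosomes too
## short to carry the ultra component; weights w are the anchor-choice
## weights (length x dosage)
.ultraCorrected <- function(fUltra, lengths, w) {
  eligible <- lengths > ULTRA_BP
  pe <- sum(w[eligible]) / sum(w)
  if (pe == 0) return(rep(0, length(lengths)))
  f <- min(1, fUltra / pe)
  ifelse(eligible, f, 0)
}

## uniformly pick an anchor ordinal whose effective A/B class matches the
## class at offset db, by vectorized rejection rounds with an exhaustive
## fallback; o, db are 0-based ordinals, gOff the global bin offset per
## element, maxO the largest admissible ordinal, cls the global class
## vector
.matchAnchors <- function(o, db, gOff, maxO, cls, nRounds = 40L) {
  active <- which(db >= 1L)
  for (r in seq_len(nRounds)) {
    if (!length(active)) break
    ok <- cls[gOff[active] + o[active] + 1L] ==
      cls[gOff[active] + o[active] + db[active] + 1L]
    active <- active[!ok]
    if (!length(active)) break
    o[active] <- floor(runif(length(active)) * (maxO[active] + 1))
  }
  ## exhaustive fallback for (rare) offsets with few or no matching anchors
  for (i in active) {
    cand <- 0:maxO[i]
    hit <- cand[cls[gOff[i] + cand + 1L] == cls[gOff[i] + cand + db[i] + 1L]]
    if (length(hit)) o[i] <- if (length(hit) == 1L) hit else sample(hit, 1)
  }
  o
}

#' Simulate one cell's chromatin contacts
#'
#' Draws \code{nContacts} contacts under a stage preset. Each contact is
#' inter-chromosomal with probability \code{fInter} (chromosome pair drawn
#' proportional to length(i) x length(j) x hubWeight(i,j)); otherwise
#' intra-chromosomal: the anchor chromosome is drawn proportional to
#' length, a distance is drawn from the preset's mixture (corrected for
#' chromosomes shorter than 10 Mb), and anchor/partner positions are
#' placed uniformly within their bins. With probability \code{rho} the
#' anchor bin is chosen so that anchor and partner share the same
#' effective A/B class (the preset's drift shifting designated dynamic
#' bins); inter-chromosomal partners are matched the same way. For male
#' cells the X-chromosome weight is halved (single X).
#'
#' @param preset a [StagePreset].
#' @param genome a [Genome].
#' @param track a [CompartmentTrack] on the same genome.
#' @param nContacts number of contacts to draw (>= 1).
#' @param seed RNG seed.
#' @param sex \code{"F"} or \code{"M"}.
#' @param cellId,donor,age,ageUnit cell metadata.
#' @return a [ContactSet] with truth labels (\code{stage}, \code{sex},
#'   \code{donor}).
#' @export
simulateCell <- function(preset, genome, track, nContacts, seed = 1,
                         sex = "F", cellId = "cell", donor = NA_character_,
                         age = NA_real_, ageUnit = "years") {
  stopifnot(is(preset, "StagePreset"), is(track, "CompartmentTrack"))
  if (nContacts < 1) stop("nContacts must be >= 1")
  set.seed(seed)
  bi <- track@binIndex
  g <- genome
  cn <- g@chromNames
  len <- chromLengths(g)
  nbins <- bi@chromBins
  gOffAll <- bi@offsets
  binSz <- bi@binSize
  eff <- effectiveTrack(track, preset)
  eff[is.na(eff)] <- 0.5
  cls <- eff >= 0.5

  dosage <- setNames(rep(1, length(cn)), cn)
  if (identical(sex, "M") && !is.na(g@xChrom)) dosage[g@xChrom] <- 0.5
  w <- len * dosage

  nInter <- rbinom(1, nContacts, preset@fInter)
  nIntra <- nContacts - nInter

  out <- vector("list", 2)

  if (nIntra > 0) {
    ci <- sample(seq_along(cn), nIntra, replace = TRUE, prob = w)
    fU <- .ultraCorrected(preset@fUltra, len, w)
    L <- len[ci]
    d <- numeric(nIntra)
    ultra <- runif(nIntra) < fU[ci]
    if (any(ultra))
      d[ultra] <- exp(log(ULTRA_BP) +
                      runif(sum(ultra)) * (log(L[ultra]) - log(ULTRA_BP)))
    if (any(!ultra)) {
      b <- pmin(ULTRA_BP, L[!ultra]) - 1
      d[!ultra] <- .sampleShortDistance(sum(!ultra), preset@alpha, b)
    }
    d <- pmin(round(d), L - 1)
    db <- as.integer(round(d / binSz))
    maxO <- nbins[ci] - 1L - db
    fix <- maxO < 0L
    if (any(fix)) { db[fix] <- nbins[ci][fix] - 1L; maxO[fix] <- 0L }
    o <- floor(runif(nIntra) * (maxO + 1))
    hard <- runif(nIntra) < preset@rho
    if (any(hard))
      o[hard] <- .matchAnchors(o[hard], db[hard], gOffAll[ci][hard],
                               maxO[hard], cls)
    posA <- o * binSz + 1 + floor(runif(nIntra) * binSz)
    posB <- (o + db) * binSz + 1 + floor(runif(nIntra) * binSz)
    posA <- pmin(posA, L); posB <- pmin(posB, L)
    out[[1]] <- data.frame(chromA = cn[ci], posA = posA,
                           chromB = cn[ci], posB = posB,
                           stringsAsFactors = FALSE)
  }

  if (nInter > 0) {
    M <- hubWeightMatrix(preset, g)
    pr <- which(upper.tri(M), arr.ind = TRUE)
    pw <- w[pr[, 1]] * w[pr[, 2]] * M[pr]
    k <- sample(nrow(pr), nInter, replace = TRUE, prob = pw)
    ci <- pr[k, 1]; cj <- pr[k, 2]
    oA <- floor(runif(nInter) * nbins[ci])
    oB <- floor(runif(nInter) * nbins[cj])
    hard <- runif(nInter) < preset@rho
    if (any(hard)) {
      ## partner bin drawn uniformly among same-class bins of its chromosome
      clsA <- cls[gOffAll[ci] + oA + 1L]
      grp <- interaction(cj, clsA, drop = TRUE)
      for (gset in split(which(hard), grp[hard])) {
        if (!length(gset)) next
        chrom <- cj[gset[1]]
        want <- clsA[gset[1]]
        pool <- which(cls[gOffAll[chrom] + seq_len(nbins[chrom])] == want) - 1L
        if (length(pool))
          oB[gset] <- pool[ceiling(runif(length(gset)) * length(pool))]
      }
    }
    posA <- pmin(oA * binSz + 1 + floor(runif(nInter) * binSz), len[ci])
    posB <- pmin(oB * binSz + 1 + floor(runif(nInter) * binSz), len[cj])
    out[[2]] <- data.frame(chromA = cn[ci], posA = posA,
                           chromB = cn[cj], posB = posB,
                           stringsAsFactors = FALSE)
  }

  df <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  df <- canonicalizeContacts(df, g)
  rownames(df) <- NULL
  new("ContactSet", cellId = cellId, donor = donor, age = age,
      ageUnit = ageUnit, sex = sex, species = g@species, contacts = df,
      truth = list(stage = preset@name, sex = sex, donor = donor))
}

#' Describe a synthetic cohort
#'
#' @param genome a [Genome].
#' @param track a [CompartmentTrack] (shared reference for all stages).
#' @param stages list of stage blocks, each a list with elements
#'   \code{preset} (a [StagePreset] or preset name), \code{nCells}, and
#'   \code{ageRange} (length-2 numeric, years; ages drawn log-uniformly).
#' @param nContactsMean mean contacts per cell.
#' @param nContactsDisp negative-binomial dispersion (size) of per-cell
#'   contact counts; \code{Inf} for a fixed count.
#' @param seed RNG seed for the whole cohort.
#' @param femaleFrac fraction of female cells.
#' @return a cohort design (list) for [simulateCohort()].
#' @export
cohortDesign <- function(genome, track, stages, nContactsMean = 5000,
                         nContactsDisp = Inf, seed = 1, femaleFrac = 0.5) {
  stopifnot(length(stages) > 0)
  stages <- lapply(stages, function(s) {
    if (is.character(s$preset)) s$preset <- stagePreset(s$preset)
    stopifnot(is(s$preset, "StagePreset"), s$nCells > 0,
              length(s$ageRange) == 2)
    s
  })
  structure(list(genome = genome, track = track, stages = stages,
                 nContactsMean = nContactsMean,
                 nContactsDisp = nContactsDisp, seed = seed,
                 femaleFrac = femaleFrac),
            class = "cohortDesign")
}

#' Default five-stage granule-cell cohort design
#'
#' Five stage presets (S1-S5) of the given species with age ranges
#' spanning the published stage abundance peaks (~0.2, 1, 10, 30 and 80
#' years for human; early postnatal to old age for mouse).
#'
#' @param species \code{"human"} or \code{"mouse"}.
#' @param nCellsPerStage cells per stage (default 100).
#' @param nContacts contacts per cell (fixed; default 20000 -- enough
#'   for most 1-Mb bins to clear the 5-contact scA/B support mask).
#' @param seed cohort seed.
#' @param nDynamic dynamic bins designated in the generated track.
#' @param trackSeed seed for the reference track.
#' @return a cohort design (see [cohortDesign()]); the genome is the
#'   packaged one for the species and the track is generated with truth.
#' @export
defaultCohortDesign <- function(species = c("human", "mouse"),
                                nCellsPerStage = 100, nContacts = 20000,
                                seed = 1, nDynamic = 40, trackSeed = 99) {
  species <- match.arg(species)
  g <- packagedGenome(species)
  track <- makeCompartmentTrack(g, 1e6, nDynamic = nDynamic,
                                seed = trackSeed)
  ageRanges <- if (species == "human")
    list(c(0.1, 0.4), c(0.5, 2), c(5, 20), c(20, 50), c(55, 90))
  else  # postnatal mouse life in years (P3 ~ 0.008 yr to ~1.7 yr)
    list(c(0.008, 0.02), c(0.02, 0.08), c(0.08, 0.3), c(0.3, 0.8),
         c(0.8, 1.7))
  stages <- lapply(1:5, function(s) list(
    preset = stagePreset(sprintf("%s-S%d", species, s)),
    nCells = nCellsPerStage, ageRange = ageRanges[[s]]))
  cohortDesign(g, track, stages, nContactsMean = nContacts,
               nContactsDisp = Inf, seed = seed)
}

## stable per-cell substream seed below 2^31
.cellSeed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 1000003 + idx * 7919) %% 2147483629)
}

#' Simulate a cohort of synthetic cells
#'
#' Draws every cell of the design with a per-cell RNG substream derived
#' from the cohort seed, so cohorts are reproducible and individual cells
#' can be regenerated independently.
#'
#' @param design a design from [cohortDesign()] or
#'   [defaultCohortDesign()].
#' @return list with \code{cells} (list of [ContactSet]) and
#'   \code{metadata} (data.frame: cell, stage truth, age in years, sex,
#'   nContacts).
#' @export
simulateCohort <- function(design) {
  stopifnot(inherits(design, "cohortDesign"))
  set.seed(design$seed)
  plan <- do.call(rbind, lapply(seq_along(design$stages), function(si) {
    s <- design$stages[[si]]
    data.frame(stageIdx = si, stage = s$preset@name, n = seq_len(s$nCells))
  }))
  nTot <- nrow(plan)
  lo <- vapply(design$stages, function(s) s$ageRange[1], 0)[plan$stageIdx]
  hi <- vapply(design$stages, function(s) s$ageRange[2], 0)[plan$stageIdx]
  ages <- exp(runif(nTot, log(lo), log(hi)))
  sexes <- ifelse(runif(nTot) < design$femaleFrac, "F", "M")
  nCon <- if (is.finite(design$nContactsDisp))
    pmax(1L, stats::rnbinom(nTot, mu = design$nContactsMean,
                            size = design$nContactsDisp))
  else rep(as.integer(design$nContactsMean), nTot)

  cells <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    preset <- design$stages[[plan$stageIdx[i]]]$preset
    id <- sprintf("%s_c%03d", plan$stage[i], plan$n[i])
    cells[[i]] <- simulateCell(preset, design$genome, design$track,
                               nCon[i], seed = .cellSeed(design$seed, i),
                               sex = sexes[i], cellId = id,
                               donor = sprintf("donor%02d", plan$stageIdx[i]),
                               age = ages[i], ageUnit = "years")
  }
  meta <- data.frame(cell = vapply(cells, cellId, ""),
                     stage = plan$stage, age = ages, sex = sexes,
                     nContacts = nCon, stringsAsFactors = FALSE)
  list(cells = cells, metadata = meta)
}

#' Simulate a pooled-donor SNP panel and per-cell allele observations
#'
#' Donor genotypes are drawn per SNP as binomial(2, alleleFreq) dosages;
#' each cell (with a true donor drawn uniformly unless given) observes
#' each SNP independently with probability \code{coverage}, reads one
#' allele from the donor's genotype, and the read is flipped with
#' probability \code{epsilon}.
#'
#' @param nDonors number of pooled donors (>= 2).
#' @param nCells number of cells.
#' @param nSNPs number of biallelic SNPs in the panel (>= 1).
#' @param coverage per-SNP observation probability in (0, 1].
#' @param epsilon allele read error rate.
#' @param alleleFreq population alt-allele frequency.
#' @param seed RNG seed.
#' @param trueDonors optional character vector of true donor ids per cell.
#' @return list with \code{panel} (a [GenotypePanel]), \code{obs} (an
#'   [AlleleObservations]) and \code{truth} (true donor per cell).
#' @export
simulatePool <- function(nDonors, nCells, nSNPs, coverage = 0.15,
                         epsilon = 0.01, alleleFreq = 0.5, seed = 1,
                         trueDonors = NULL) {
  stopifnot(nDonors >= 2, nSNPs >= 1)
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  set.seed(seed)
  donors <- sprintf("donor%02d", seq_len(nDonors))
  G <- matrix(rbinom(nDonors * nSNPs, 2, alleleFreq), nrow = nDonors,
              dimnames = list(donors, NULL))
  snps <- data.frame(chrom = "chr1",
                     pos = sort(sample.int(2.4e8, nSNPs)),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  snpIds <- paste0("snp", seq_len(nSNPs))
  colnames(G) <- snpIds
  panel <- new("GenotypePanel", snps = cbind(id = snpIds, snps),
               donors = donors, dosage = G)
  if (is.null(trueDonors))
    trueDonors <- donors[sample.int(nDonors, nCells, replace = TRUE)]
  cellIds <- sprintf("cell%04d", seq_len(nCells))
  obs <- setNames(vector("list", nCells), cellIds)
  for (i in seq_len(nCells)) {
    seen <- which(runif(nSNPs) < coverage)
    if (!length(seen)) {
      obs[[i]] <- data.frame(snp = character(0), allele = character(0),
                             count = integer(0), stringsAsFactors = FALSE)
      next
    }
    gDos <- G[trueDonors[i], seen]
    isAlt <- runif(length(seen)) < gDos / 2
    flip <- runif(length(seen)) < epsilon
    isAlt <- xor(isAlt, flip)
    obs[[i]] <- data.frame(snp = snpIds[seen],
                           allele = ifelse(isAlt, "alt", "ref"),
                           count = 1L, stringsAsFactors = FALSE)
  }
  list(panel = panel,
       obs = new("AlleleObservations", obs = obs),
       truth = setNames(trueDonors, cellIds))
}
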