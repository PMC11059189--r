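test_that("compartment track generation honors design and seed", {
  g <- packagedGenome("human")
  tr1 <- makeCompartmentTrack(g, 1e6, blockBinsA = 6, blockBinsB = 2,
                              seed = 5)
  tr2 <- makeCompartmentTrack(g, 1e6, blockBinsA = 6, blockBinsB = 2,
                              seed = 5)
  expect_identical(trackValues(tr1), trackValues(tr2))
  expect_true(all(trackValues(tr1) >= 0 & trackValues(tr1) <= 1))
  # A bins high, B bins low
  expect_true(all(trackValues(tr1)[tr1@truth == "A"] >= 0.6))
  expect_true(all(trackValues(tr1)[tr1@truth == "B"] <= 0.4))
  # realized A proportion close to the design (Poisson blocks, min 1)
  muA <- 6 + dpois(0, 6); muB <- 2 + dpois(0, 2)
  designed <- muA / (muA + muB)
  expect_lt(abs(mean(tr1@truth == "A") - designed), 0.05)

  # degenerate single-block genome: constant truth label
  g1 <- Genome("chr1", 3e6)
  trc <- makeCompartmentTrack(g1, 1e6, blockBinsA = 100,
                              blockBinsB = 100, seed = 2)
  expect_length(unique(trc@truth), 1L)
  expect_error(makeCompartmentTrack(Genome("chr1", 5e5), 1e6),
               "at least 2 bins")
})

test_that("intra-chromosomal distances follow the two-component mixture", {
  p <- stagePreset("human-S5")
  d0 <- sampleIntraDistance(p, 5e7, n = 2000, fUltra = 0, seed = 1)
  expect_true(all(d0 < 1e7))
  expect_true(all(d0 >= 1e4 - 1))
  d1 <- sampleIntraDistance(p, 5e7, n = 2000, fUltra = 1, seed = 1)
  expect_true(all(d1 >= 1e7 & d1 <= 5e7))
  # short chromosomes draw only the short component
  ds <- sampleIntraDistance(p, 8e6, n = 500, seed = 1)
  expect_true(all(ds < 8e6))
  # empirical ultra fraction within 3 s.e. of the mixture weight
  n <- 1e5
  dm <- sampleIntraDistance(p, 1.5e8, n = n, seed = 42)
  f <- mean(dm >= 1e7)
  se <- sqrt(p@fUltra * (1 - p@fUltra) / n)
  expect_lt(abs(f - p@fUltra), 3 * se)
})

test_that("simulated cells conserve contact counts and X dosage", {
  g <- toyGenome()
  tr <- makeCompartmentTrack(g, 1e6, seed = 3)
  p <- stagePreset("human-S1")
  cell <- simulateCell(p, g, tr, 1234, seed = 9)
  expect_equal(length(cell), 1234L)
  expect_error(simulateCell(p, g, tr, 0), "nContacts")

  xShare <- function(sex, i) {
    cc <- contacts(simulateCell(p, g, tr, 2000, seed = i, sex = sex))
    mean(c(cc$chromA, cc$chromB) == "chrX")
  }
  shareM <- mean(vapply(1:50, function(i) xShare("M", i), 0))
  shareF <- mean(vapply(1:50, function(i) xShare("F", 100 + i), 0))
  # halved X weight: expected share ratio (0.5wX/(wA+0.5wX))/(wX/(wA+wX))
  wX <- 1.5e7; wA <- 5e7
  expected <- (0.5 * wX / (wA + 0.5 * wX)) / (wX / (wA + wX))
  expect_lt(abs(shareM / shareF - expected), 0.05)
})

test_that("full same-compartment preference joins only matching bins", {
  g <- Genome("chr1", 4e7)
  tr <- makeCompartmentTrack(g, 1e6, blockBinsA = 3, blockBinsB = 3,
                             seed = 6)
  p <- stagePreset("human-S3")  # drift 0
  p@rho <- 1; p@fInter <- 0
  cell <- simulateCell(p, g, tr, 3000, seed = 13)
  bi <- tr@binIndex
  cc <- contacts(cell)
  clsA <- trackValues(tr)[assignBin(cc$chromA, cc$posA, bi)] >= 0.5
  clsB <- trackValues(tr)[assignBin(cc$chromB, cc$posB, bi)] >= 0.5
  expect_true(all(clsA == clsB))
})

test_that("per-preset ultra fraction calibrates within 2 points", {
  for (spec in list(list("human-S1", "human"),
                    list("purkinje-adult", "mouse"))) {
    p <- stagePreset(spec[[1]])
    g <- packagedGenome(spec[[2]])
    tr <- makeCompartmentTrack(g, 1e6, seed = 17)
    fr <- vapply(1:100, function(i)
      distanceProfile(simulateCell(p, g, tr, 5000, seed = i))$fraction, 0)
    expect_lt(abs(mean(fr) - p@fUltra), 0.02)
  }
})

test_that("disabling hub weights leaves pair frequencies length-driven", {
  g <- packagedGenome("human")
  tr <- makeCompartmentTrack(g, 1e6, seed = 21)
  p <- stagePreset("human-S1")  # hubWeight 1
  p@fInter <- 1; p@rho <- 0
  cc <- do.call(rbind, lapply(1:20, function(i)
    contacts(simulateCell(p, g, tr, 5000, seed = i))))
  obs <- table(paste(cc$chromA, cc$chromB))
  len <- chromLengths(g)
  pairs <- t(combn(chromNames(g), 2))
  key <- apply(canonicalizeContacts(
    contactDF(pairs[, 1], 1, pairs[, 2], 1), g)[, c(1, 3)], 1, paste,
    collapse = " ")
  w <- len[pairs[, 1]] * len[pairs[, 2]]
  expected <- nrow(cc) * w / sum(w)
  got <- as.numeric(obs[key]); got[is.na(got)] <- 0
  expect_gt(cor(got, expected), 0.99)
  big <- expected > 200
  expect_lt(mean(abs(got[big] - expected[big]) / expected[big]), 0.08)
})

test_that("cohort simulation is reproducible bookkeeping", {
  g <- miniGenome()
  tr <- makeCompartmentTrack(g, 1e6, seed = 2)
  stages <- lapply(1:5, function(s) list(
    preset = stagePreset(sprintf("human-S%d", s)), nCells = 4,
    ageRange = c(s, s + 0.5)))
  des <- cohortDesign(g, tr, stages, nContactsMean = 300, seed = 31)
  coh1 <- simulateCohort(des)
  coh2 <- simulateCohort(des)
  expect_identical(coh1$metadata, coh2$metadata)
  expect_identical(contacts(coh1$cells[[7]]), contacts(coh2$cells[[7]]))
  expect_equal(nrow(coh1$metadata), 20L)
  expect_equal(unname(table(coh1$metadata$stage)["human-S5"]), 4L)
  a5 <- coh1$metadata$age[coh1$metadata$stage == "human-S5"]
  expect_true(all(a5 >= 5 & a5 <= 5.5))
})

test_that("pooled SNP observations follow coverage and the error model", {
  # noise-free, full coverage: every observation at a homozygous site
  # reads the donor's allele exactly, and every SNP is observed
  pool <- simulatePool(2, 10, 50, coverage = 1, epsilon = 1e-12, seed = 5)
  for (i in seq_along(pool$obs@obs)) {
    o <- pool$obs@obs[[i]]
    expect_equal(nrow(o), 50L)
    dos <- pool$panel@dosage[pool$truth[i], o$snp]
    hom <- dos %in% c(0, 2)
    expect_identical(o$allele[hom],
                     unname(ifelse(dos[hom] == 2, "alt", "ref")))
  }

  pool2 <- simulatePool(4, 200, 400, coverage = 0.15, epsilon = 0.01,
                        seed = 9)
  counts <- vapply(pool2$obs@obs, nrow, 0L)
  expect_lt(abs(mean(counts) - 0.15 * 400),
            3 * sqrt(400 * 0.15 * 0.85 / 200))
  pool2b <- simulatePool(4, 200, 400, coverage = 0.15, epsilon = 0.01,
                         seed = 9)
  expect_identical(pool2$obs@obs, pool2b$obs@obs)
  expect_identical(pool2$panel@dosage, pool2b$panel@dosage)
  expect_error(simulatePool(2, 5, 10, coverage = 0), "coverage")
})
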