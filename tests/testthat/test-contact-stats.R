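test_that("distance profiles use intra contacts with inclusive threshold", {
  g <- Genome("chr1", 2e8)
  df <- contactDF("chr1", rep(1, 4), "chr1",
                  c(1e6, 5e6, 1.2e7, 5e7) + 1)
  prof <- distanceProfile(handCell(df, g))
  expect_equal(prof$fraction, 0.5)
  expect_equal(sort(prof$distances), c(1e6, 5e6, 1.2e7, 5e7))

  short <- handCell(contactDF("chr1", c(1, 1), "chr1", c(100, 2e6)), g)
  expect_equal(distanceProfile(short)$fraction, 0)

  # exactly 10 Mb counts in the numerator
  exact <- handCell(contactDF("chr1", 1, "chr1", 1e7 + 1), g)
  expect_equal(distanceProfile(exact)$fraction, 1)

  g2 <- toyGenome()
  interOnly <- handCell(contactDF("chr1", 5, "chr2", 6), g2)
  expect_warning(p <- distanceProfile(interOnly), "no intra")
  expect_true(is.na(p$fraction))
  expect_equal(p$nInter, 1L)
})

test_that("the U test agrees with exhaustive rank enumeration", {
  # closed case: complete separation of 3 vs 3
  res <- compareGroups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)

  # enumeration oracle: exact two-sided p over all C(nA+nB, nA) splits
  enumP <- function(a, b) {
    pool <- c(a, b); nA <- length(a)
    U <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    u0 <- U(a, b)
    splits <- combn(length(pool), nA)
    us <- apply(splits, 2, function(i) U(pool[i], pool[-i]))
    mu <- length(a) * length(b) / 2
    mean(abs(us - mu) >= abs(u0 - mu) - 1e-9)
  }
  set.seed(9)
  for (rep in 1:5) {
    a <- round(runif(sample(3:6, 1)), 3)
    b <- round(runif(sample(3:6, 1)), 3)
    got <- compareGroups(a, b)
    expect_equal(got$p, enumP(a, b), tolerance = 1e-10)
    # U symmetry identity
    expect_equal(got$U + compareGroups(b, a)$U,
                 length(a) * length(b))
  }

  # identical groups: p ~ 1 under the approximation
  set.seed(10)
  x <- rnorm(30)
  expect_gt(compareGroups(x, x)$p, 0.9)
  expect_error(compareGroups(numeric(0), 1), "nonempty")

  # descriptives
  expect_equal(res$meanA, 2); expect_equal(res$sdB, 1)
})

test_that("aggregated maps count and symmetrize contacts correctly", {
  g <- toyGenome()
  one <- handCell(contactDF("chr1", 2.5e5, "chr1", 1.7e6), g)
  m <- aggregateMap(list(one), g, list(type = "chrom", chrom = "chr1"),
                    binSize = 1e6)
  expect_equal(sum(m$counts), 2)  # mirrored off-diagonal
  expect_equal(m$counts[1, 2], 1)
  expect_equal(m$counts[2, 1], 1)

  diagc <- handCell(contactDF("chr1", 1e5, "chr1", 9e5), g)
  md <- aggregateMap(list(diagc), g, list(type = "chrom", chrom = "chr1"),
                     binSize = 1e6)
  expect_equal(sum(md$counts), 1)  # diagonal counted once
  expect_equal(md$counts[1, 1], 1)

  # conservation and loop oracle on 1,000 random contacts
  set.seed(12)
  n <- 1000
  df <- contactDF("chr1", sample.int(3e7, n), "chr1", sample.int(3e7, n))
  cell <- handCell(df, g)
  mm <- aggregateMap(list(cell), g, list(type = "chrom", chrom = "chr1"),
                     binSize = 1e6)
  brute <- matrix(0, 30, 30)
  cc <- contacts(cell)
  for (k in seq_len(n)) {
    i <- floor((cc$posA[k] - 1) / 1e6) + 1
    j <- floor((cc$posB[k] - 1) / 1e6) + 1
    brute[i, j] <- brute[i, j] + 1
    if (i != j) brute[j, i] <- brute[j, i] + 1
  }
  expect_equal(unname(mm$counts), brute)
  expect_equal(mm$counts, t(mm$counts))
  offDiag <- sum(mm$counts) - sum(diag(mm$counts))
  expect_equal(offDiag / 2 + sum(diag(mm$counts)), n)

  # pair scope is endpoint-ordered by the requested chromosomes
  pr <- handCell(contactDF("chr1", 5e5, "chr2", 1.5e6), g)
  mp <- aggregateMap(list(pr), g,
                     list(type = "pair", chromA = "chr2", chromB = "chr1"),
                     binSize = 1e6)
  expect_equal(dim(mp$counts), c(20L, 30L))
  expect_equal(mp$counts[2, 1], 1)

  expect_error(aggregateMap(list(one), g,
                            list(type = "chrom", chrom = "chr2"),
                            binSize = 9e7), "bin size")
  dir <- withr::local_tempdir()
  writeMap(mm, file.path(dir, "map.tsv"))
  back <- as.matrix(read.table(file.path(dir, "map.tsv"), sep = "\t",
                               comment.char = "#"))
  expect_equal(unname(back), unname(mm$counts))
})

test_that("inter-chromosomal enrichment is ~1 under the null and finds hubs", {
  g <- packagedGenome("human")
  tr <- makeCompartmentTrack(g, 1e6, seed = 14)
  null <- stagePreset("human-S1")  # hubWeight 1
  null@fInter <- 0.6; null@rho <- 0
  cellsN <- lapply(1:25, function(i) simulateCell(null, g, tr, 8000,
                                                  seed = 200 + i))
  enrN <- interchromEnrichment(cellsN, g)
  ut <- upper.tri(enrN$enrichment)
  offd <- enrN$enrichment[ut]
  # every pair within ~4 counting s.e. of its expectation
  expect_true(all(abs(enrN$observed[ut] - enrN$expected[ut]) <=
                    4 * sqrt(enrN$expected[ut])))
  expect_lt(abs(mean(offd) - 1), 0.02)
  expect_equal(enrN$enrichment, t(enrN$enrichment))
  # expected matrix sums to the observed inter total (over pairs)
  expect_equal(sum(enrN$expected[upper.tri(enrN$expected)]),
               sum(enrN$observed[upper.tri(enrN$observed)]))

  # a small-length hub recovers ~the designed weight (marginal-product
  # null absorbs part of the weight for large hubs)
  hub <- stagePreset("human-S1")
  hub@hubChroms <- c("chr21", "chr22"); hub@hubWeight <- 2
  hub@fInter <- 0.6; hub@rho <- 0
  cellsH <- lapply(1:25, function(i) simulateCell(hub, g, tr, 8000,
                                                  seed = 300 + i))
  enrH <- interchromEnrichment(cellsH, g)
  nonhub <- setdiff(chromNames(g), c("chr21", "chr22"))
  ratio <- enrH$enrichment["chr21", "chr22"] /
    mean(enrH$enrichment[nonhub, nonhub], na.rm = TRUE)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
  # hub chromosomes top the hub score among themselves
  expect_gt(enrH$enrichment["chr21", "chr22"],
            max(enrH$enrichment[nonhub, nonhub], na.rm = TRUE))
})

test_that("enrichment deltas contrast groups with sign symmetry", {
  g <- packagedGenome("human")
  tr <- makeCompartmentTrack(g, 1e6, seed = 15)
  p <- stagePreset("human-S1"); p@fInter <- 0.5; p@rho <- 0
  cells <- lapply(1:10, function(i) simulateCell(p, g, tr, 5000,
                                                 seed = 400 + i))
  dAA <- enrichmentDelta(cells, cells, g)
  expect_equal(max(abs(dAA), na.rm = TRUE), 0)

  hub <- stagePreset("human-S1")
  hub@hubChroms <- c("chr20", "chr21", "chr22"); hub@hubWeight <- 3
  hub@fInter <- 0.5; hub@rho <- 0
  cellsB <- lapply(1:10, function(i) simulateCell(hub, g, tr, 5000,
                                                  seed = 500 + i))
  dAB <- enrichmentDelta(cells, cellsB, g)
  expect_equal(dAB, -t(enrichmentDelta(cellsB, cells, g))[
    rownames(dAB), colnames(dAB)])
  hubPairs <- dAB[c("chr20", "chr21", "chr22"), c("chr20", "chr21", "chr22")]
  expect_gt(min(hubPairs[upper.tri(hubPairs)]), 0.5)
})
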