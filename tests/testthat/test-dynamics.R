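# build a small ScABMatrix directly from a value matrix (bins x cells)
scabFromMatrix <- function(v, support = NULL) {
  g <- Genome("chr1", nrow(v) * 1e6)
  bi <- makeBins(g, 1e6)
  if (is.null(support)) support <- matrix(20L, nrow(v), ncol(v))
  dimnames(support) <- dimnames(v)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(scab = v, support = support),
    rowData = S4Vectors::DataFrame(binTable(bi),
                                   row.names = seq_len(nrow(v))))
  new("ScABMatrix", se)
}

mkv <- function(nbin, ncell, fill = 0.5) {
  matrix(fill, nbin, ncell,
         dimnames = list(seq_len(nbin), paste0("c", seq_len(ncell))))
}

test_that("stage means average unmasked entries per stage", {
  v <- mkv(3, 4)
  v[, 1] <- c(0.2, 0.6, NA); v[, 2] <- c(0.4, 0.6, 0.8)
  v[, 3] <- c(0.9, 0.1, 0.5); v[, 4] <- c(0.7, 0.3, 0.5)
  m <- scabFromMatrix(v)
  stages <- setNames(c("S1", "S1", "S2", "S2"), colnames(v))
  sm <- stageMeanScAB(m, stages, minSupport = 1)
  expect_equal(sm$means[1, "S1"], 0.3)   # mean of 0.2, 0.4
  expect_equal(sm$means[3, "S1"], 0.8)   # masked entry excluded
  expect_equal(sm$means[1, "S2"], 0.8)
  expect_equal(sm$support[3, "S1"], 1)
  # one cell per stage reproduces that cell
  sm1 <- stageMeanScAB(m[, c(2, 3)],
                       setNames(c("A", "B"), c("c2", "c3")),
                       minSupport = 1)
  expect_equal(unname(sm1$means[, "A"]), unname(v[, 2]))
  expect_error(stageMeanScAB(m, setNames(rep(NA, 4), colnames(v))),
               "stage label")
})

test_that("the top-fraction rule selects exactly round(frac * eligible)", {
  set.seed(21)
  nb <- 2500
  v <- mkv(nb, 10, runif(nb * 10))
  m <- scabFromMatrix(v)
  stages <- setNames(rep(c("S1", "S2"), each = 5), colnames(v))
  sm <- stageMeanScAB(m, stages, minSupport = 5)
  expect_equal(sum(sm$eligible), 2500)
  dyn <- dynamicRegions(sm, topFrac = 0.20)
  expect_length(dyn$bins, 500L)

  # brute-force sort oracle on a hand-made profile
  means <- cbind(S1 = c(0.5, 0.5, rep(0.5, 8)),
                 S2 = c(0.80, 0.75, rep(0.51, 8)))
  smH <- list(means = means, support = matrix(10, 10, 2),
              eligible = rep(TRUE, 10), bins = 1:10)
  dynH <- dynamicRegions(smH, topFrac = 0.2)
  expect_identical(dynH$bins, c(1L, 2L))
  expect_equal(dynH$score, c(0.30, 0.25))

  # all-constant input: deterministic tie-break by bin id
  smC <- list(means = matrix(0.5, 10, 2), support = matrix(10, 10, 2),
              eligible = rep(TRUE, 10), bins = 1:10)
  expect_identical(dynamicRegions(smC, 0.2)$bins, c(1L, 2L))
  expect_error(dynamicRegions(smC, 1.5), "topFrac")
  smS <- smC; smS$eligible <- c(TRUE, TRUE, rep(FALSE, 8))
  expect_error(dynamicRegions(smS, 0.2), "eligible")
})

test_that("trajectory clusters split rising from falling profiles", {
  up <- t(vapply(1:10, function(i) seq(0.2, 0.8, length.out = 5) +
                   i / 100, numeric(5)))
  down <- t(vapply(1:10, function(i) seq(0.9, 0.3, length.out = 5) -
                     i / 100, numeric(5)))
  means <- rbind(up, down)
  rownames(means) <- paste0("b", 1:20)
  lab <- clusterTrajectories(means, k = 2)
  expect_identical(unname(lab[1:10]), rep("increasing", 10))
  expect_identical(unname(lab[11:20]), rep("decreasing", 10))
  # invariant to row permutation
  perm <- sample(20)
  lab2 <- clusterTrajectories(means[perm, ], k = 2)
  expect_identical(lab2[rownames(means)], lab[rownames(means)])
  # k = 1 names the overall trend
  expect_identical(unname(unique(clusterTrajectories(up, k = 1))),
                   "increasing")
  expect_error(clusterTrajectories(up, k = 11), "exceeds")
})

test_that("gene-set trajectories recover drift and stage contrasts", {
  # uniform-value matrix: per-stage means equal the constant
  v <- mkv(20, 6, 0.42)
  m <- scabFromMatrix(v)
  stages <- setNames(rep(c("S1", "S2", "S3"), each = 2), colnames(v))
  gt <- genesetTrajectory(m, stages, bins = 1:20)
  expect_equal(gt$summary$mean, rep(0.42, 3))

  # singleton bin set reproduces the bin's stage means
  v2 <- mkv(5, 4); v2[3, ] <- c(0.1, 0.3, 0.7, 0.9)
  m2 <- scabFromMatrix(v2)
  st2 <- setNames(c("S1", "S1", "S2", "S2"), colnames(v2))
  gt2 <- genesetTrajectory(m2, st2, bins = 3)
  expect_equal(gt2$summary$mean, c(0.2, 0.8))
  expect_equal(nrow(gt2$tests), 1L)
  expect_error(genesetTrajectory(m2, st2, bins = integer(0)))

  # synthetic drift-up bins: strictly increasing means, S1-vs-S5 p < 0.01
  des <- defaultCohortDesign("human", nCellsPerStage = 25,
                             nContacts = 10000, seed = 23)
  coh <- simulateCohort(des)
  sc <- suppressMessages(scabMatrix(coh$cells, des$track))
  stagesT <- setNames(sub("human-", "", coh$metadata$stage),
                      coh$metadata$cell)
  up <- dynamicBins(des$track)$up
  gtd <- genesetTrajectory(sc, stagesT, bins = up)
  expect_true(all(diff(gtd$summary$mean) > 0))
  s1 <- gtd$cellValues[stagesT == "S1"]
  s5 <- gtd$cellValues[stagesT == "S5"]
  expect_lt(compareGroups(s1[!is.na(s1)], s5[!is.na(s5)])$p, 0.01)
})

test_that("dynamic-region selection is enriched for designed drift bins", {
  des <- defaultCohortDesign("human", nCellsPerStage = 25,
                             nContacts = 20000, seed = 29)
  coh <- simulateCohort(des)
  sc <- suppressMessages(scabMatrix(coh$cells, des$track))
  stagesT <- setNames(sub("human-", "", coh$metadata$stage),
                      coh$metadata$cell)
  sm <- stageMeanScAB(sc, stagesT, minSupport = 10)
  dyn <- dynamicRegions(sm, topFrac = 0.20)
  truthBins <- unlist(dynamicBins(des$track))
  recall <- mean(truthBins %in% dyn$bins)
  expect_gte(recall, 0.8)
  # their trajectories cluster into one rising and one falling set
  lab <- clusterTrajectories(dyn$means, k = 2)
  expect_setequal(unique(unname(lab)), c("increasing", "decreasing"))
})

test_that("gene intervals map to every bin they overlap", {
  g <- miniGenome()
  bi <- makeBins(g, 1e6)
  genes <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(1.2e6, 0.9e6, 0.1e6),
                      end = c(1.3e6, 1.1e6, 0.2e6),
                      name = c("gA", "gB", "gC"))
  bins <- mapGenesToBins(genes, bi)
  # gA inside bin 2; gB spans bins 1-2; gC in chr2 bin 1 (global 11)
  expect_identical(bins, c(1L, 2L, 11L))

  expect_warning(b2 <- mapGenesToBins(
    data.frame(chrom = c("chr1", "chr9"), start = c(0, 0),
               end = c(5e5, 5e5)), bi), "unknown")
  expect_identical(b2, 1L)

  # brute-force interval-overlap oracle on 100 random genes
  set.seed(33)
  bt <- binTable(bi)
  rg <- data.frame(chrom = sample(chromNames(g), 100, TRUE),
                   start = sample.int(9e6, 100))
  rg$end <- rg$start + sample.int(3e6, 100)
  rg$end <- pmin(rg$end, chromLengths(g)[rg$chrom])
  rg <- rg[rg$start + 1 <= rg$end, ]
  got <- mapGenesToBins(rg, bi)
  brute <- sort(unique(unlist(lapply(seq_len(nrow(rg)), function(i) {
    bt$bin[bt$chrom == rg$chrom[i] & bt$start <= rg$end[i] &
             bt$end >= rg$start[i] + 1]
  }))))
  expect_identical(got, brute)

  # file-based BED input
  f <- withr::local_tempfile()
  write.table(genes, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_identical(mapGenesToBins(f, bi), c(1L, 2L, 11L))
})
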