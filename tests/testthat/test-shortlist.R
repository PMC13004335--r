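test_that("two-cluster partition matches hand-checked splits", {
  p <- twoClusterPartition(c(1, 2, 10, 11))
  expect_equal(p$high, c(3L, 4L))
  expect_false(p$degenerate)

  p2 <- twoClusterPartition(c(0, 100))
  expect_equal(p2$high, 2L)

  deg <- twoClusterPartition(c(5, 5, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$high, 1:3)

  expect_true(twoClusterPartition(42)$degenerate)
  expect_error(twoClusterPartition(numeric(0)), "empty")
})

test_that("split-point scan attains the exhaustive bipartition optimum", {
  set.seed(77)
  for (rep in 1:120) {
    n <- sample(2:12, 1)
    values <- round(rnorm(n, sd = sample(c(0.5, 5), 1)), 2)
    if (length(unique(values)) == 1L) values[1] <- values[1] + 1
    p <- twoClusterPartition(values)
    expect_equal(withinSS(values, p$high), oracleMinSplitSS(values),
                 tolerance = 1e-9, info = paste(values, collapse = ","))
    expect_gte(mean(values[p$high]), mean(values[p$low]))
  }
})

make_shortlist_fixture <- function(gainMeans, refDf = NULL) {
  n <- length(gainMeans)
  cmpDf <- makeRecords(rep("A", n), rep("B", n), sprintf("LG%d", seq_len(n)),
                       sprintf("RG%d", seq_len(n)), lr_mean = gainMeans)
  if (is.null(refDf)) {
    refDf <- makeRecords("A", "B", "LX", "RX", lr_mean = 1)
    cmpDf <- rbind(cmpDf, refDf)
  }
  compareTables(interactionTable(refDf, "1m"), interactionTable(cmpDf, "3m"))
}

test_that("gain/potential-loss shortlisting selects the high-magnitude cluster", {
  res <- make_shortlist_fixture(c(0.1, 0.2, 3.0))
  sl <- shortlistGainPL(res, "gain")
  expect_equal(sl$ligand[sl$selected], "LG3")
  expect_equal(sl$score, c(0.1, 0.2, 3.0))

  # single-entry category: selected with degenerate flag
  one <- make_shortlist_fixture(5)
  sOne <- shortlistGainPL(one, "gain")
  expect_true(all(sOne$selected) && all(sOne$degenerate))

  # empty category gives an empty shortlist
  expect_equal(nrow(shortlistGainPL(one, "potential_loss")), 0L)

  # scale equivariance: scaling all magnitudes preserves the selection
  scaled <- make_shortlist_fixture(c(0.1, 0.2, 3.0) * 57)
  expect_equal(shortlistGainPL(scaled, "gain")$selected, sl$selected)
})

test_that("consensus shortlisting scores absolute rank change within type", {
  n <- 5
  refDf <- makeRecords(rep("A", n), rep("B", n), sprintf("L%d", 1:n),
                       sprintf("R%d", 1:n), lr_mean = c(10, 8, 6, 4, 2))
  # pair L1 drops from rank 1 to rank 5; everyone else shifts by one
  cmpDf <- refDf
  cmpDf$lr_mean <- c(1, 9, 7, 5, 3)
  res <- compareTables(interactionTable(refDf, "1m"),
                       interactionTable(cmpDf, "3m"))
  sl <- shortlistConsensus(res)
  expect_equal(sl$score[sl$ligand == "L1"], 4)
  expect_equal(sort(sl$score), c(1, 1, 1, 1, 4))
  expect_equal(sl$ligand[sl$selected], "L1")

  # rank swap 1 <-> 2 in a two-pair type scores 1 on both
  refDf2 <- makeRecords(rep("A", 2), rep("B", 2), c("L1", "L2"),
                        c("R1", "R2"), lr_mean = c(2, 1))
  cmpDf2 <- refDf2
  cmpDf2$lr_mean <- c(1, 2)
  swap <- shortlistConsensus(compareTables(interactionTable(refDf2, "1m"),
                                           interactionTable(cmpDf2, "3m")))
  expect_equal(swap$score, c(1, 1))

  # identical rankings: all scores zero, degenerate
  same <- shortlistConsensus(compareTables(interactionTable(refDf, "1m"),
                                           interactionTable(refDf, "3m")))
  expect_true(all(same$score == 0) && all(same$degenerate))
})

test_that("pair frequencies count distinct communication types per category", {
  cl <- data.frame(
    source = c("fibroblast", "cardiomyocyte", "fibroblast", "EC"),
    target = c("fibroblast", "fibroblast", "fibroblast", "EC"),
    ligand = c("FBLN1", "FBLN1", "COL1A1", "FBLN1"),
    receptor = c("ITGB1", "ITGB1", "ITGB1", "ITGB1"),
    category = c("gain", "gain", "gain", "consensus"),
    stringsAsFactors = FALSE)
  fr <- pairFrequencies(cl, "1m->3m")
  fg <- fr[fr$ligand == "FBLN1" & fr$category == "gain", ]
  expect_equal(fg$frequency, 2L)
  # same pair under another category is a separate record
  fc <- fr[fr$ligand == "FBLN1" & fr$category == "consensus", ]
  expect_equal(fc$frequency, 1L)
  expect_equal(fr$frequency[fr$ligand == "COL1A1"], 1L)
  # frequency mass: sums over pairs equal the distinct (type, pair) rows
  expect_equal(sum(fr$frequency[fr$category == "gain"]), 3L)
})

test_that("top-k selection is deterministic, idempotent and order-invariant", {
  set.seed(13)
  fr <- data.frame(ligand = sprintf("L%02d", 1:30),
                   receptor = sprintf("R%02d", 1:30),
                   stage_interval = "1m->3m",
                   category = sample(c("gain", "consensus"), 30, TRUE),
                   frequency = sample(1:8, 30, TRUE),
                   stringsAsFactors = FALSE)
  top <- topKPairs(fr, 10)
  expect_equal(nrow(top), 10L)
  expect_equal(topKPairs(top, 10), top)
  shuf <- fr[sample.int(30), ]
  expect_equal(topKPairs(shuf, 10), top)
  expect_equal(nrow(topKPairs(fr[1:5, ], 20)), 5L)
  # retained frequencies are the k largest
  expect_true(min(top$frequency) >= sort(fr$frequency, decreasing = TRUE)[10])
})

test_that("molecule decomposition counts roles and conserves mass", {
  top <- data.frame(ligand = c("FBLN1", "COL1A1"),
                    receptor = c("ITGB1", "ITGB1"),
                    stage_interval = "1m->3m", category = "gain",
                    stringsAsFactors = FALSE)
  mol <- decomposeMolecules(top)
  itgb1 <- mol[mol$molecule == "ITGB1", ]
  expect_equal(itgb1$occurrence_count, 2L)
  expect_equal(itgb1$n_as_receptor, 2L)
  expect_equal(itgb1$n_as_ligand, 0L)
  # mass conservation: no complexes => total = 2 x pairs
  expect_equal(sum(mol$occurrence_count), 4L)

  cx <- data.frame(ligand = "COL1A1", receptor = "ITGA1_ITGB1",
                   category = "gain", stringsAsFactors = FALSE)
  molSplit <- decomposeMolecules(cx, splitComplexes = TRUE)
  expect_setequal(molSplit$molecule, c("COL1A1", "ITGA1", "ITGB1"))
  molWhole <- decomposeMolecules(cx, splitComplexes = FALSE)
  expect_setequal(molWhole$molecule, c("COL1A1", "ITGA1_ITGB1"))

  expect_equal(nrow(decomposeMolecules(top[0, ])), 0L)
})
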