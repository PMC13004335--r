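test_that("state sets materialise one LR set per communication type", {
  df <- makeRecords(c("A", "A", "B", "B", "A"),
                    c("B", "B", "B", "B", "A"),
                    c("L1", "L2", "L1", "L3", "L4"),
                    c("R1", "R2", "R1", "R3", "R4"))
  ss <- buildStateSet(interactionTable(df, "1m"), 1L)
  expect_s4_class(ss, "StateSet")
  expect_equal(stateIndex(ss), 1L)
  sets <- lrSets(ss)
  expect_setequal(names(sets), c("A->B", "B->B", "A->A"))
  expect_setequal(sets[["A->B"]], c("L1|R1", "L2|R2"))
  # autocrine type (source == target) is an ordinary member
  expect_equal(sets[["A->A"]], "L4|R4")
  expect_equal(sum(lengths(sets)), 5L)

  empty <- buildStateSet(
    doublePvalueFilter(interactionTable(df, "1m"), 1e-9), 2L)
  expect_length(lrSets(empty), 0L)
})

test_that("intersection ratios match hand-computed set arithmetic", {
  expect_equal(intersectionRatios(c("a", "b"), c("a", "b")),
               list(r_ref = 1, r_cmp = 1, n_intersection = 2L))
  expect_equal(intersectionRatios(c("a", "b"), c("a", "b", "c", "d")),
               list(r_ref = 1, r_cmp = 0.5, n_intersection = 2L))
  expect_equal(intersectionRatios(c("a", "b"), c("c", "d")),
               list(r_ref = 0, r_cmp = 0, n_intersection = 0L))
  expect_error(intersectionRatios(character(0), "a"), "empty")
})

test_that("SE score sign conventions and direction labels behave as stated", {
  # identical sets balance to zero under both conventions
  for (conv in c("semantic", "literal")) {
    r <- seScore(c("a", "b"), c("a", "b"), conv)
    expect_identical(r$se, 0)
    expect_identical(r$direction, "stable")
  }
  # strict superset comparator: expansion positive under semantic
  expect_equal(seScore(c("a", "b"), c("a", "b", "c", "d"))$se, 0.5)
  expect_equal(seScore(c("a", "b", "c", "d"), c("a", "b"))$se, -0.5)
  # literal convention preserves the printed algebra r(2) - r(1)
  expect_equal(seScore(c("a", "b"), c("a", "b", "c", "d"), "literal")$se, -0.5)
  # complete turnover balances to zero but is not "unchanged"
  turn <- seScore(c("a", "b"), c("c", "d"))
  expect_identical(turn$se, 0)
  expect_identical(turn$direction, "stable")
  expect_error(seScore(character(0), character(0)), "empty")
})

test_that("single-state communication types are emergent or vanished", {
  em <- seScore(character(0), c("a", "b"))
  expect_identical(em$direction, "emergent")
  expect_identical(em$se, 1)
  expect_true(is.na(em$r_ref))
  va <- seScore(c("a", "b"), character(0))
  expect_identical(va$direction, "vanished")
  expect_identical(va$se, -1)
  # literal convention negates, preserving antisymmetry
  expect_identical(seScore(character(0), c("a"), "literal")$se, -1)
})

test_that("classification endpoints match the ratio semantics", {
  r <- classifyUnits(c("a", "b"), c("b", "c"))
  expect_equal(r$consensus, "b")
  expect_equal(r$gain, "c")
  expect_equal(r$potential_loss, "a")
  expect_equal(r$gain_ratio, 0.5)
  expect_equal(r$potential_loss_ratio, 0.5)
  # completely new comparator content: GR = 1
  expect_equal(classifyUnits("a", "b")$gain_ratio, 1)
  # fully preserved reference content: PLR = 0
  expect_equal(classifyUnits("a", c("a", "b"))$potential_loss_ratio, 0)
  # identity: all consensus, both ratios zero
  ident <- classifyUnits(c("a", "b"), c("a", "b"))
  expect_equal(ident$consensus, c("a", "b"))
  expect_equal(ident$gain_ratio, 0)
  expect_equal(ident$potential_loss_ratio, 0)
})

test_that("SE and classification agree with the naive oracle on random sets", {
  set.seed(101)
  universe <- randomPairUniverse(12)
  for (i in 1:300) {
    lRef <- randomSubset(universe)
    lCmp <- randomSubset(universe)
    for (conv in c("semantic", "literal")) {
      expect_equal(seScore(lRef, lCmp, conv)$se, oracleSE(lRef, lCmp, conv))
    }
    got <- classifyUnits(lRef, lCmp)
    want <- oracleClassify(lRef, lCmp)
    expect_equal(got[c("consensus", "gain", "potential_loss")],
                 want[c("consensus", "gain", "potential_loss")])
    expect_equal(got$gain_ratio, want$gain_ratio)
    expect_equal(got$potential_loss_ratio, want$potential_loss_ratio)
    # partition law and ratio complements
    expect_setequal(c(got$consensus, got$gain, got$potential_loss),
                    union(lRef, lCmp))
    expect_equal(length(got$consensus) + length(got$gain), length(lCmp))
    expect_equal(length(got$consensus) + length(got$potential_loss),
                 length(lRef))
    expect_equal(got$gain_ratio + length(got$consensus) / length(lCmp), 1)
    expect_equal(got$potential_loss_ratio +
                   length(got$consensus) / length(lRef), 1)
    # antisymmetry and bounds
    expect_equal(seScore(lRef, lCmp)$se, -seScore(lCmp, lRef)$se)
    expect_lte(abs(seScore(lRef, lCmp)$se), 1)
  }
})

test_that("strict set containment forces the semantic SE sign", {
  set.seed(7)
  universe <- randomPairUniverse(10)
  for (i in 1:50) {
    small <- randomSubset(universe[1:9])
    big <- union(small, sample(setdiff(universe, small), 1))
    expect_gt(seScore(small, big)$se, 0)
    expect_lt(seScore(big, small)$se, 0)
  }
})

test_that("compareStates covers the union of communication types", {
  refDf <- makeRecords(c("A", "A"), c("B", "B"), c("L1", "L2"), c("R1", "R2"))
  cmpDf <- makeRecords(c("A", "C"), c("B", "C"), c("L1", "L9"), c("R1", "R9"))
  res <- compareStates(
    buildStateSet(interactionTable(refDf, "1m"), 1L),
    buildStateSet(interactionTable(cmpDf, "3m"), 2L))
  se <- seTable(res)
  expect_equal(nrow(se), 2L)
  expect_equal(se$direction[se$source == "C"], "emergent")
  cl <- classificationTable(res)
  expect_equal(sort(unique(cl$category)),
               c("consensus", "gain", "potential_loss"))

  # identical state sets: everything stable, all-consensus
  same <- compareStates(
    buildStateSet(interactionTable(refDf, "1m"), 1L),
    buildStateSet(interactionTable(refDf, "3m"), 2L))
  expect_true(all(seTable(same)$direction == "stable"))
  expect_true(all(classificationTable(same)$category == "consensus"))

  # swapped indices rejected
  expect_error(compareStates(
    buildStateSet(interactionTable(refDf, "1m"), 2L),
    buildStateSet(interactionTable(cmpDf, "3m"), 1L)), "stateIndex")
})

test_that("compareTables annotates magnitudes on the correct side", {
  refDf <- makeRecords(c("A", "A"), c("B", "B"), c("L1", "L2"),
                       c("R1", "R2"), lr_mean = c(1.0, 2.0))
  cmpDf <- makeRecords(c("A", "A"), c("B", "B"), c("L1", "L3"),
                       c("R1", "R3"), lr_mean = c(1.5, 3.0))
  res <- compareTables(interactionTable(refDf, "1m"),
                       interactionTable(cmpDf, "3m"))
  cl <- classificationTable(res)
  cons <- cl[cl$category == "consensus", ]
  expect_equal(cons$lr_mean_ref, 1.0)
  expect_equal(cons$lr_mean_cmp, 1.5)
  gain <- cl[cl$category == "gain", ]
  expect_true(is.na(gain$lr_mean_ref) && gain$lr_mean_cmp == 3.0)
  pl <- cl[cl$category == "potential_loss", ]
  expect_true(pl$lr_mean_ref == 2.0 && is.na(pl$lr_mean_cmp))
})

test_that("organ aggregation excludes stable types and guards division", {
  se <- data.frame(se = c(0.2, 0.4, 0.9, -0.1, 0, 0, 0, 0, 0, 0),
                   direction = c(rep("expanding", 3), "shrinking",
                                 rep("stable", 6)))
  organ <- aggregateOrgan(se)
  expect_equal(organ$n_expand, 3L)
  expect_equal(organ$n_shrink, 1L)
  expect_equal(organ$n_stable, 6L)
  expect_equal(organ$n_total, 4L)
  expect_equal(organ$se_organ, 0.5)

  allUp <- aggregateOrgan(data.frame(se = c(0.1, 0.2),
                                     direction = rep("expanding", 2)))
  expect_equal(allUp$se_organ, 1)

  expect_warning(
    none <- aggregateOrgan(data.frame(se = 0, direction = "stable")),
    "undefined")
  expect_true(is.na(none$se_organ))

  withEm <- data.frame(se = c(1, -0.5), direction = c("emergent", "shrinking"))
  expect_equal(aggregateOrgan(withEm)$n_expand, 1L)
  expect_equal(suppressWarnings(
    aggregateOrgan(withEm, includeEmergent = FALSE))$n_expand, 0L)
})
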