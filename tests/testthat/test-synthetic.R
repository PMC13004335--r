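test_that("generated tables validate and the same seed is byte-identical", {
  syn <- generateTwoState(nCommTypes = 5, seed = 42)
  expect_s4_class(syn$ref, "InteractionTable")
  expect_true(validObject(syn$ref) && validObject(syn$cmp))
  syn2 <- generateTwoState(nCommTypes = 5, seed = 42)
  expect_identical(interactionData(syn$ref), interactionData(syn2$ref))
  expect_identical(interactionData(syn$cmp), interactionData(syn2$cmp))
  expect_identical(syn$truth, syn2$truth)
  syn3 <- generateTwoState(nCommTypes = 5, seed = 43)
  expect_false(identical(interactionData(syn$ref),
                         interactionData(syn3$ref)))
})

test_that("filtering recovers exactly the planted sets; decoys never leak", {
  syn <- generateTwoState(nCommTypes = 6, nDecoys = 5, seed = 9)
  refF <- doublePvalueFilter(syn$ref, syn$truth$p_threshold)
  sets <- lrSets(buildStateSet(refF, 1L))
  for (k in names(syn$truth$types)) {
    t <- syn$truth$types[[k]]
    planted <- sort(c(t$consensus, t$potential_loss))
    expect_equal(sort(sets[[k]]), planted, info = k)
  }
  # decoy rows carry >= 1 failing p-value, planted rows pass both
  raw <- interactionData(syn$ref)
  kept <- interactionData(refF)
  dropped <- raw[!paste(raw$source, raw$target, raw$ligand, raw$receptor) %in%
                   paste(kept$source, kept$target, kept$ligand, kept$receptor), ]
  expect_true(all(pmax(dropped$pval_method_a, dropped$pval_method_b) >= 0.05))
})

test_that("planted truth satisfies the partition law and SE arithmetic", {
  syn <- generateTwoState(nCommTypes = 8, seed = 3)
  for (t in syn$truth$types) {
    expect_equal(length(t$consensus) + length(t$potential_loss), t$n_ref)
    expect_equal(length(t$consensus) + length(t$gain), t$n_cmp)
    expect_equal(t$se, seScore(c(t$consensus, t$potential_loss),
                               c(t$consensus, t$gain))$se)
  }
  org <- syn$truth$organ
  expect_equal(org$n_total, org$n_expand + org$n_shrink)
})

test_that("explicitly planted sets drive the tables and the truth", {
  sets <- list(
    "FB->FB" = list(consensus = c("A|B"), gain = c("FBLN1|ITGB1"),
                    potential_loss = character(0)),
    "CM->FB" = list(consensus = c("A|B", "C|D"), gain = c("FBLN1|ITGB1"),
                    potential_loss = c("E|F")))
  syn <- generateTwoState(sets = sets, nDecoys = 2, seed = 5)
  expect_equal(syn$truth$types[["FB->FB"]]$gain, "FBLN1|ITGB1")
  res <- compareTables(syn$ref, syn$cmp)
  cl <- classificationTable(res)
  gains <- cl[cl$category == "gain" & cl$ligand == "FBLN1", ]
  expect_equal(nrow(gains), 2L)
})

test_that("identical planted states are all stable with undefined organ SE", {
  sets <- list(
    "A->A" = list(consensus = c("a|x", "b|y"), gain = character(0),
                  potential_loss = character(0)),
    "A->B" = list(consensus = c("c|z"), gain = character(0),
                  potential_loss = character(0)))
  syn <- generateTwoState(sets = sets, seed = 2)
  expect_true(all(vapply(syn$truth$types, function(t) t$direction,
                         character(1)) == "stable"))
  expect_true(is.na(syn$truth$organ$se_organ))
  res <- compareTables(syn$ref, syn$cmp)
  expect_true(all(seTable(res)$se == 0))
})

test_that("size preconditions reject empty states unless emergent requested", {
  bad <- data.frame(consensus = 0, gain = 3, loss = 0)
  expect_error(generateTwoState(nCommTypes = 1, sizes = bad, seed = 1),
               "allowEmergent")
  ok <- generateTwoState(nCommTypes = 1, sizes = bad, allowEmergent = TRUE,
                         seed = 1)
  expect_equal(ok$truth$types[[1]]$direction, "emergent")
  expect_equal(ok$truth$types[[1]]$se, 1)
})

test_that("lifespan series chains transitions consistently", {
  ser <- generateLifespanSeries(nStates = 4, nCommTypes = 4, seed = 21)
  expect_length(ser$tables, 4L)
  expect_length(ser$truth$transitions, 3L)
  # state s+1's reference set equals state s's comparator set
  for (i in 1:2) {
    a <- ser$truth$transitions[[i]]
    b <- ser$truth$transitions[[i + 1]]
    for (k in names(a$types)) {
      cmpSet <- sort(c(a$types[[k]]$consensus, a$types[[k]]$gain))
      refSet <- sort(c(b$types[[k]]$consensus, b$types[[k]]$potential_loss))
      expect_equal(cmpSet, refSet, info = sprintf("interval %d type %s", i, k))
    }
  }
  # each transition's truth is recovered by the pipeline on its two tables
  for (i in seq_along(ser$truth$transitions)) {
    tr <- ser$truth$transitions[[i]]
    res <- compareTables(ser$tables[[i]], ser$tables[[i + 1]])
    se <- seTable(res)
    for (k in names(tr$types)) {
      row <- se[commKeyRow(se) == k, ]
      expect_equal(row$se, tr$types[[k]]$se, info = k)
    }
  }
})

test_that("pure-growth and alternating drift plant the promised signs", {
  grow <- generateLifespanSeries(
    nStates = 4, nCommTypes = 3,
    driftSpec = data.frame(nGain = c(3, 3, 3), nLoss = c(0, 0, 0)),
    seed = 8)
  organSE <- vapply(grow$truth$transitions, function(t) t$organ$se_organ,
                    numeric(1))
  expect_true(all(organSE > 0))

  zero <- generateLifespanSeries(
    nStates = 3, nCommTypes = 3,
    driftSpec = data.frame(nGain = c(0, 0), nLoss = c(0, 0)), seed = 8)
  expect_true(all(is.na(vapply(zero$truth$transitions,
                               function(t) t$organ$se_organ, numeric(1)))))

  alt <- generateLifespanSeries(
    nStates = 3, nCommTypes = 3, initSize = 10,
    driftSpec = data.frame(nGain = c(4, 0), nLoss = c(0, 4)), seed = 8)
  se <- vapply(alt$truth$transitions, function(t) t$organ$se_organ,
               numeric(1))
  expect_true(se[1] > 0 && se[2] < 0)
})

test_that("planted cross-type frequency structure is recovered exactly", {
  pair <- "FBLN1|ITGB1"
  sets <- list(
    "FB->FB" = list(consensus = "a|x", gain = pair,
                    potential_loss = character(0)),
    "CM->FB" = list(consensus = "b|y", gain = pair,
                    potential_loss = character(0)),
    "EC->EC" = list(consensus = c("c|z", pair), gain = character(0),
                    potential_loss = character(0)))
  syn <- generateTwoState(sets = sets, seed = 17)
  res <- compareTables(syn$ref, syn$cmp)
  fr <- pairFrequencies(classificationTable(res), "1m->3m")
  expect_equal(fr$frequency[fr$ligand == "FBLN1" & fr$category == "gain"], 2L)
  expect_equal(fr$frequency[fr$ligand == "FBLN1" &
                              fr$category == "consensus"], 1L)
})
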