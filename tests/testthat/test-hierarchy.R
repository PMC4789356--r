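test_that("defaultParams returns the published working points", {
  expect_equal(defaultParams("HbL_vs_non", "AC"), list(gamma = 25, cost = 400))
  expect_equal(defaultParams("sHb", "PSSM"), list(gamma = 5, cost = 7))
  expect_equal(defaultParams("fg_cyto_FAD_NAD", "DC"),
               list(gamma = 5, cost = 200))
  expect_equal(defaultParams("HbL_vs_non", "hybrid"),
               list(gamma = 0.1, cost = 375))
  ## the shared domain tasks carry the subfamily working points
  expect_equal(defaultParams("single_domain", "AC"), defaultParams("sHb", "AC"))
  expect_equal(defaultParams("trunc_domain", "MM"), defaultParams("trHb", "MM"))
  err <- tryCatch(defaultParams("bogus", "AC"), error = conditionMessage)
  expect_match(err, "valid tasks")
})

test_that("trainHierarchy builds nine task models with shared domain models", {
  ds <- generateDataset(nPerClass = 25, seed = 14, separation = 8)
  reg <- trainHierarchy(ds, "AC", seed = 1)
  expect_s4_class(reg, "ModelRegistry")
  expect_setequal(names(reg@models), hblTasks())
  expect_identical(getModel(reg, "single_domain"), getModel(reg, "sHb"))
  expect_identical(getModel(reg, "trunc_domain"), getModel(reg, "trHb"))
  expect_error(getModel(reg, "nope"), "no model for task")

  ## each subfamily model is positive on its own class's training examples
  feat <- encodeSequences(ds, "AC")
  lab <- labelTable(ds)
  for (task in subfamilyTasks()) {
    own <- lab$id[!is.na(lab$subfamily) & lab$subfamily == task]
    sc <- decisionScore(getModel(reg, task), feat[own, , drop = FALSE])
    expect_gt(mean(sc >= 0), 0.9)
  }

  ## a single-class task is a hard error
  sub <- ds[lab$class == "nonHbL" | (!is.na(lab$subfamily) & lab$subfamily == "sHb")]
  expect_error(trainHierarchy(sub, "AC"), "single class")
})

test_that("stage gating and argmax subfamily assignment behave as documented", {
  ds <- generateDataset(nPerClass = 60, seed = 15, separation = 8)
  reg <- trainHierarchy(ds, "AC", seed = 1)
  test <- generateDataset(nPerClass = 20, seed = 16, separation = 8)
  pred <- predictHierarchy(test, reg)
  lab <- labelTable(test)

  ## gating: no subfamily/domain call without a positive stage-1 score
  neg <- pred$stage1_label == "nonHbL"
  expect_true(any(neg))
  expect_true(all(is.na(pred$subfamily[neg])))
  expect_true(all(is.na(pred$domain[neg])))
  expect_true(all(is.na(pred$sHb_score[neg])))

  ## synthetic sHb-like sequences are assigned subfamily sHb
  shbIdx <- which(lab$subfamily == "sHb" & pred$stage1_label == "HbL")
  expect_gt(mean(pred$subfamily[shbIdx] == "sHb", na.rm = TRUE), 0.95)

  ## assignment is the arg-max of the three subfamily scores
  pos <- which(pred$stage1_label == "HbL" & !is.na(pred$subfamily))
  sc <- as.matrix(pred[pos, paste0(subfamilyTasks(), "_score")])
  expect_identical(pred$subfamily[pos],
                   subfamilyTasks()[apply(sc, 1, which.max)])
  ## all-negative subfamily scores mean unclassified HbL, never a label
  allneg <- which(pred$stage1_label == "HbL" &
                  pred$sHb_score < 0 & pred$flavoHb_score < 0 &
                  pred$trHb_score < 0)
  expect_true(all(is.na(pred$subfamily[allneg])))
})

test_that("every stage reaches >= 95% pooled CV accuracy on separable data", {
  ds <- generateDataset(nPerClass = 60, seed = 17, separation = 8)
  for (task in c("HbL_vs_non", "sHb", "flavoHb", "trHb", "fg_cyto_FAD_NAD")) {
    y <- taskLabels(ds, task)
    feat <- encodeSequences(ds[names(y)], "AC")
    p <- defaultParams(task, "AC")
    cv <- crossValidate(feat, y, gamma = p$gamma, cost = p$cost, k = 5,
                        seed = 5, scheme = "AC")
    expect_gte(cv$pooled[["ACC"]], 95)
  }
})

test_that("retraining with the same seed reproduces identical predictions", {
  ds <- generateDataset(nPerClass = 20, seed = 18, separation = 8)
  test <- generateDataset(nPerClass = 10, seed = 19, separation = 8)
  r1 <- trainHierarchy(ds, "AC", seed = 4)
  r2 <- trainHierarchy(ds, "AC", seed = 4)
  expect_identical(predictHierarchy(test, r1), predictHierarchy(test, r2))
})

test_that("registries round-trip through the model directory format", {
  ds <- generateDataset(nPerClass = 20, seed = 20, separation = 8)
  test <- generateDataset(nPerClass = 8, seed = 21, separation = 8)
  reg <- trainHierarchy(ds, "AC", seed = 1)
  dir <- tempfile()
  saveRegistry(reg, dir)
  reg2 <- loadRegistry(dir)
  expect_identical(reg2@scheme, "AC")
  p1 <- predictHierarchy(test, reg)
  p2 <- predictHierarchy(test, reg2)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(loadRegistry(tempfile()), "registry.json")
})

test_that("the PSSM scheme runs through the whole hierarchy", {
  ds <- generateDataset(nPerClass = 15, seed = 22, separation = 8)
  seqs <- sequences(ds)
  pssms <- lapply(seq_along(seqs), function(i)
    generatePSSM(as.character(seqs[i]), signal = 0.9, seed = 1000 + i))
  names(pssms) <- names(seqs)
  reg <- trainHierarchy(ds, "PSSM", seed = 1, pssms = pssms)
  pred <- predictHierarchy(ds, reg, pssms = pssms)
  lab <- labelTable(ds)
  expect_gt(mean((pred$stage1_label == "HbL") == (lab$class == "HbL")), 0.95)
  expect_error(predictHierarchy(ds, reg), "requires")
})
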