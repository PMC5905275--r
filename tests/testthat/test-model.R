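test_that("stratified split matches round(class * fraction) per class", {
  ms <- moleculeSet(paste0("m", 1:10), rep("C", 10),
                    rep(c("sweet", "bitter"), each = 5))
  sp <- stratifiedSplit(ms, 0.2, seed = 4)
  expect_equal(length(sp$train), 8L)
  expect_equal(length(sp$test), 2L)
  expect_equal(sort(unique(tasteLabels(sp$test))), c("bitter", "sweet"))
  # union of parts is the input
  expect_setequal(c(molIds(sp$train), molIds(sp$test)), molIds(ms))
  # deterministic given seed
  sp2 <- stratifiedSplit(ms, 0.2, seed = 4)
  expect_identical(molIds(sp$test), molIds(sp2$test))
  sp3 <- stratifiedSplit(ms, 0.2, seed = 5)
  expect_false(identical(molIds(sp$test), molIds(sp3$test)))
})

test_that("per-class test counts use round-half-even at the 517/685 sizes", {
  big <- moleculeSet(paste0("m", 1:1202), rep("C", 1202),
                     c(rep("sweet", 517), rep("bitter", 685)))
  sp <- stratifiedSplit(big, 0.2, seed = 1)
  tab <- table(tasteLabels(sp$test))
  expect_equal(unname(tab[["sweet"]]), 103L)    # round(0.2 * 517)
  expect_equal(unname(tab[["bitter"]]), 137L)   # round(0.2 * 685)
  expect_equal(length(sp$train), 1202L - 240L)
  expect_error(stratifiedSplit(moleculeSet("a", "C"), 0.2, 1), "labeled")
  one <- moleculeSet(c("a", "b", "c"), rep("C", 3),
                     c("sweet", "bitter", "bitter"))
  expect_error(stratifiedSplit(one, 0.2, 1), "too small")
})

test_that("training reflects the configuration and retains fingerprints", {
  ms <- pureFixture()
  cfg <- rfConfig(nTrees = 200, seed = 3)
  model <- trainTasteForest(ms, cfg)
  expect_s4_class(model, "TasteForest")
  expect_equal(model@forest$num.trees, 200)
  expect_equal(dim(trainingFingerprints(model)), c(40L, 2048L))
  expect_equal(modelClasses(model), c("bitter", "sweet"))
  expect_error(trainTasteForest(ms[tasteLabels(ms) == "sweet"], cfg),
               "both classes")
})

test_that("a separable set is learned to perfection on its training data", {
  ms <- pureFixture()
  model <- trainTasteForest(ms, rfConfig(nTrees = 1000, seed = 5))
  pred <- predictTaste(model, ms)
  expect_equal(pred$predicted_class, tasteLabels(ms))
  expect_true(all(pred$confidence > 0.9))
})

test_that("prediction scores are proper probabilities in input order", {
  ms <- midFixture()
  model <- trainTasteForest(ms[1:30], rfConfig(nTrees = 100, seed = 2))
  pred <- predictTaste(model, ms)
  expect_equal(pred$id, molIds(ms))
  expect_equal(pred$score_sweet + pred$score_bitter, rep(1, length(ms)),
               tolerance = 1e-9)
  expect_equal(pred$confidence, pmax(pred$score_sweet, pred$score_bitter))
  expect_true(all(pred$confidence >= 0.5 & pred$confidence <= 1))
  # row-order equivariance
  perm <- rev(seq_len(length(ms)))
  pred2 <- predictTaste(model, ms[perm])
  expect_equal(pred2$score_sweet, pred$score_sweet[perm])
  # empty input -> empty output
  expect_equal(nrow(predictTaste(model, ms[integer(0)])), 0L)
})

test_that("training and prediction are deterministic given the seed", {
  ms <- midFixture()
  cfg <- rfConfig(nTrees = 150, seed = 42)
  p1 <- predictTaste(trainTasteForest(ms, cfg), ms)
  p2 <- predictTaste(trainTasteForest(ms, cfg), ms)
  expect_identical(p1, p2)
  p3 <- predictTaste(trainTasteForest(ms, rfConfig(nTrees = 150, seed = 43)),
                     ms)
  expect_false(identical(p1$score_sweet, p3$score_sweet))
})

test_that("leave-one-out returns one out-of-sample prediction per record", {
  ms <- midFixture()[c(1:8, 21:28)]
  cv <- looCV(ms, rfConfig(nTrees = 80, seed = 6))
  expect_equal(nrow(cv), 16L)
  expect_equal(cv$id, molIds(ms))
  expect_equal(cv$label, tasteLabels(ms))
  # separable signal is recovered out of sample
  pure <- pureFixture()
  cvp <- looCV(pure, rfConfig(nTrees = 200, seed = 6))
  expect_equal(mean(cvp$predicted_class == cvp$label), 1)
  expect_equal(rocAUC(cvp$label, cvp$score_sweet), 1)
})

test_that("k-fold cross-validation is stratified and seed-stable", {
  ms <- midFixture()
  cfg <- rfConfig(nTrees = 100, seed = 8)
  cv1 <- crossValidate(ms, cfg, method = "kfold", folds = 5)
  cv2 <- crossValidate(ms, cfg, method = "kfold", folds = 5)
  expect_identical(cv1, cv2)
  expect_equal(nrow(cv1), length(ms))
  expect_equal(cv1$id, molIds(ms))
  expect_gt(rocAUC(cv1$label, cv1$score_sweet), 0.8)
})

test_that("fingerprint comparison returns one AUC-sorted row per kind", {
  ms <- midFixture()
  tab <- compareFingerprints(ms, kinds = c("morgan", "atompair"),
                             config = rfConfig(nTrees = 100, seed = 9),
                             method = "kfold", folds = 5)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$fingerprint, c("morgan", "atompair"))
  expect_true(!is.unsorted(rev(tab$roc_auc)))
  expect_error(compareFingerprints(ms, kinds = "morgan"), "at least two")
})

test_that("model bundles round-trip through serialization", {
  ms <- pureFixture()
  model <- trainTasteForest(ms, rfConfig(nTrees = 100, seed = 10))
  path <- tempfile(fileext = ".rds")
  saveTasteForest(model, path)
  back <- readTasteForest(path)
  expect_equal(modelConfig(back)@seed, 10L)
  expect_equal(modelConfig(back)@fingerprint, "morgan")
  expect_identical(predictTaste(back, ms), predictTaste(model, ms))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(meta = list(format = "other")), bad)
  expect_error(readTasteForest(bad), "unsupported bundle")
})
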