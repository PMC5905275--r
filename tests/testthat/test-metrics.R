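test_that("confusion counts follow the cell definitions", {
  lab <- rep(c("sweet", "bitter"), each = 5)
  cc <- confusionCounts(lab, lab, "sweet")
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 5L, tn = 5L, fp = 0L, fn = 0L))
  lab2 <- c(rep("sweet", 3), rep("bitter", 7))
  cc2 <- confusionCounts(lab2, rep("sweet", 10), "sweet")
  expect_equal(unlist(cc2[c("tp", "tn", "fp", "fn")]),
               c(tp = 3L, tn = 0L, fp = 7L, fn = 0L))
  # swapping the positive class swaps tp<->tn and fp<->fn
  pred <- c("sweet", "bitter", "sweet", "bitter", "sweet",
            "bitter", "sweet", "bitter", "bitter", "sweet")
  a <- confusionCounts(lab, pred, "sweet")
  b <- confusionCounts(lab, pred, "bitter")
  expect_equal(a$tp, b$tn); expect_equal(a$tn, b$tp)
  expect_equal(a$fp, b$fn); expect_equal(a$fn, b$fp)
  expect_error(confusionCounts(lab, pred[-1], "sweet"), "lengths differ")
  expect_error(confusionCounts(c("sweet", "sour"), pred[1:2], "sweet"),
               "unknown class")
})

test_that("metric panel reproduces hand-computed closed forms", {
  p <- metricsPanel(list(tp = 9, tn = 9, fp = 1, fn = 1,
                         positive_class = "sweet"))
  expect_equal(p$accuracy, 0.9)
  expect_equal(p$sensitivity, 0.9)
  expect_equal(p$specificity, 0.9)
  expect_equal(p$ner, 0.9)
  expect_equal(p$cohens_kappa, 0.8)   # p_o 0.9, p_e 0.5
  perfect <- metricsPanel(list(tp = 4, tn = 6, fp = 0, fn = 0,
                               positive_class = "sweet"))
  for (m in c("accuracy", "sensitivity", "specificity", "precision",
              "f_measure", "ner", "cohens_kappa"))
    expect_equal(perfect[[m]], 1, label = m)
  # zero denominators surface as NA, never as 0
  nopos <- metricsPanel(list(tp = 0, tn = 5, fp = 0, fn = 0,
                             positive_class = "sweet"))
  expect_true(is.na(nopos$sensitivity))
  expect_true(is.na(nopos$precision))
  expect_error(metricsPanel(list(tp = 0, tn = 0, fp = 0, fn = 0)), "empty")
})

test_that("panel matches a brute-force recount on random vectors", {
  set.seed(7)
  for (k in 1:200) {
    n <- sample(10:60, 1)
    lab <- sample(c("sweet", "bitter"), n, replace = TRUE)
    pred <- sample(c("sweet", "bitter"), n, replace = TRUE)
    pos <- sample(c("sweet", "bitter"), 1)
    cc <- confusionCounts(lab, pred, pos)
    oc <- bruteConfusion(lab, pred, pos)
    expect_identical(unname(unlist(cc[c("tp", "tn", "fp", "fn")])),
                     unname(unlist(oc)))
    p <- metricsPanel(cc)
    o <- brutePanel(oc$tp, oc$tn, oc$fp, oc$fn)
    for (m in names(o)) expect_equal(p[[m]], o[[m]], label = m)
  }
})

test_that("random agreement with matched marginals gives kappa near zero", {
  set.seed(11)
  lab <- sample(c("sweet", "bitter"), 10000, replace = TRUE)
  pred <- sample(c("sweet", "bitter"), 10000, replace = TRUE)
  k <- metricsPanel(confusionCounts(lab, pred, "sweet"))$cohens_kappa
  expect_lt(abs(k), 0.02)
})

test_that("rocAUC reproduces perfect, random and hand-enumerated cases", {
  lab <- c("sweet", "sweet", "bitter", "bitter")
  expect_equal(rocAUC(lab, c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(rocAUC(lab, c(0.5, 0.5, 0.5, 0.5)), 0.5)
  expect_equal(rocAUC(lab, c(0.9, 0.4, 0.6, 0.1)), 0.75)  # 3 of 4 pairs concordant
  expect_error(rocAUC(rep("sweet", 3), c(.1, .2, .3)), "at least one")
  expect_error(rocAUC(lab, c(1, 2, Inf, 0)), "finite")
})

test_that("rank-formula AUC equals trapezoidal ROC integration", {
  set.seed(3)
  for (k in 1:500) {
    n <- sample(8:80, 1)
    lab <- c("sweet", "bitter",
             sample(c("sweet", "bitter"), n - 2, replace = TRUE))
    scores <- if (k %% 3 == 0) sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties
              else runif(n)
    expect_equal(rocAUC(lab, scores), aucTrapezoid(lab, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  lab <- sample(c("sweet", "bitter"), 100, replace = TRUE)
  sc <- runif(100) + 0.4 * (lab == "sweet")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(lab, c("bitter", "sweet")), predictor = sc,
    quiet = TRUE, direction = "<")))
  expect_equal(rocAUC(lab, sc), ref, tolerance = 1e-12)
})

test_that("dual-perspective reports mirror each other", {
  set.seed(9)
  lab <- sample(c("sweet", "bitter"), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.75, lab,
                 sample(c("sweet", "bitter"), 60, replace = TRUE))
  sc <- runif(60, 0, 0.45) + 0.55 * (pred == "sweet")
  tab <- metricsTable(lab, pred, sc)
  sw <- tab[tab$positive_class == "sweet", ]
  bt <- tab[tab$positive_class == "bitter", ]
  expect_equal(sw$sensitivity, bt$specificity)
  expect_equal(sw$specificity, bt$sensitivity)
  expect_equal(sw$accuracy, bt$accuracy)
  expect_equal(sw$cohens_kappa, bt$cohens_kappa)
  expect_equal(sw$positives, bt$negatives)
  # kappa never exceeds accuracy when chance agreement is positive
  expect_lte(sw$cohens_kappa, sw$accuracy)
  # f-measure is the harmonic mean of precision and sensitivity
  expect_equal(sw$f_measure,
               2 * sw$precision * sw$sensitivity /
                 (sw$precision + sw$sensitivity))
})
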