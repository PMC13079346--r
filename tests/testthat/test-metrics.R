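test_that("confusion counts match hand-computed one-vs-rest tallies", {
  cc <- confusion_counts(truth = c(0, 0, 1, 2), pred = c(0, 1, 1, 2), n_classes = 3)
  expect_equal(cc$counts$tp, c(1L, 1L, 1L))
  expect_equal(cc$counts$fp, c(0L, 1L, 0L))
  expect_equal(cc$counts$fn, c(1L, 0L, 0L))
  expect_equal(sum(cc$counts$tp), sum(c(0, 0, 1, 2) == c(0, 1, 1, 2)))
  expect_equal(cc$counts$tp + cc$counts$fn, cc$counts$n_true)

  perfect <- confusion_counts(0:4, 0:4, 5)
  expect_true(all(perfect$counts$fp == 0) && all(perfect$counts$fn == 0))

  expect_error(confusion_counts(c(0, 1), c(0), 2), "equal length")
  expect_error(confusion_counts(c(0, 3), c(0, 1), 3), "lie in")
})

test_that("classification report reproduces the toy example and its identities", {
  cc <- confusion_counts(c(0, 0, 1, 2), c(0, 1, 1, 2), 3)
  rep <- classification_report(cc)
  expect_equal(rep$per_class$f1, c(2 / 3, 2 / 3, 1))
  expect_equal(rep$f1_macro, 7 / 9)
  # single-label multi-class: micro F1 equals accuracy
  expect_equal(rep$f1_micro, rep$accuracy)
  ora <- oracle_classification(c(0, 0, 1, 2), c(0, 1, 1, 2), 3)
  expect_equal(rep$f1_weighted, ora$f1_weighted)

  # balanced classes: weighted F1 equals macro F1
  set.seed(4)
  truth <- rep(0:3, each = 25)
  pred <- ifelse(runif(100) < 0.7, truth, sample(0:3, 100, TRUE))
  repb <- classification_report(confusion_counts(truth, pred, 4))
  expect_equal(repb$f1_weighted, repb$f1_macro)
})

test_that("classification metrics agree with independent implementations on random labels", {
  set.seed(99)
  for (rep_i in 1:25) {
    K <- sample(2:6, 1)
    n <- 40
    truth <- sample(0:(K - 1), n, TRUE)
    pred <- sample(0:(K - 1), n, TRUE)
    r <- classification_report(suppressWarnings(confusion_counts(truth, pred, K)))
    o <- oracle_classification(truth, pred, K)
    expect_equal(r$accuracy, o$accuracy, tolerance = 1e-9)
    expect_equal(r$f1_micro, o$f1_micro, tolerance = 1e-9)
    expect_equal(r$f1_macro, o$f1_macro, tolerance = 1e-9)
    expect_equal(r$f1_weighted, o$f1_weighted, tolerance = 1e-9)
  }
  # cross-check per-class recall/precision against caret's reference implementation
  set.seed(7)
  truth <- sample(0:2, 300, TRUE)
  pred <- ifelse(runif(300) < 0.6, truth, sample(0:2, 300, TRUE))
  r <- classification_report(confusion_counts(truth, pred, 3))
  cm <- caret::confusionMatrix(factor(pred, 0:2), factor(truth, 0:2))
  expect_equal(unname(r$per_class$recall),
               unname(cm$byClass[, "Sensitivity"]), tolerance = 1e-9)
  expect_equal(unname(r$per_class$precision),
               unname(cm$byClass[, "Pos Pred Value"]), tolerance = 1e-9)
  expect_equal(r$accuracy, unname(cm$overall["Accuracy"]), tolerance = 1e-9)
})

test_that("dice_iou matches hand values and algebraic identities", {
  p <- c(rep(1, 4), rep(0, 6)); g <- c(rep(1, 2), rep(0, 2), rep(1, 4), 0, 0)
  # |P| = 4, |G| = 6, |P intersect G| = 2
  expect_equal(sum(p), 4); expect_equal(sum(g), 6); expect_equal(sum(p & g), 2)
  s <- dice_iou(p, g)
  expect_equal(unname(s["dice"]), 0.4)
  expect_equal(unname(s["iou"]), 0.25)
  expect_equal(oracle_dice_iou(p, g), s)

  m <- matrix(rbinom(64, 1, .4), 8)
  expect_equal(dice_iou(m, m), c(dice = 1, iou = 1))
  expect_equal(dice_iou(m * 0, m * 0), c(dice = 1, iou = 1))

  set.seed(11)
  for (i in 1:20) {
    a <- matrix(rbinom(100, 1, .3), 10); b <- matrix(rbinom(100, 1, .5), 10)
    s <- dice_iou(a, b)
    expect_equal(unname(s["iou"]), unname(s["dice"] / (2 - s["dice"])), tolerance = 1e-9)
    expect_true(s["iou"] <= s["dice"] + 1e-12 && s["dice"] <= 1 && s["iou"] >= 0)
  }
  expect_error(dice_iou(matrix(0, 2, 2), matrix(0, 3, 3)), "share shape")
})

test_that("multiclass dice/iou handles absent classes and mean conventions", {
  truth <- matrix(c(0, 1, 1, 2), 2)
  m <- multiclass_dice_iou(truth, truth, n_classes = 4)
  expect_true(all(m$per_class$dice == 1))
  expect_true(m$per_class$absent[4])   # class 3 in neither mask
  expect_equal(m$mean_dice, mean(m$per_class$dice[-1]))
  mb <- multiclass_dice_iou(truth, truth, 4, include_background = TRUE)
  expect_equal(mb$mean_iou, mean(mb$per_class$iou))
})

test_that("stability reports the mean and population standard deviation", {
  s <- stability(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$std, sqrt(8 / 3))          # population divisor n, not n - 1
  expect_equal(stability(rep(5, 4))$std, 0)
  expect_error(stability(3), ">= 2")
})
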