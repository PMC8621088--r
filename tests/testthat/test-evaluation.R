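# Confusion counts, the four metrics, and one-vs-rest ROC/AUC.

test_that("confusion counts match a hand count", {
  cc <- confusion_counts(c(1, 1, 2), c(1, 2, 2))
  c1 <- cc[cc$class == 1, ]
  expect_equal(c(c1$tp, c1$fn, c1$fp, c1$tn), c(1, 1, 0, 1))
  c2 <- cc[cc$class == 2, ]
  expect_equal(c(c2$tp, c2$fn, c2$fp, c2$tn), c(1, 0, 1, 1))
  # counts sum to n for every class
  expect_true(all(cc$tp + cc$fp + cc$fn + cc$tn == 3))
})

test_that("perfect and empty predictions give degenerate counts", {
  cc <- confusion_counts(c(1, 2, 3), c(1, 2, 3))
  expect_true(all(cc$fp == 0) && all(cc$fn == 0))
  cc0 <- confusion_counts(integer(), integer(), classes = 1:2)
  expect_true(all(cc0$tp == 0 & cc0$tn == 0))
  expect_error(confusion_counts(1:3, 1:2),
               class = "ddihybrid_dimension_error")
})

test_that("metrics evaluate the printed formulas", {
  counts <- tibble::tibble(class = 1, tp = 9, fp = 1, fn = 3, tn = 0,
                           support = 12)
  m <- metrics_from_counts(counts)
  pc <- m$per_class
  expect_equal(pc$precision, 0.9)
  expect_equal(pc$recall, 0.75)
  expect_equal(pc$f1, 2 * 0.9 * 0.75 / (0.9 + 0.75))  # 0.81818...
  expect_equal(pc$f1, 0.8181818, tolerance = 1e-6)
})

test_that("zero-division convention yields flagged zeros", {
  counts <- tibble::tibble(class = 1, tp = 0, fp = 0, fn = 5, tn = 10,
                           support = 5)
  m <- metrics_from_counts(counts)
  expect_equal(m$per_class$precision, 0)
  expect_true(m$per_class$zero_division)
})

test_that("F1 equals P when P equals R, and sits between them otherwise", {
  counts <- tibble::tibble(class = 1, tp = 6, fp = 2, fn = 2, tn = 10,
                           support = 8)
  m <- metrics_from_counts(counts)
  expect_equal(m$per_class$f1, m$per_class$precision)
  set.seed(31)
  for (rep in 1:30) {
    y_true <- sample(1:4, 60, TRUE)
    y_pred <- sample(1:4, 60, TRUE)
    mm <- metrics_from_counts(confusion_counts(y_true, y_pred))
    with_pr <- mm$per_class[mm$per_class$precision +
                              mm$per_class$recall > 0, ]
    expect_true(all(with_pr$f1 >= pmin(with_pr$precision,
                                       with_pr$recall) - 1e-12))
    expect_true(all(with_pr$f1 <= pmax(with_pr$precision,
                                       with_pr$recall) + 1e-12))
    # micro-averaged P = R = accuracy in single-label multiclass
    expect_equal(mm$summary$micro_precision, mm$summary$accuracy)
    expect_equal(mm$summary$micro_recall, mean(y_true == y_pred))
  }
})

test_that("metrics match a brute-force pairwise recount", {
  set.seed(32)
  for (rep in 1:20) {
    y_true <- sample(1:3, 25, TRUE)
    y_pred <- sample(1:3, 25, TRUE)
    cc <- confusion_counts(y_true, y_pred, 1:3)
    for (cl in 1:3) {
      ref <- oracle_confusion(y_true, y_pred, cl)
      row <- cc[cc$class == cl, ]
      expect_equal(c(row$tp, row$fp, row$fn, row$tn), unname(ref))
    }
  }
})

test_that("AUC hits the exact endpoints for perfect and reversed rankings", {
  y <- rep(c(1, 2), each = 10)
  sc <- cbind(`1` = c(seq(1, 0.6, length.out = 10),
                      seq(0.4, 0, length.out = 10)))
  sc <- cbind(sc, `2` = 1 - sc[, 1])
  auc <- roc_auc_ovr(y, sc, classes = c(1, 2))
  expect_equal(auc$auc, c(1, 1))
  rev_auc <- roc_auc_ovr(y, sc[, c(2, 1)], classes = c(1, 2))
  expect_equal(rev_auc$auc, c(0, 0))
})

test_that("random scores give AUC near one half", {
  set.seed(33)
  n <- 10000
  y <- sample(1:2, n, TRUE)
  sc <- matrix(runif(2 * n), n, 2)
  auc <- roc_auc_ovr(y, sc, classes = 1:2)
  expect_true(all(abs(auc$auc - 0.5) < 0.02))
})

test_that("tied scores are handled by midranks and match pROC", {
  set.seed(34)
  y <- sample(1:2, 200, TRUE)
  sc2 <- round(runif(200), 1)  # heavy ties
  scores <- cbind(`1` = 1 - sc2, `2` = sc2)
  auc <- roc_auc_ovr(y, scores, classes = 1:2)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = y == 2, predictor = sc2, quiet = TRUE, direction = "<"
  )))
  expect_equal(auc$auc[2], ref, tolerance = 1e-12)
})

test_that("classes absent from the truth get NA AUC", {
  y <- rep(1, 5)
  sc <- cbind(`1` = runif(5), `2` = runif(5))
  auc <- roc_auc_ovr(y, sc, classes = 1:2)
  expect_true(is.na(auc$auc[2]))
})

test_that("evaluate_predictions assembles metrics and AUC together", {
  set.seed(35)
  y <- sample(1:3, 90, TRUE)
  sc <- matrix(runif(270), 90, 3, dimnames = list(NULL, 1:3))
  sc <- sc / rowSums(sc)
  pred <- as.integer(colnames(sc)[max.col(sc)])
  ev <- evaluate_predictions(y, pred, scores = sc, classes = 1:3)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_true("auc" %in% names(tidy(ev)))
  expect_true(all(glance(ev)[, c("accuracy", "macro_f1")] >= 0))
  expect_true(all(tidy(ev)$f1 >= 0 & tidy(ev)$f1 <= 1))
})
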