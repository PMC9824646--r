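test_that("confusion counts tally true/predicted pairs", {
  # perfect prediction: diagonal with full trace
  cm <- confusion(rep(0:2, each = 4), rep(0:2, each = 4), 3)
  expect_identical(unname(diag(unclass(cm))), rep(4L, 3))
  expect_identical(sum(cm), 12L)
  # everything predicted as class 0: a single nonzero column
  cm0 <- confusion(rep(0:2, each = 4), rep(0L, 12), 3)
  expect_identical(unname(unclass(cm0)[, 1]), rep(4L, 3))
  expect_identical(sum(unclass(cm0)[, -1]), 0L)
  # hand-enumerated 3-class toy
  tr <- c(0L, 1L, 2L, 0L, 1L, 2L); pr <- c(0L, 1L, 1L, 2L, 1L, 0L)
  cm3 <- confusion(tr, pr, 3)
  expect_equal(unclass(cm3),
               matrix(c(1L, 0L, 1L, 0L, 2L, 1L, 1L, 0L, 0L), 3, 3),
               ignore_attr = TRUE)
  expect_error(confusion(0:2, 0:1, 3), class = "csbnet_bad_input")
  expect_error(confusion(0:3, 0:3, 3), class = "csbnet_bad_input")
})

test_that("hand-checked 2-class arithmetic and the perfect-prediction identity", {
  m <- matrix(c(8L, 3L, 2L, 7L), 2, 2)  # [[8,2],[3,7]] in row order
  s <- score(m)
  expect_equal(s$accuracy, 0.75)
  expect_equal(s$per_class$precision[1], 8 / 11)
  expect_equal(s$per_class$recall[1], 0.8)
  expect_equal(s$per_class$f1[1], 2 * (8 / 11) * 0.8 / (8 / 11 + 0.8))
  perfect <- score(diag(c(5L, 3L, 2L)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$per_class$precision, rep(1, 3))
  expect_equal(perfect$per_class$recall, rep(1, 3))
  expect_equal(perfect$per_class$f1, rep(1, 3))
})

test_that("zero-denominator metrics report 0 with a warning", {
  w <- testthat::capture_warnings(s <- score(matrix(c(2L, 2L, 0L, 0L), 2, 2)))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(s$per_class$precision[2], 0)
})

test_that("metrics agree with an independent reference on 100 random confusion matrices", {
  set.seed(2024)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    n <- sample(20:60, 1)
    tr <- sample(0:(K - 1), n, replace = TRUE)
    pr <- sample(0:(K - 1), n, replace = TRUE)
    s <- suppressWarnings(score(confusion(tr, pr, K)))
    ref <- caret::confusionMatrix(factor(pr, levels = 0:(K - 1)),
                                  factor(tr, levels = 0:(K - 1)))
    expect_equal(s$accuracy, unname(ref$overall["Accuracy"]), tolerance = 1e-12)
    if (K == 2) {
      # binary caret reports the positive class (level "0") only;
      # specificity is the recall of the other class
      ref_rec <- unname(c(ref$byClass["Sensitivity"], ref$byClass["Specificity"]))
    } else {
      ref_rec <- unname(ref$byClass[, "Sensitivity"])
      ref_prec <- unname(ref$byClass[, "Pos Pred Value"])
      expect_equal(s$per_class$precision, ifelse(is.na(ref_prec), 0, ref_prec),
                   tolerance = 1e-12)
    }
    expect_equal(s$per_class$recall, ifelse(is.na(ref_rec), 0, ref_rec),
                 tolerance = 1e-12)
  }
})

test_that("permuting class order permutes per-class metrics, macro values invariant", {
  set.seed(5)
  tr <- sample(0:3, 80, replace = TRUE)
  pr <- sample(0:3, 80, replace = TRUE)
  s1 <- suppressWarnings(score(confusion(tr, pr, 4)))
  perm <- c(2L, 0L, 3L, 1L)
  s2 <- suppressWarnings(score(confusion(perm[tr + 1L], perm[pr + 1L], 4)))
  ord <- order(perm)
  expect_equal(s2$per_class$precision[perm + 1L], s1$per_class$precision)
  expect_equal(s2$per_class$recall[perm + 1L], s1$per_class$recall)
  expect_equal(s1$accuracy, s2$accuracy)
  expect_equal(s1$macro_f1, s2$macro_f1)
  expect_equal(s1$macro_precision, s2$macro_precision)
})

test_that("tidy/glance expose per-class rows plus macro summary; writers round-trip", {
  s <- suppressWarnings(score(matrix(c(8L, 3L, 2L, 7L), 2, 2)))
  td <- tidy(s)
  expect_identical(nrow(td), 3L)
  expect_identical(td$class[3], "macro")
  gl <- glance(s)
  expect_identical(names(gl),
                   c("accuracy", "macro_precision", "macro_recall", "macro_f1", "n"))
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_metrics(s, csv); write_metrics(s, jsn)
  expect_equal(nrow(utils::read.csv(csv)), 3L)
  expect_equal(jsonlite::read_json(jsn)$accuracy, s$accuracy)
})
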