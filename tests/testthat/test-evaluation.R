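# Misclassification counts of the published 200-seed validation: row = true
# class, column = predicted class; diagonal reconstructed from the published
# per-class accuracies (59/100/77/77/89%) and row sums.
published_counts <- function() {
  m <- matrix(c(10, 0, 1, 4, 2,
                0, 5, 0, 0, 0,
                1, 2, 10, 0, 0,
                2, 1, 1, 57, 13,
                0, 0, 2, 8, 81),
              5, 5, byrow = TRUE, dimnames = list(true = 1:5, predicted = 1:5))
  storage.mode(m) <- "integer"
  m
}

test_that("confusion_counts cross-tabulates exactly", {
  res <- data.frame(true_class = c(1, 1, 2), predicted_class = c(1, 4, 2))
  cc <- confusion_counts(res)
  expect_identical(sum(cc), 3L)
  expect_identical(cc["1", "4"], 1L)
  expect_identical(cc["2", "2"], 1L)
  expect_error(confusion_counts(data.frame(true_class = NA,
                                           predicted_class = 1)),
               "true class")
})

test_that("accuracy and FN/FP percentages follow their definitions", {
  cc <- published_counts()
  expect_identical(sum(cc) - sum(diag(cc)), 37L)
  expect_equal(classification_accuracy(cc, 200), 81.5)
  expect_identical(round(classification_accuracy(cc, 200)), 82)

  expect_equal(false_negative_pct(cc, 4, 200), 8.5)
  expect_equal(false_negative_pct(cc, 5, 200), 5)
  expect_equal(false_negative_pct(cc, 3, 200), 1.5)
  expect_equal(false_negative_pct(cc, 2, 200), 0)
  expect_equal(false_positive_pct(cc, 1, 200), 1.5)
  expect_equal(false_positive_pct(cc, 2, 200), 1.5)
  expect_equal(false_positive_pct(cc, 3, 200), 2)

  # a diagonal table has no false calls
  d <- diag(5) * 10
  dimnames(d) <- dimnames(cc)
  expect_equal(classification_accuracy(d), 100)
  for (k in 1:5) {
    expect_equal(false_negative_pct(d, k), 0)
    expect_equal(false_positive_pct(d, k), 0)
  }
  # none correct
  o <- matrix(1, 5, 5, dimnames = dimnames(cc))
  diag(o) <- 0
  expect_equal(classification_accuracy(o), 0)
  expect_error(classification_accuracy(cc, 0), "positive")
})

test_that("per-class accuracy is the diagonal over the row total", {
  cc <- published_counts()
  acc <- per_class_accuracy(cc)
  expect_equal(round(unname(acc)), c(59, 100, 77, 77, 89))
})

test_that("per-variety accuracy restricts the overall formula", {
  res <- data.frame(variety_id = c("v", "v", "v"),
                    true_class = c(1, 2, 3), predicted_class = c(1, 2, 3))
  expect_equal(unname(per_variety_accuracy(res)), 100)
  res2 <- data.frame(variety_id = rep(c("v1", "v2"), c(4, 2)),
                     true_class = c(1, 1, 1, 1, 2, 2),
                     predicted_class = c(1, 1, 1, 2, 2, 3))
  pv <- per_variety_accuracy(res2)
  expect_equal(unname(pv), c(75, 50))
})

test_that("count conservation holds on randomized confusion tables", {
  set.seed(9)
  for (trial in 1:100) {
    cc <- random_counts()
    n <- sum(cc)
    fn <- rowSums(cc) - diag(cc)
    fp <- colSums(cc) - diag(cc)
    expect_identical(sum(fn), sum(fp))
    expect_identical(sum(fn), n - sum(diag(cc)))
    # accuracy% + sum of FN% is exactly 100 in rational arithmetic
    expect_identical(100 * (sum(diag(cc)) + sum(fn)) / n, 100)
  }
})

test_that("evaluation_report assembles counts, rates and variety accuracy", {
  set.seed(10)
  res <- data.frame(true_class = sample(1:5, 60, replace = TRUE),
                    variety_id = rep(1:3, 20))
  res$predicted_class <- ifelse(runif(60) < 0.7, res$true_class,
                                sample(1:5, 60, replace = TRUE))
  rep_ <- evaluation_report(res)
  expect_identical(sum(rep_$counts), 60L)
  expect_equal(rep_$overall_accuracy,
               100 * mean(res$true_class == res$predicted_class))
  expect_identical(rep_$per_class$fn_count,
                   as.integer(rowSums(rep_$counts) - diag(rep_$counts)))
  # min and max variety accuracies bracket the overall accuracy
  expect_gte(rep_$overall_accuracy, min(rep_$per_variety_accuracy))
  expect_lte(rep_$overall_accuracy, max(rep_$per_variety_accuracy))
  # the rendered report shows the Table-style layout
  out <- capture.output(print(rep_))
  expect_true(any(grepl("accuracy%", out)))
  expect_true(any(grepl("FN%", out)))
})
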