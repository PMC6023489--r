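test_that("the threshold sits at the midpoint under equal priors", {
  values <- c(rnorm(10, 0, 1e-6), rnorm(10, 10, 1e-6))
  labels <- rep(c("normal", "pah"), each = 10)
  model <- fit_lda(values, labels, priors = "equal")
  expect_equal(model$threshold, 5, tolerance = 1e-3)
  expect_false(model$positive_low)       # pah mean is the higher one here
})

test_that("unequal priors shift the threshold by the closed form", {
  set.seed(501)
  mu <- c(0, 10); s2_target <- 1
  values <- c(rnorm(30, mu[1], 1), rnorm(10, mu[2], 1))
  labels <- rep(c("normal", "pah"), c(30, 10))
  model <- fit_lda(values, labels, priors = c(normal = 0.75, pah = 0.25))
  m <- model$class_means
  expected <- (m[["pah"]] + m[["normal"]]) / 2 -
    model$pooled_variance * log(0.25 / 0.75) / (m[["pah"]] - m[["normal"]])
  expect_equal(model$threshold, expected)
  expect_gt(model$threshold, (m[["pah"]] + m[["normal"]]) / 2)  # toward rarer
})

test_that("decisions equal brute-force posterior comparison on a grid", {
  set.seed(502)
  for (priors in list("empirical", "equal")) {
    values <- c(rnorm(12, 2, 1.5), rnorm(18, 6, 1.5))
    labels <- rep(c("normal", "pah"), c(12, 18))
    model <- fit_lda(values, labels, priors = priors)
    grid <- seq(-4, 12, length.out = 400)
    pred <- predict(model, grid)
    # oracle: argmax of the two equal-variance Gaussian class posteriors
    pr <- model$priors
    post_n <- pr[["normal"]] *
      dnorm(grid, model$class_means[["normal"]], sqrt(model$pooled_variance))
    post_p <- pr[["pah"]] *
      dnorm(grid, model$class_means[["pah"]], sqrt(model$pooled_variance))
    oracle <- ifelse(post_p > post_n, "pah", "normal")
    expect_equal(as.character(pred), oracle)
  }
})

test_that("degenerate classification inputs are rejected", {
  expect_error(fit_lda(rnorm(5), rep("a", 5)), "two classes")
  expect_error(fit_lda(c(1, 2), c("a", "b")), "at least 3")
  expect_error(fit_lda(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               "variance is zero")
  expect_error(loo_evaluate(rnorm(2), c("a", "b")), "at least 3")
})

test_that("perfect separation yields a perfect leave-one-out score", {
  set.seed(503)
  values <- c(rnorm(10, 0, 0.1), rnorm(8, 50, 0.1))
  labels <- rep(c("normal", "pah"), c(10, 8))
  res <- loo_evaluate(values, labels)
  expect_equal(res$sensitivity, 100)
  expect_equal(res$specificity, 100)
  expect_equal(res$TP + res$FN, 8)
  expect_equal(res$TN + res$FP, 10)
  expect_equal(nrow(res$predictions), 18)
})

test_that("leave-one-out is invariant to affine feature rescaling", {
  set.seed(504)
  values <- c(rnorm(12, 0, 2), rnorm(9, 3, 2))
  labels <- rep(c("normal", "pah"), c(12, 9))
  a <- loo_evaluate(values, labels)
  b <- loo_evaluate(-5 + 0.01 * values, labels)
  expect_equal(a$predictions$predicted, b$predictions$predicted)
  expect_equal(a$sensitivity, b$sensitivity)
})

test_that("label swap exchanges sensitivity and specificity under equal priors", {
  set.seed(505)
  values <- c(rnorm(12, 0, 2), rnorm(9, 2.5, 2))
  labels <- rep(c("normal", "pah"), c(12, 9))
  fwd <- loo_evaluate(values, labels, priors = "equal", positive = "pah")
  swapped <- ifelse(labels == "pah", "normal", "pah")
  rev <- loo_evaluate(values, swapped, priors = "equal", positive = "normal")
  expect_equal(fwd$sensitivity, rev$sensitivity)
  expect_equal(fwd$specificity, rev$specificity)
})

test_that("overlapping classes score near the majority-class rate", {
  set.seed(506)
  accs <- replicate(40, {
    values <- rnorm(30)
    labels <- rep(c("normal", "pah"), c(18, 12))
    res <- loo_evaluate(values, labels)
    (res$TP + res$TN) / 30
  })
  expect_equal(mean(accs), 18 / 30, tolerance = 0.15)
})

test_that("accuracy does not degrade as separation grows", {
  set.seed(507)
  acc_at <- function(delta) {
    mean(replicate(25, {
      values <- c(rnorm(12, 0), rnorm(10, delta))
      labels <- rep(c("normal", "pah"), c(12, 10))
      res <- loo_evaluate(values, labels)
      (res$TP + res$TN) / 22
    }))
  }
  accs <- vapply(c(0.5, 2, 5), acc_at, numeric(1))
  expect_true(all(diff(accs) > -0.02))
})

test_that("confusion metrics reproduce the printed formulas", {
  cm <- confusion_metrics(TP = 21, FN = 4, TN = 31, FP = 4)
  expect_equal(cm$sensitivity, 84)
  expect_equal(round(cm$specificity, 2), 88.57)
  perfect <- confusion_metrics(10, 0, 12, 0)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_error(confusion_metrics(0, 0, 5, 1), "sensitivity undefined")
  expect_error(confusion_metrics(5, 1, 0, 0), "specificity undefined")
  expect_error(confusion_metrics(-1, 2, 3, 4), "non-negative")
})
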