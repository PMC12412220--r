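test_that("the hand-worked 2x2 confusion matrix gives the published metric values", {
  cm <- matrix(c(8, 1, 2, 9), 2)  # rows true: (8,2; 1,9)
  r <- metricsFromConfusion(cm)
  expect_equal(accuracy(r), 0.85)
  expect_equal(unname(macroMetrics(r)["recall"]), 0.85)
  expect_equal(unname(macroMetrics(r)["specificity"]), 0.85)
})

test_that("a class with clean row and column scores 1.0000 on all its metrics", {
  cm <- matrix(c(50, 0, 0,
                 0, 48, 2,
                 0, 3, 47), 3, byrow = TRUE)
  r <- metricsFromConfusion(cm)
  pc <- perClassMetrics(r)
  expect_equal(unlist(pc[1, c("recall", "precision", "f1", "specificity")]),
               c(recall = 1, precision = 1, f1 = 1, specificity = 1))
})

test_that("perfect classification scores 1 everywhere", {
  r <- metricsFromConfusion(diag(7, 4))
  expect_equal(accuracy(r), 1)
  expect_equal(unname(macroMetrics(r)), rep(1, 4))
})

test_that("metrics agree with a first-principles per-class oracle on random matrices", {
  set.seed(202)
  for (trial in 1:200) {
    K <- sample(2:10, 1)
    cm <- matrix(rpois(K * K, lambda = sample(1:20, 1)), K)
    if (sum(cm) == 0) cm[1, 1] <- 1
    r <- suppressWarnings(metricsFromConfusion(cm))
    total <- sum(cm)
    spec <- rec <- prec <- f1 <- numeric(K)
    for (c in 1:K) {
      tp <- cm[c, c]
      fn <- sum(cm[c, ]) - tp
      fp <- sum(cm[, c]) - tp
      tn <- total - tp - fn - fp
      rec[c] <- if (tp + fn == 0) 0 else tp / (tp + fn)
      prec[c] <- if (tp + fp == 0) 0 else tp / (tp + fp)
      spec[c] <- if (tn + fp == 0) 0 else tn / (tn + fp)
      f1[c] <- if (prec[c] + rec[c] == 0) 0 else
        2 * prec[c] * rec[c] / (prec[c] + rec[c])
    }
    expect_equal(accuracy(r), sum(diag(cm)) / total, tolerance = 1e-12)
    expect_equal(unname(macroMetrics(r)),
                 c(mean(spec), mean(rec), mean(prec), mean(f1)),
                 tolerance = 1e-12)
  }
})

test_that("0/0 metric ratios are defined as 0 with a warning", {
  # class 2 is never predicted: precision (and F1) denominators are 0
  w <- capture_warnings(metricsFromConfusion(matrix(c(10, 0, 5, 0), 2,
                                                    byrow = TRUE)))
  expect_true(any(grepl("0/0", w)))
  expect_error(metricsFromConfusion(matrix(0, 2, 2)), "empty|invalid")
  expect_error(metricsFromConfusion(matrix(1, 3, 2)), "square")
})

test_that("the t confidence interval matches its closed form", {
  expect_equal(meanCI(rep(3, 5)), c(mean = 3, lower = 3, upper = 3))
  ci <- meanCI(c(0, 2), 0.95)
  # half-width t_{0.975,1} * sd/sqrt(2) = 12.70620 * sqrt(2)/sqrt(2)
  expect_equal(unname(ci["mean"]), 1)
  expect_equal(unname(ci["lower"]), 1 - qt(0.975, 1), tolerance = 1e-6)
  expect_equal(unname(ci["upper"]), 1 + qt(0.975, 1), tolerance = 1e-6)
  expect_equal(unname(round(ci["lower"], 3)), -11.706)
  expect_equal(unname(round(ci["upper"], 3)), 13.706)
  expect_error(meanCI(1), "at least 2")
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  r <- anovaOneway(list(c(2, 3, 4), c(4, 5, 6), c(6, 7, 8)))
  expect_equal(unname(r["F"]), 12)
  expect_equal(unname(r["df1"]), 2)
  expect_equal(unname(r["df2"]), 6)
  expect_equal(unname(r["p"]), pf(12, 2, 6, lower.tail = FALSE))
  expect_equal(unname(round(r["p"], 3)), 0.008)
  # identical groups: no between-group variance
  r0 <- anovaOneway(list(c(2, 3, 4), c(2, 3, 4)))
  expect_equal(unname(r0["F"]), 0)
  expect_equal(unname(r0["p"]), 1)
  expect_error(anovaOneway(list(c(1, 2, 3))), "at least 2")
  expect_error(anovaOneway(list(c(1, 1), c(2, 2))), "degenerate")
})

test_that("CI coverage and ANOVA size are calibrated under the null", {
  # 95% t interval covers the true mean in 93-97% of n=10 normal samples
  set.seed(77)
  cover <- vapply(1:500, function(i) {
    ci <- meanCI(rnorm(10, mean = 2, sd = 3))
    ci["lower"] <= 2 && 2 <= ci["upper"]
  }, logical(1))
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
  # ANOVA type-I error at alpha = 0.05 within [0.03, 0.07]
  set.seed(78)
  rej <- vapply(1:2000, function(i) {
    g <- list(rnorm(5), rnorm(5), rnorm(5))
    anovaOneway(g)["p"] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
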