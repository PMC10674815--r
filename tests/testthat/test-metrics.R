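# Metrics and calibration: confusion ratios, Brier score, rank-based AUROC
# with its trapezoidal oracle, most-confident statistic.

test_that("confusion counts enumerate the four cells with 'good' positive", {
  c1 <- confusion_counts(c("good", "good", "bad", "bad"),
                         c("good", "bad", "bad", "good"))
  expect_equal(c(c1$tp, c1$fn, c1$tn, c1$fp), c(1L, 1L, 1L, 1L))
  c2 <- confusion_counts(c("good", "bad", "good", "bad"),
                         c("good", "bad", "good", "bad"))
  expect_equal(c(c2$fp, c2$fn), c(0L, 0L))
  # swapping the positive-class convention swaps tp<->tn and fp<->fn
  c3 <- confusion_counts(c("good", "good", "bad", "bad"),
                         c("good", "bad", "bad", "good"), positive = "bad")
  expect_equal(c(c3$tp, c3$fp, c3$tn, c3$fn), c(c1$tn, c1$fn, c1$tp, c1$fp))
  expect_error(confusion_counts("good", c("good", "bad")), "equal length")
})

test_that("accuracy, sensitivity and specificity are the exact ratios", {
  cc <- structure(list(tp = 87L, fn = 13L, tn = 70L, fp = 30L),
                  class = "qc_confusion")
  expect_equal(sensitivity(cc), 0.87)
  expect_equal(specificity(cc), 0.70)
  expect_equal(accuracy(cc), 0.785)
  perfect <- structure(list(tp = 50L, fn = 0L, tn = 50L, fp = 0L),
                       class = "qc_confusion")
  expect_equal(c(accuracy(perfect), sensitivity(perfect), specificity(perfect)),
               c(1, 1, 1))
  empty_neg <- structure(list(tp = 3L, fn = 1L, tn = 0L, fp = 0L),
                         class = "qc_confusion")
  expect_warning(s <- specificity(empty_neg), "undefined")
  expect_true(is.na(s))
})

test_that("ratio identities hold against direct enumeration", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    a <- sample(c("good", "bad"), n, TRUE)
    p <- sample(c("good", "bad"), n, TRUE)
    cc <- confusion_counts(a, p)
    expect_equal(suppressWarnings(accuracy(cc)), mean(a == p))
    if (any(a == "good"))
      expect_equal(suppressWarnings(sensitivity(cc)),
                   mean(p[a == "good"] == "good"))
    if (any(a == "bad"))
      expect_equal(suppressWarnings(specificity(cc)),
                   mean(p[a == "bad"] == "bad"))
  }
})

test_that("Brier score matches hand-evaluated cases", {
  labs <- c("good", "bad", "good", "bad")
  expect_equal(brier_score(c(1, 0, 1, 0), labs), 0)
  expect_equal(brier_score(rep(0.5, 4), labs), 0.25)
  expect_equal(brier_score(c(0.8, 0.3), c("good", "bad")), 0.065)
  # constant-0.5 predictor scores 0.25 for any label mix
  set.seed(2)
  labs2 <- sample(c("good", "bad"), 33, TRUE)
  expect_equal(brier_score(rep(0.5, 33), labs2), 0.25)
})

test_that("AUROC matches its analytic anchor cases", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c("good", "good", "bad", "bad")), 1)
  expect_equal(auroc(rep(0.7, 10), rep(c("good", "bad"), 5)), 0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.1), c("good", "good", "bad", "bad")),
               0.75)
  expect_warning(a <- auroc(1:3, rep("good", 3)), "single class")
  expect_true(is.na(a))
})

test_that("rank-based AUROC equals trapezoidal ROC integration", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    a <- c("good", "bad", sample(c("good", "bad"), n - 2, TRUE))
    s <- round(stats::runif(n), sample(c(1, 2, 7), 1))  # induce ties often
    expect_equal(auroc(s, a), dosevision:::.auroc_trapezoid(s, a),
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  set.seed(8)
  for (i in 1:5) {
    a <- c("good", "bad", sample(c("good", "bad"), 30, TRUE))
    s <- stats::runif(32)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = a, predictor = s, levels = c("bad", "good"),
      direction = "<", quiet = TRUE)))
    expect_equal(auroc(s, a), ref, tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(9)
  a <- c("good", "bad", sample(c("good", "bad"), 20, TRUE))
  s <- stats::runif(22)
  base <- auroc(s, a)
  expect_equal(auroc(exp(3 * s), a), base)
  expect_equal(auroc(rank(s, ties.method = "average"), a), base)
})

test_that("most-confident values are the row maxima, bounded below by 0.5", {
  p <- rbind(c(0.5, 0.5), c(0.2, 0.8), c(0.99, 0.01))
  expect_equal(most_confident(p), c(0.5, 0.8, 0.99))
  pg <- seq(0, 1, by = 0.001)
  mc <- most_confident(cbind(1 - pg, pg))
  expect_equal(min(mc), 0.5)
  expect_true(all(mc <= 1))
})

test_that("prob_predictions validates its invariants", {
  expect_error(prob_predictions(cbind(0.6, 0.6), "good"), "sum to 1")
  expect_error(prob_predictions(cbind(-0.1, 1.1), "good"), "0, 1")
  pp <- prob_predictions(c(0.3, 0.9), c("bad", "good"))
  expect_equal(colnames(pp$probs), c("bad", "good"))
})

test_that("accuracy lies between sensitivity and specificity for balanced classes", {
  set.seed(11)
  for (i in 1:20) {
    n <- 2 * sample(3:20, 1)
    a <- rep(c("good", "bad"), n / 2)
    p <- sample(c("good", "bad"), n, TRUE)
    cc <- confusion_counts(a, p)
    acc <- accuracy(cc)
    se <- suppressWarnings(sensitivity(cc))
    sp <- suppressWarnings(specificity(cc))
    expect_gte(acc, min(se, sp) - 1e-12)
    expect_lte(acc, max(se, sp) + 1e-12)
  }
})

test_that("evaluate_model produces an internally consistent report", {
  toy <- toy_separable(n = 30, d = 5)
  m <- qc_train(toy$x, toy$y, technique = "DT", tuned = FALSE, seed = 1)
  rep <- evaluate_model(m, toy$x, toy$y)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$brier, 0)  # degenerate leaf probabilities on training data
  expect_equal(rep$accuracy,
               (rep$counts$tp + rep$counts$tn) / rep$n)
  pg <- predict(m, toy$x, type = "prob")[, "good"]
  expect_equal(rep$auroc, auroc(pg, toy$y))
  expect_true(all(rep$confidence_profile >= 0.5 - 1e-12))
})

test_that("confidence reports bin the most-confident profile conservatively", {
  pp <- prob_predictions(c(1, 1, 0, 0.5), c("good", "good", "bad", "bad"))
  cr <- confidence_report(pp)
  expect_equal(sum(cr$histogram), 4)
  expect_equal(unname(cr$histogram[10]), 3L)  # the three degenerate rows
  expect_equal(unname(cr$histogram[1]), 1L)   # the maximally uncertain row
  pp2 <- prob_predictions(rep(0.5, 7), sample(c("good", "bad"), 7, TRUE))
  cr2 <- confidence_report(pp2)
  expect_equal(unname(cr2$histogram[1]), 7L)
  expect_equal(cr2$brier, 0.25)
})
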