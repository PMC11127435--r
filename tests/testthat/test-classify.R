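# Splitting, SVM, MLP baseline and the metric suite.

test_that("random splits respect fractions, seeds and stratification", {
  labels <- rep(c("a", "b"), 50)
  sp <- splitData(labels, 0.7, seed = 1, stratified = FALSE)
  expect_length(sp$train, 70L)
  expect_length(sp$test, 30L)
  expect_setequal(c(sp$train, sp$test), 1:100)
  # stratified split of a balanced set keeps class shares
  sp2 <- splitData(labels, 0.7, seed = 1)
  expect_equal(sum(labels[sp2$train] == "a"), 35L)
  # two samples of one class at fraction 0.5: one each side
  sp3 <- splitData(c("a", "a"), 0.5, seed = 2)
  expect_length(sp3$train, 1L)
  expect_length(sp3$test, 1L)
  # determinism
  expect_identical(splitData(labels, 0.7, seed = 9),
                   splitData(labels, 0.7, seed = 9))
  expect_false(identical(splitData(labels, 0.7, seed = 9),
                         splitData(labels, 0.7, seed = 10)))
  expect_error(splitData(c("a", "b", "b"), 0.7, stratified = TRUE), "a")
  expect_error(splitData(labels, 1.2), "trainFraction")
})

test_that("the SVM separates separable clusters and behaves on XOR", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  y <- rep(c("lo", "hi"), each = 20)
  model <- trainSVM(x, y, kernel = "linear")
  expect_equal(mean(predict(model, x) == y), 1)
  expect_true(all(supportVectorCounts(model) >= 1))

  # XOR: no linear separator beats 3/4 on the 4 points
  xXor <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  yXor <- c("a", "a", "b", "b")
  lin <- trainSVM(xXor, yXor, kernel = "linear")
  expect_lte(mean(predict(lin, xXor) == yXor), 0.75)
  rbf <- trainSVM(xXor, yXor, kernel = "radial", gamma = 4, cost = 100)
  expect_equal(mean(predict(rbf, xXor) == yXor), 1)

  expect_error(trainSVM(x, rep("one", 40)), "single class")
})

test_that("the MLP baseline learns a separable problem", {
  set.seed(2)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 5), 30, 2))
  y <- rep(c("lo", "hi"), each = 30)
  mlp <- trainMLP(x, y, hidden = 8, epochs = 200, seed = 3)
  expect_gte(mean(predict(mlp, x) == y), 0.95)
  # deterministic under the seed
  mlp2 <- trainMLP(x, y, hidden = 8, epochs = 200, seed = 3)
  expect_identical(predict(mlp, x), predict(mlp2, x))
})

test_that("metrics derived from a confusion table match hand computation", {
  conf <- matrix(c(8, 1, 2, 9), 2, dimnames = list(c("A", "B"), c("A", "B")))
  rep <- reportFromConfusion(conf)
  pc <- perClassMetrics(rep)
  a <- pc[pc$class == "A", ]
  expect_equal(a$precision, 100 * 8 / 9, tolerance = 1e-9)
  expect_equal(a$sensitivity, 80)
  expect_equal(a$specificity, 90)
  expect_equal(overallAccuracy(rep), 85)
  expect_equal(sum(confusionCounts(rep)), 20)
  # binary symmetry: sensitivity of A equals specificity of B
  b <- pc[pc$class == "B", ]
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(b$sensitivity, a$specificity)
})

test_that("evaluation reports are internally consistent with their confusion", {
  set.seed(4)
  x <- rbind(matrix(rnorm(60, 0, 2), 30, 2), matrix(rnorm(60, 4, 2), 30, 2))
  y <- rep(c("p", "q"), each = 30)
  model <- trainSVM(x, y)
  rep <- evaluateClassifier(model, x, y)
  conf <- confusionCounts(rep)
  expect_equal(sum(conf), 60)
  # recompute every metric from the reported confusion counts
  redo <- reportFromConfusion(conf)
  expect_equal(perClassMetrics(redo), perClassMetrics(rep))
  expect_equal(macroMetrics(redo), macroMetrics(rep))

  # perfect predictor scores 100 everywhere
  msep <- trainSVM(rbind(x - 20, x + 20), rep(c("p", "q"), each = 60))
  perf <- evaluateClassifier(msep, rbind(x[1:30, ] - 20, x[31:60, ] + 20), y)
  expect_true(all(perClassMetrics(perf)$precision == 100))
  expect_true(all(perClassMetrics(perf)$sensitivity == 100))
  expect_true(all(perClassMetrics(perf)$specificity == 100))

  expect_error(evaluateClassifier(model, x[0, , drop = FALSE], character(0)),
               "empty")
  expect_error(evaluateClassifier(model, x[1:2, ], c("p", "zz")), "unknown")
})

test_that("an always-one-class predictor has zero specificity for that class", {
  # degenerate confusion: everything predicted as class A
  conf <- matrix(c(10, 10, 0, 0), 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  rep <- reportFromConfusion(conf)
  pc <- perClassMetrics(rep)
  expect_equal(pc[pc$class == "A", "specificity"], 0)
  expect_equal(pc[pc$class == "B", "sensitivity"], 0)
  # precision of the never-predicted class is undefined
  expect_true(is.na(pc[pc$class == "B", "precision"]))
})
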