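# Peak detection, affinity scoring, greedy matching, field losses.

test_that("peak detection finds isolated joints and suppresses near-duplicates", {
  fr <- SkeletonFrame(cbind(c(30, 10, 50), c(40, 10, 55)))
  maps <- renderConfidence(list(fr), list(gridW = 64, gridH = 64, sigma = 4))
  pk <- detectPeaks(maps[, , 1], threshold = 0.1, nmsRadius = 4)
  expect_equal(nrow(pk), 1L)
  expect_lte(sqrt((pk$x - 30)^2 + (pk$y - 40)^2), 1)
  expect_equal(pk$score, 1)

  expect_equal(nrow(detectPeaks(matrix(0, 32, 32), 0.1, 3)), 0L)

  # two joints of the same type 3 px apart with a larger suppression
  # radius collapse to one peak; brute force on the 2-Gaussian sum map
  a <- c(20, 20); b <- c(23, 20)
  g <- function(x, y, c0, s = 3) exp(-((x - c0[1])^2 + (y - c0[2])^2) / s^2)
  two <- outer(1:40, 1:40, function(yy, xx)
    pmax(g(xx, yy, a), g(xx, yy, b)))
  pk2 <- detectPeaks(two, threshold = 0.1, nmsRadius = 5)
  expect_equal(nrow(pk2), 1L)
  # the kept peak is the global maximum of the scanned map
  expect_equal(pk2$score, max(two))

  expect_error(detectPeaks(two, threshold = 1.2, nmsRadius = 3), "threshold")
})

test_that("affinity score integrates the projected field", {
  # perfect field: aligned with the candidate direction everywhere
  fld <- array(0, dim = c(32, 32, 2))
  fld[, , 1] <- 1
  a <- c(4, 16); b <- c(28, 16)
  expect_equal(affinityScore(fld, a, b, 10), 1)
  # orthogonal field scores zero
  fldO <- array(0, dim = c(32, 32, 2))
  fldO[, , 2] <- 1
  expect_equal(affinityScore(fldO, a, b, 10), 0)
  # field aligned on half the samples (x <= 16), zero elsewhere:
  # 10 uniform samples on [0,1] place 5 of them in the support
  fldH <- array(0, dim = c(32, 32, 2))
  fldH[, 1:16, 1] <- 1
  u <- seq(0, 1, length.out = 10)
  qx <- round((1 - u) * a[1] + u * b[1])
  expected <- mean(qx <= 16)
  expect_equal(affinityScore(fldH, a, b, 10), expected)
  expect_equal(expected, 0.5)

  expect_error(affinityScore(fld, a, a, 10), "zero-length")
})

test_that("affinity score is symmetric under candidate swap with field negation", {
  set.seed(42)
  for (k in 1:20) {
    fld <- array(rnorm(32 * 32 * 2), dim = c(32, 32, 2))
    a <- runif(2, 2, 30); b <- runif(2, 2, 30)
    expect_equal(affinityScore(fld, a, b, 10),
                 affinityScore(-fld, b, a, 10), tolerance = 1e-12)
  }
})

test_that("single noiseless persons are recovered joint-perfect over many seeds", {
  p <- SceneParams(64, 64, 3, 2, noiseSd = 0)
  jm <- JointModel()
  classes <- names(activityClasses())
  for (s in 1:100) {
    m <- makeMotion(classes[(s %% 3) + 1], 3, seed = s, params = p)
    sc <- makeScene(list(m), ((s %% 3) + 1), p, jm)
    sk <- assembleScene(sc, jointModel = jm)
    expect_length(sk, 1)
    truth <- coords(truthFrames(sc)[[1]])
    err <- sqrt(rowSums((sk[[1]]@coords - truth)^2))
    expect_true(all(err <= 1))
    expect_equal(nrow(sk[[1]]@limbs), nrow(limbList(jm)))
    # every accepted limb connects the right joint types
    expect_setequal(sk[[1]]@limbs$limb, 0:(nrow(limbList(jm)) - 1))
  }
})

test_that("an impossible reliability threshold rejects all limbs", {
  p <- SceneParams(64, 64, 3, 2, noiseSd = 0)
  m <- makeMotion("running", 3, seed = 1, params = p)
  sc <- makeScene(list(m), 1, p)
  sk <- assembleScene(sc, eMin = 1.1)
  expect_length(sk, 0)
})

test_that("greedy matching equals brute-force assignment on separated persons", {
  jm <- JointModel()
  for (s in 1:10) {
    n <- 2 + (s %% 2)
    p <- SceneParams(96, 64, 3, 2, noiseSd = 0, seed = s)
    ms <- makeMultiMotion(rep(names(activityClasses()), length.out = n),
                          3, seed = s, params = p)
    sc <- makeScene(ms, 2, p, jm)
    sk <- assembleScene(sc, jointModel = jm)
    expect_length(sk, n)
    # greedy total E per limb type equals the exhaustive optimum
    or <- limbScoreMatrices(sc, jm)
    greedyTotal <- sum(unlist(lapply(sk, function(x) x@limbs$E)))
    bruteTotal <- sum(vapply(or$E, function(E)
      bruteForceAssignment(E, 0.5)$total, numeric(1)))
    expect_equal(greedyTotal, bruteTotal, tolerance = 1e-9)
    # joint-to-person assignment is exact
    truths <- lapply(truthFrames(sc), coords)
    for (x in sk) {
      d <- vapply(truths, function(tr)
        max(sqrt(rowSums((x@coords - tr)^2))), numeric(1))
      expect_lte(min(d), 1)
    }
  }
})

test_that("masked field losses follow the squared-error definitions", {
  jm <- JointModel(jointNames = c("a", "b"),
                   segments = list(BB = c(0L, 0L, 1L), UB = rep(0:1, l = 7),
                                   LB = rep(0:1, l = 7)),
                   limbs = rbind(c(0L, 1L)), measured = 0:1)
  tm <- array(runif(2 * 2 * 2), dim = c(2, 2, 2))
  tf <- array(runif(2 * 2 * 2 * 1), dim = c(2, 2, 2, 1))
  mask <- array(1, dim = c(2, 2, 2))
  # exact prediction: all three losses zero
  z <- fieldLoss(tm, tm, tf, tf, mask, jointModel = jm)
  expect_equal(unlist(z), c(fR = 0, fM = 0, f = 0))
  # all-zero mask: zero loss regardless of the prediction
  z0 <- fieldLoss(tm * 0, tm, tf * 0, tf, mask * 0, jointModel = jm)
  expect_equal(z0$f, 0)
  # hand case: single 2x2 map, residual 0.5 at one unmasked point
  tm1 <- array(0, dim = c(2, 2, 1))
  pm1 <- tm1; pm1[1, 1, 1] <- 0.5
  m1 <- array(0, dim = c(2, 2, 1)); m1[1, 1, 1] <- 1
  tf1 <- array(0, dim = c(2, 2, 2, 1))
  z1 <- fieldLoss(pm1, tm1, tf1, tf1, m1,
                  fieldMask = matrix(1, 2, 2))
  expect_equal(z1$fR, 0.25)
  expect_equal(z1$fM, 0)
  # vector residuals in the affinity term
  pf <- tf1; pf[2, 2, , 1] <- c(0.3, 0.4)
  z2 <- fieldLoss(tm1, tm1, pf, tf1, m1, fieldMask = matrix(1, 2, 2))
  expect_equal(z2$fM, 0.3^2 + 0.4^2)
  expect_error(fieldLoss(tm, tm1, tf, tf, mask), "shapes disagree")
  # multi-stage total: sum of per-stage fR + fM
  expect_equal(fieldLossTotal(list(z1, z2)), z1$f + z2$f)
})

test_that("field losses are non-negative and zero only for zero masked residuals", {
  set.seed(9)
  for (k in 1:10) {
    tm <- array(runif(3 * 3 * 2), dim = c(3, 3, 2))
    pm <- tm + array(rnorm(18, sd = 0.1), dim = dim(tm))
    tf <- array(runif(3 * 3 * 2 * 1), dim = c(3, 3, 2, 1))
    mask <- array(rbinom(18, 1, 0.5), dim = c(3, 3, 2))
    z <- fieldLoss(pm, tm, tf, tf, mask, fieldMask = matrix(1, 3, 3))
    expect_gte(z$fR, 0)
    masked <- sum(mask * (pm - tm)^2)
    expect_equal(z$fR == 0, masked == 0)
  }
})
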