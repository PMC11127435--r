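# Range normalization and Procrustes calibration.

test_that("range normalization hits the exact bounds at the defining extrema", {
  set.seed(1)
  co <- cbind(runif(14, 10, 90), runif(14, 5, 200))
  nf <- normalizeFrame(co)
  expect_equal(nf$coords[which.max(co[, 1]), 1], 200)
  expect_equal(nf$coords[which.min(co[, 1]), 1], -200)
  expect_equal(nf$coords[which.max(co[, 2]), 2], 800)
  expect_equal(nf$coords[which.min(co[, 2]), 2], -800)
  # midpoint maps to zero
  co2 <- cbind(c(0, 5, 10), c(0, 50, 100))
  nf2 <- normalizeFrame(co2)
  expect_equal(nf2$coords[2, ], c(0, 0))
  # affine and order-preserving per axis
  expect_equal(order(co[, 1]), order(nf$coords[, 1]))
  expect_equal(diff(nf$coords[, 1]) / diff(co[, 1]),
               rep(400 / diff(range(co[, 1])), 13), tolerance = 1e-12)
  # degenerate ranges name the axis
  expect_error(normalizeFrame(cbind(rep(1, 4), 1:4)), "x axis")
  expect_error(normalizeFrame(cbind(1:4, rep(2, 4))), "y axis")
})

test_that("sequence normalization shares extrema across frames", {
  m <- makeMotion("running", 20, seed = 2)
  nm <- normalizeSequence(m)
  co <- coords(nm)
  expect_equal(range(co[, , 1]), c(-200, 200))
  expect_equal(range(co[, , 2]), c(-800, 800))
  # per-frame extrema would pin every frame to the bounds; shared
  # extrema leave most frames inside them
  perFrameX <- apply(co[, , 1], 1, max)
  expect_true(any(perFrameX < 200 - 1e-9))
})

test_that("centring and anisotropic scaling behave as defined", {
  cc <- centerPoints(rbind(c(0, 0), c(2, 0)))
  expect_equal(cc$centroid, c(1, 0))
  expect_equal(cc$centered, rbind(c(-1, 0), c(1, 0)))
  # already centred: identity
  pts <- rbind(c(-1, -2), c(1, 2))
  expect_equal(centerPoints(pts)$centered, pts)
  expect_error(centerPoints(matrix(numeric(0), 0, 2)), "empty")

  sc <- scalePoints(pts)
  expect_equal(sc$sFx, 1)
  expect_equal(sc$sFy, 2)
  expect_equal(sc$scaled, rbind(c(-1, -1), c(1, 1)))
  # idempotence: rescoring the scaled output gives unit norms
  sc2 <- scalePoints(sc$scaled)
  expect_equal(c(sc2$sFx, sc2$sFy), c(1, 1))
  # random frame: per-axis RMS of the output is exactly 1
  set.seed(7)
  r <- centerPoints(cbind(rnorm(14), rnorm(14)))$centered
  rs <- scalePoints(r)$scaled
  expect_equal(sqrt(mean(rs[, 1]^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(mean(rs[, 2]^2)), 1, tolerance = 1e-12)
  expect_error(scalePoints(cbind(rep(0, 5), 1:5 - 3)), "x axis")
})

test_that("optimal rotation recovers known angles and matches grid search", {
  set.seed(3)
  model <- centerPoints(cbind(rnorm(14), rnorm(14)))$centered
  idt <- optimalRotation(model, model)
  expect_equal(idt$theta, 0)
  expect_equal(idt$pd2, 0, tolerance = 1e-20)
  # a sample that is the model rotated by +30 degrees needs -30 back
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sample <- model %*% t(R)
  rec <- optimalRotation(sample, model)
  expect_equal(rec$theta, -th, tolerance = 1e-12)
  expect_equal(rec$pd2, 0, tolerance = 1e-18)
  # random pair: closed form equals the 0.01-degree grid search
  sample2 <- centerPoints(cbind(rnorm(14), rnorm(14)))$centered
  cf <- optimalRotation(sample2, model)
  gs <- gridSearchTheta(sample2, model)
  expect_equal(cf$pd2, gs$pd2, tolerance = 1e-6)
  expect_lt(abs(cf$theta - gs$theta), 0.011 * pi / 180)
  expect_error(optimalRotation(model[1:5, ], model), "counts differ")
})

test_that("calibration is the identity on the model frame itself", {
  model <- basePose()
  m <- MotionSequence(array(model, dim = c(1, 15, 2)))
  cal <- procrustesCalibrate(m, model)
  tr <- cal$transforms[[1]]
  expect_equal(tr@theta, 0, tolerance = 1e-12)
  expect_equal(tr@pd2, 0, tolerance = 1e-18)
})

test_that("calibration undoes random translation + per-axis scaling + rotation", {
  # the base pose is left-right symmetric, so its centred x and y
  # coordinates are uncorrelated; that is the regime where anisotropic
  # RMS scaling commutes with the rotation recovery and the chain is
  # exactly invertible (see the methods vignette)
  base <- basePose()
  bs <- scalePoints(centerPoints(base)$centered)$scaled
  for (s in 1:20) {
    set.seed(s)
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    distorted <- bs %*% t(R)
    distorted <- sweep(distorted, 2, c(runif(1, 0.5, 3), runif(1, 0.5, 3)), `*`)
    distorted <- sweep(distorted, 2, runif(2, -50, 50), `+`)
    m <- MotionSequence(array(distorted, dim = c(1, 15, 2)))
    cal <- procrustesCalibrate(m, base)
    expect_lt(cal$transforms[[1]]@pd2, 1e-12)
    # the recovered angle undoes the applied one
    dth <- (cal$transforms[[1]]@theta + th) %% (2 * pi)
    expect_lt(min(dth, 2 * pi - dth), 1e-6)
  }
  # translation + per-axis scaling alone is always exactly undone
  mTS <- MotionSequence(array(sweep(sweep(base, 2, c(2.5, 0.7), `*`),
                                    2, c(30, -10), `+`),
                              dim = c(1, 15, 2)))
  calTS <- procrustesCalibrate(mTS, base)
  expect_equal(calTS$transforms[[1]]@pd2, 0, tolerance = 1e-18)
  expect_equal(calTS$transforms[[1]]@theta, 0, tolerance = 1e-12)
})

test_that("calibrated output is invariant to pre-applied translation and scaling", {
  m <- normalizeSequence(makeMotion("aerobics", 10, seed = 5))
  model <- meanFrame(list(m))
  cal1 <- procrustesCalibrate(m, model)$motion
  co <- coords(m)
  co2 <- co
  for (i in 1:10)
    co2[i, , ] <- sweep(sweep(co[i, , ], 2, c(1.7, 0.4), `*`),
                        2, c(12, -5), `+`)
  m2 <- MotionSequence(co2, label = activityLabel(m))
  cal2 <- procrustesCalibrate(m2, model)$motion
  expect_equal(coords(cal2), coords(cal1), tolerance = 1e-9)
})

test_that("calibrated output is invariant to pre-applied rotation for symmetric frames", {
  base <- basePose()
  bs <- scalePoints(centerPoints(base)$centered)$scaled
  m <- MotionSequence(array(bs, dim = c(1, 15, 2)))
  cal1 <- procrustesCalibrate(m, base)$motion
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  m2 <- MotionSequence(array(bs %*% t(R), dim = c(1, 15, 2)))
  cal2 <- procrustesCalibrate(m2, base)$motion
  expect_equal(coords(cal2), coords(cal1), tolerance = 1e-9)
})

test_that("mean squared Procrustes distance grows with coordinate noise", {
  base <- basePose() * 60 + 64
  meanPd2 <- vapply(c(0, 2, 6), function(sd) {
    tot <- 0
    for (s in 1:10) {
      set.seed(100 + s)
      noisy <- base + matrix(rnorm(30, sd = sd), 15, 2)
      m <- MotionSequence(array(noisy, dim = c(1, 15, 2)))
      tot <- tot + procrustesCalibrate(m, base)$transforms[[1]]@pd2
    }
    tot / 10
  }, numeric(1))
  expect_true(all(diff(meanPd2) > 0))
})
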