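# Synthetic motion generation and ground-truth field rendering.

test_that("motion generation is deterministic and matches the closed form at zero noise", {
  m1 <- makeMotion("running", 50, seed = 1)
  m2 <- makeMotion("running", 50, seed = 1)
  expect_identical(coords(m1), coords(m2))
  expect_equal(dim(coords(m1)), c(50L, 15L, 2L))

  m3 <- makeMotion("running", 50, seed = 7)
  expect_false(identical(coords(m1), coords(m3)))

  # zero noise: reconstruct the r_wrist (joint 8) trajectory directly
  # from the class table and base pose
  p0 <- SceneParams(noiseSd = 0)
  m0 <- makeMotion("running", 50, seed = 1, params = p0)
  cls <- activityClasses()$running
  base <- basePose()
  tt <- (0:49) / 20
  h <- 0.55 * 128
  cmp <- Filter(function(cc) 8 %in% cc$joints, cls$components)[[1]]
  s <- sin(2 * pi * cls$freq_hz * tt + 2 * pi * cmp$phase)
  expect_equal(coords(m0)[, 9, 1], 64 + h * (base[9, 1] + cmp$amp_x * s),
               tolerance = 1e-12)
  expect_equal(coords(m0)[, 9, 2], 64 + h * (base[9, 2] + cmp$amp_y * s),
               tolerance = 1e-12)
  # derived hip centre stays the femur-head midpoint, noise or not
  mN <- makeMotion("running", 20, seed = 3)
  expect_equal(coords(mN)[, 1, ],
               (coords(mN)[, 10, ] + coords(mN)[, 13, ]) / 2,
               tolerance = 1e-12)
})

test_that("unknown class tokens fail with the valid tokens named", {
  expect_error(makeMotion("swimming", 10), "running")
  expect_error(makeMotion("x", 10), "unknown activity class")
})

test_that("confidence rendering follows the Gaussian model with max fusion", {
  fr <- SkeletonFrame(cbind(c(30, 10, 40), c(40, 12, 20)))
  p <- list(gridW = 64, gridH = 64, sigma = 6)
  maps <- renderConfidence(list(fr), p)
  # value 1 exactly at the joint, exp(-1) at distance sigma
  expect_equal(maps[40, 30, 1], 1)
  expect_equal(maps[40, 36, 1], exp(-1), tolerance = 1e-12)
  expect_true(all(maps > 0 & maps <= 1))

  # two persons on an 8x8 grid: fused map equals the brute-force
  # pointwise max of the per-person Gaussians
  f1 <- SkeletonFrame(cbind(c(2, 3, 4), c(2, 3, 4)), personId = 1)
  f2 <- SkeletonFrame(cbind(c(6, 6, 6), c(6, 5, 2)), personId = 2)
  p8 <- list(gridW = 8, gridH = 8, sigma = 2)
  fused <- renderConfidence(list(f1, f2), p8)
  for (j in 1:3) {
    expected <- matrix(0, 8, 8)
    for (y in 1:8) for (x in 1:8) {
      s1 <- exp(-((x - f1@coords[j, 1])^2 + (y - f1@coords[j, 2])^2) / 4)
      s2 <- exp(-((x - f2@coords[j, 1])^2 + (y - f2@coords[j, 2])^2) / 4)
      expected[y, x] <- max(s1, s2)
    }
    expect_equal(fused[, , j], expected, tolerance = 1e-12)
  }
  # fused map dominates each per-person map pointwise
  m1 <- renderConfidence(list(f1), p8)
  m2 <- renderConfidence(list(f2), p8)
  expect_true(all(fused >= m1 - 1e-15))
  expect_true(all(fused >= m2 - 1e-15))
})

test_that("affinity fields hold unit vectors on the limb and zero elsewhere", {
  jm <- JointModel()
  # vertical limb 0-1 for a single person: field on the midline is the
  # unit vector from joint 1 towards joint 0
  co <- basePose() * 40 + 32
  fr <- SkeletonFrame(co)
  p <- list(gridW = 64, gridH = 64, sigma = 3, limbWidth = 2)
  paf <- renderPAF(list(fr), p, jm)
  p1 <- co[1, ]; p2 <- co[2, ]
  v <- (p1 - p2) / sqrt(sum((p1 - p2)^2))
  mid <- round((p1 + p2) / 2)
  expect_equal(unname(paf[mid[2], mid[1], , 1]), unname(v), tolerance = 1e-12)
  # far corner is off every limb
  expect_equal(paf[1, 64, , 1], c(0, 0))
  # norms never exceed 1
  nrm <- sqrt(paf[, , 1, ]^2 + paf[, , 2, ]^2)
  expect_true(all(nrm <= 1 + 1e-12))
  # single-person averaging is idempotent: field values are 0 or unit
  expect_true(all(abs(nrm) < 1e-12 | abs(nrm - 1) < 1e-12))
})

test_that("overlapping limbs of two persons are averaged over contributors", {
  jm <- JointModel(jointNames = c("a", "b", "c"),
                   segments = list(BB = 0:2, UB = c(0:2, 0:2, 0),
                                   LB = c(0:2, 0:2, 0)),
                   limbs = rbind(c(0L, 1L), c(1L, 2L)), measured = 0:2)
  # person 1: horizontal limb through (20, 20); person 2: vertical limb
  # crossing it at the same point
  f1 <- SkeletonFrame(cbind(c(30, 10, 10), c(20, 20, 30)))
  f2 <- SkeletonFrame(cbind(c(20, 20, 30), c(30, 10, 35)))
  p <- list(gridW = 40, gridH = 40, sigma = 3, limbWidth = 1.5)
  paf <- renderPAF(list(f1, f2), p, jm)
  u1 <- c(1, 0)    # person 1, limb 0-1 points +x
  u2 <- c(0, 1)    # person 2, limb 0-1 points +y
  expect_equal(unname(paf[20, 20, , 1]), (u1 + u2) / 2, tolerance = 1e-12)
})

test_that("coincident limb endpoints are skipped with a warning", {
  jm <- JointModel(jointNames = c("a", "b", "c"),
                   segments = list(BB = 0:2, UB = c(0:2, 0:2, 0),
                                   LB = c(0:2, 0:2, 0)),
                   limbs = rbind(c(0L, 1L), c(1L, 2L)), measured = 0:2)
  fr <- SkeletonFrame(cbind(c(10, 10, 20), c(10, 10, 20)))
  expect_warning(paf <- renderPAF(list(fr), list(gridW = 32, gridH = 32,
                                                 limbWidth = 2), jm),
                 "coincident")
  expect_equal(sum(abs(paf[, , , 1])), 0)
})

test_that("scenes carry visibility masks and compose correctly", {
  p <- SceneParams(64, 64, 3, 2, noiseSd = 0)
  m <- makeMotion("running", 5, seed = 1, params = p)
  sc <- makeScene(list(m), 2, p)
  expect_true(all(sceneMask(sc) == 1))
  expect_equal(dim(confMaps(sc)), c(64, 64, 15))
  expect_equal(dim(pafFields(sc)), c(64, 64, 2, 14))

  vis <- matrix(TRUE, nFrames(m), nJoints(m))
  vis[, 6] <- FALSE
  m2 <- MotionSequence(coords(m), visible = vis, label = "running")
  sc2 <- makeScene(list(m2), 2, p)
  expect_true(all(sceneMask(sc2)[, , 6] == 0))
  expect_true(all(sceneMask(sc2)[, , -6] == 1))
  # an invisible joint is not rendered
  expect_equal(sum(confMaps(sc2)[, , 6]), 0)

  expect_error(makeScene(list(), 1, p), "empty")
  expect_error(makeScene(list(m), 99, p), "missing")
})

test_that("scene determinism: identical params and seed give identical scenes", {
  p <- SceneParams(64, 64, 3, 2, noiseSd = 1, seed = 4)
  s1 <- makeScene(list(makeMotion("aerobics", 4, seed = 4, params = p)), 3, p)
  s2 <- makeScene(list(makeMotion("aerobics", 4, seed = 4, params = p)), 3, p)
  expect_identical(confMaps(s1), confMaps(s2))
  expect_identical(pafFields(s1), pafFields(s2))
})
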