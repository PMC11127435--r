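# Independent oracles used to check the package's implementations.
# These deliberately use different algorithms (exhaustive enumeration,
# explicit grid search, direct normal equations) from the code under
# test.

# Exhaustive maximum-total-score assignment between row and column
# candidates of a score matrix, keeping only pairs with score >= eMin.
# Enumerates every injective partial assignment (fine for <= 5 x 5).
bruteForceAssignment <- function(E, eMin) {
  nA <- nrow(E); nB <- ncol(E)
  best <- list(total = 0, pairs = cbind(integer(0), integer(0)))
  recurse <- function(row, used, total, pairs) {
    if (total > best$total + 1e-12) best <<- list(total = total, pairs = pairs)
    if (row > nA) return()
    recurse(row + 1L, used, total, pairs)         # leave this row unmatched
    for (col in seq_len(nB)) {
      if (used[col] || E[row, col] < eMin) next
      used[col] <- TRUE
      recurse(row + 1L, used, total + E[row, col], rbind(pairs, c(row, col)))
      used[col] <- FALSE
    }
  }
  recurse(1L, logical(nB), 0, best$pairs)
  best
}

# Rotation-angle grid search at a given resolution (degrees), applying
# explicit rotation matrices to the sample set for every angle.
gridSearchTheta <- function(sample, model, resDeg = 0.01) {
  th <- seq(-180, 180, by = resDeg) * pi / 180
  cs <- cos(th); sn <- sin(th)
  rx <- outer(cs, sample[, 1]) - outer(sn, sample[, 2])
  ry <- outer(sn, sample[, 1]) + outer(cs, sample[, 2])
  pd2 <- rowSums(sweep(rx, 2, model[, 1])^2) +
         rowSums(sweep(ry, 2, model[, 2])^2)
  k <- which.min(pd2)
  list(theta = th[k], pd2 = pd2[k])
}

# Direct normal-equations polynomial fit (independent of lm.fit).
normalEquationsPolyfit <- function(y, degree, u = NULL) {
  n <- length(y)
  if (is.null(u)) u <- (seq_len(n) - 1) / (n - 1)
  X <- outer(u, 0:degree, `^`)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Candidate tables and per-limb affinity matrices for a scene, used to
# compare greedy matching against the brute-force oracle.
limbScoreMatrices <- function(scene, jointModel = JointModel(),
                              threshold = 0.1, nmsRadius = NULL,
                              nSamples = 10L) {
  if (is.null(nmsRadius)) nmsRadius <- sceneParams(scene)@sigma
  nJ <- dim(confMaps(scene))[3]
  cands <- lapply(seq_len(nJ), function(j)
    detectPeaks(confMaps(scene)[, , j], threshold, nmsRadius))
  limbs <- limbList(jointModel)
  mats <- vector("list", nrow(limbs))
  for (ci in seq_len(nrow(limbs))) {
    cA <- cands[[limbs[ci, 1] + 1]]
    cB <- cands[[limbs[ci, 2] + 1]]
    E <- matrix(-Inf, nrow(cA), nrow(cB))
    for (ia in seq_len(nrow(cA))) for (ib in seq_len(nrow(cB))) {
      a <- c(cB$x[ib], cB$y[ib]); b <- c(cA$x[ia], cA$y[ia])
      if (sum((a - b)^2) > 1e-18)
        E[ia, ib] <- affinityScore(pafFields(scene)[, , , ci], a, b, nSamples)
    }
    mats[[ci]] <- E
  }
  list(candidates = cands, E = mats)
}
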