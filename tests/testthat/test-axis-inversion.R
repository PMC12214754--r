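test_that("eigenposes obey the mean-pose identities", {
  b <- fx_basis("3D_VD", small = TRUE)
  mean_pose <- poseAxes:::reshape_pose(pcCenter(b))
  for (i in c(1, 4)) {
    expect_equal(eigenpose(b, i, 0), mean_pose, tolerance = 1e-15)
    ep <- eigenpose(b, i, 1)
    em <- eigenpose(b, i, -1)
    expect_equal(ep + em, 2 * mean_pose, tolerance = 1e-12)
    d <- eigenpose(b, i, 3) - mean_pose
    expect_equal(sum(d^2), 9 * pcSds(b)[i]^2, tolerance = 1e-10)
  }
  expect_error(eigenpose(b, 99, 1), "invalid-argument")
})

test_that("the axis transform is the loading-weighted component sum", {
  b <- fx_basis("3D_VD", small = TRUE)
  e1 <- c(1, rep(0, 9))
  T1 <- axisToKeypoints(b, e1)
  expect_equal(as.vector(t(T1)), pcComponents(b)[, 1], tolerance = 1e-15)
  expect_true(all(axisToKeypoints(b, rep(0, 10)) == 0))
  beta <- rnorm(10)
  T <- axisToKeypoints(b, beta)
  # orthonormal components preserve the norm
  expect_equal(sum(T^2), sum(beta^2), tolerance = 1e-12)
})

test_that("keypoint weights are row magnitudes", {
  expect_equal(keypointWeights(rbind(c(3, 4), c(0, 0))), c(5, 0))
  expect_equal(keypointWeights(rbind(c(1, 2, 2))), 3)
})

test_that("poses along the axis are linear in the step and match eigenposes", {
  b <- fx_basis("3D_VD", small = TRUE)
  beta <- rnorm(10)
  mean_pose <- poseAxes:::reshape_pose(pcCenter(b))
  expect_equal(poseAlongAxis(b, beta, 0), mean_pose, tolerance = 1e-15)
  a1 <- poseAlongAxis(b, beta, 1) - mean_pose
  a2 <- poseAlongAxis(b, beta, 2) - mean_pose
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
  # an axis on PC1 only traverses the PC1 eigenpose family rescaled by the
  # component's variance (the extra sd factor of the scaled coefficients)
  e1 <- c(1, rep(0, 9))
  kappa <- 2
  expected <- mean_pose +
    pcSds(b)[1]^2 * (eigenpose(b, 1, kappa) - mean_pose) / pcSds(b)[1]
  expect_equal(poseAlongAxis(b, e1, kappa),
               mean_pose + (eigenpose(b, 1, kappa) - mean_pose) * pcSds(b)[1],
               tolerance = 1e-12)
  expect_equal(poseAlongAxis(b, e1, kappa), expected, tolerance = 1e-12)
})

test_that("model responses agree in keypoint and PC space", {
  # inversion round trip: (x - center) . t == z . beta
  X <- dataMatrix(fx_mat("3D_VD", small = TRUE))
  b <- fx_basis("3D_VD", small = TRUE)
  Z <- fx_scores("3D_VD", small = TRUE)
  beta <- rnorm(10)
  t_vec <- as.vector(t(axisToKeypoints(b, beta)))
  resp_kp <- drop(sweep(X, 2, pcCenter(b)) %*% t_vec)
  resp_pc <- drop(Z %*% beta)
  expect_equal(resp_kp, resp_pc, tolerance = 1e-12)
})

test_that("weights are invariant to component sign flips", {
  b <- fx_basis("3D_VD", small = TRUE)
  beta <- rnorm(10)
  w <- keypointWeights(axisToKeypoints(b, beta))
  b2 <- b
  b2@components[, 3] <- -b2@components[, 3]
  beta2 <- beta
  beta2[3] <- -beta2[3]
  expect_equal(keypointWeights(axisToKeypoints(b2, beta2)), w,
               tolerance = 1e-12)
})

test_that("permutation significance recovers planted keypoint loadings", {
  # an axis planted on the two hand keypoints, expressed in the standard
  # 10-PC space (its keypoint image is the subspace projection, so other
  # keypoints carry residual weight; the hands must dominate and be flagged)
  b <- fx_basis("3D_VD")
  Z <- fx_scores("3D_VD")
  hands <- match(c("l_hand", "r_hand"), poseAxes:::kp_labels)
  cols <- sort(c(3 * (hands - 1) + 1, 3 * (hands - 1) + 2, 3 * hands))
  t_true <- numeric(66)
  set.seed(23)
  t_true[cols] <- c(2, 1.5, 1.8, -1.7, 1.6, 2.1)
  beta_true <- drop(t(pcComponents(b)) %*% t_true)
  y0 <- drop(Z %*% beta_true)
  # the projected axis concentrates on the hands
  expect_identical(sort(order(-keypointWeights(axisToKeypoints(b, beta_true)))[1:2]),
                   hands)
  hits <- vapply(seq_len(20), function(rep) {
    set.seed(300 + rep)
    y <- y0 + rnorm(length(y0), sd = 0.05 * stats::sd(y0))
    ws <- weightSignificance(Z, y, b, nPerm = 400, seed = 300 + rep,
                             refit = "full")
    all(ws$significant[hands])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pure-noise units yield almost no significant keypoints", {
  Z <- fx_scores("3D_VD", small = TRUE)
  b <- fx_basis("3D_VD", small = TRUE)
  ndisc <- vapply(seq_len(100), function(rep) {
    set.seed(500 + rep)
    y <- rnorm(nrow(Z))
    sum(weightSignificance(Z, y, b, nPerm = 400, seed = 500 + rep,
                           refit = "full")$significant)
  }, numeric(1))
  expect_lt(mean(ndisc), 0.5)
})

test_that("the identity permutation gives p = 1 everywhere", {
  Z <- fx_scores("3D_VD", small = TRUE)
  b <- fx_basis("3D_VD", small = TRUE)
  y <- rnorm(nrow(Z))
  ws <- suppressWarnings(
    weightSignificance(Z, y, b, nPerm = 1, seed = 1, nFolds = 5))
  expect_true(all(ws$p == 1))
  expect_false(any(ws$significant))
  expect_warning(weightSignificance(Z, y, b, nPerm = 2, seed = 1, nFolds = 5),
                 "resolution")
})

test_that("visualizePreferredAxis bundles a consistent inversion", {
  b <- fx_basis("3D_VD", small = TRUE)
  Z <- fx_scores("3D_VD", small = TRUE)
  y <- drop(Z %*% rnorm(10)) + rnorm(nrow(Z), sd = 0.2)
  fit <- fitPcrCv(Z, y, seed = 3, unitId = "demo")
  av <- visualizePreferredAxis(b, fit)
  expect_s4_class(av, "AxisVisualization")
  expect_equal(av@weights, keypointWeights(av@T), tolerance = 1e-15)
  expect_equal(av@poses[["kappa_0"]],
               poseAxes:::reshape_pose(pcCenter(b)), tolerance = 1e-15)
  expect_equal(max(av@displayWeights), 1)
  expect_equal(av@b, pcSds(b) * preferredAxis(fit), tolerance = 1e-15)
})
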