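test_that("the pose grid has the full factorial structure", {
  ps <- fx_pose45()
  si <- stimulusInfo(ps)
  expect_equal(nrow(si), 720)
  expect_equal(length(unique(si$pose_id)), 45)
  expect_equal(sort(unique(si$azimuth)), seq(0, 315, by = 45))
  expect_equal(sort(unique(si$elevation)), c(0, 45))
  expect_false(anyDuplicated(si[c("pose_id", "azimuth", "elevation")]) > 0)
  co <- poseCoords(ps)
  expect_true(all(is.finite(co)))
  expect_true(min(co[, 1:2, ]) >= 0 && max(co[, 1:2, ]) <= 350)
  # 9 pose classes with 5 exemplars each
  expect_equal(as.vector(table(unique(si[c("pose_id", "pose_class")])$pose_class)),
               rep(5L, 9))
})

test_that("pose generation is deterministic and validates its arguments", {
  a <- generatePoseSet(4, 16, seed = 3)
  b <- generatePoseSet(4, 16, seed = 3)
  expect_identical(poseCoords(a), poseCoords(b))
  expect_error(generatePoseSet(0, 16, seed = 1), "invalid-argument")
  expect_error(generatePoseSet(4, 15, seed = 1), "invalid-argument")
})

test_that("projection wraps at 360 degrees and respects bilateral symmetry", {
  ang <- poseAxes:::kp_neutral_angles()
  coords <- poseAxes:::kp_forward(ang)
  p0 <- poseAxes:::project_pose(coords, 0, 45)
  p360 <- poseAxes:::project_pose(coords, 360, 45)
  expect_equal(p0, p360, tolerance = 1e-12)

  # a bilaterally symmetric pose: mirror every left bone azimuth onto the
  # right one (angles phi -> pi - phi about the sagittal plane)
  sym <- ang
  left <- grep("^l_", poseAxes:::kp_labels[poseAxes:::kp_bones()[, 2]])
  right <- grep("^r_", poseAxes:::kp_labels[poseAxes:::kp_bones()[, 2]])
  sym[right, 1] <- pi - sym[left, 1]
  sym[right, 2] <- sym[left, 2]
  co <- poseAxes:::kp_forward(sym)
  v90 <- poseAxes:::project_pose(co, 90, 0)
  v270 <- poseAxes:::project_pose(co, 270, 0)
  # the two views relate by a mirror: per keypoint, x negates about the
  # center; equivalently (by the pose's symmetry) left/right relabeling
  # reproduces the other view exactly
  expect_equal(v270[, "x"], -v90[, "x"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(v270[, "y"], v90[, "y"], tolerance = 1e-10,
               ignore_attr = TRUE)
  lab <- poseAxes:::kp_labels
  mirrored <- sub("^l_", "TMP_", lab)
  mirrored <- sub("^r_", "l_", mirrored)
  mirrored <- sub("^TMP_", "r_", mirrored)
  swap <- match(mirrored, lab)
  expect_equal(v270[swap, c("x", "y")], v90[, c("x", "y")],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("silhouettes are binary, clipped, and empty without bones", {
  ps <- fx_pose8()
  sil <- renderSilhouettes(ps, 25)
  s <- sil@silhouettes
  expect_equal(dim(s), c(128, 25, 25))
  expect_true(all(s %in% c(0, 1)))
  expect_true(all(apply(s, 1, sum) > 0))
  expect_error(renderSilhouettes(ps, 4), "invalid-argument")
  # no bones -> all-zero image
  empty <- poseAxes:::rasterize_bones(matrix(100, 22, 2),
                                      matrix(integer(0), 0, 2), 350, 25)
  expect_true(all(empty == 0))
  # translating a pose a full image width off canvas -> all-zero image
  xy <- poseCoords(ps)[, 1:2, 1]
  off <- poseAxes:::rasterize_bones(xy + 360, poseAxes:::kp_bones(), 350, 25)
  expect_true(all(off == 0))
})

test_that("noise-free units reproduce their generative means exactly", {
  b <- fx_basis("3D_VD", small = TRUE)
  X <- fx_mat("3D_VD", small = TRUE)
  u <- simulateEncodingUnits(b, X, nUnits = 2, gain = 20, noise = "none",
                             nTrials = 4, seed = 5)[[1]]
  Z <- fx_scores("3D_VD", small = TRUE)
  mu <- pmax(10 + 20 * drop(Z %*% u@groundTruth$beta_true), 0)
  expect_equal(colMeans(u@responseRates), mu, tolerance = 1e-12)
  expect_equal(splitHalfReliability(u@responseRates, 5, seed = 1), 1)
})

test_that("zero-gain units are selective only at the nominal false-positive rate", {
  b <- fx_basis("3D_VD", small = TRUE)
  X <- fx_mat("3D_VD", small = TRUE)
  units <- simulateEncodingUnits(b, X, nUnits = 200, gain = 0, nTrials = 4,
                                 seed = 6)
  p <- vapply(units, function(u) selectivityTest(u@responseRates), numeric(1))
  rej <- mean(p < 0.05)
  # binomial 99% CI around 0.05 at n = 200 is about +/- 0.04
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.10)
})

test_that("reliability calibration hits its target", {
  units <- fx_units_vd()
  rel <- vapply(seq_along(units), function(i) {
    splitHalfReliability(units[[i]]@responseRates, nSplits = 50, seed = i)
  }, numeric(1))
  expect_gte(median(rel), 0.65)
  expect_lte(median(rel), 0.75)
  expect_error(
    simulateEncodingUnits(fx_basis("3D_VD", TRUE), fx_mat("3D_VD", TRUE),
                          nUnits = 2, targetReliability = 1.2, seed = 1),
    "invalid-argument")
})

test_that("identical seeds give bit-identical unit recordings", {
  b <- fx_basis("3D_VD", small = TRUE)
  X <- fx_mat("3D_VD", small = TRUE)
  u1 <- simulateEncodingUnits(b, X, nUnits = 3, gain = 8, nTrials = 4,
                              seed = 9)
  u2 <- simulateEncodingUnits(b, X, nUnits = 3, gain = 8, nTrials = 4,
                              seed = 9)
  expect_identical(lapply(u1, function(u) u@responseRates),
                   lapply(u2, function(u) u@responseRates))
  expect_identical(lapply(u1, function(u) u@groundTruth$beta_true),
                   lapply(u2, function(u) u@groundTruth$beta_true))
})

test_that("category responses map gain ratios onto the expected BSI", {
  bsi <- function(bg, ng) {
    computeBsi(simulateCategoryResponses(bg, ng, noise = "none", seed = 1))
  }
  expect_equal(bsi(2, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(bsi(3, 3), 0, tolerance = 1e-12)
  expect_equal(bsi(4, 0), 1, tolerance = 1e-12)
  expect_error(bsi(0, 0), "undefined-BSI")
})

test_that("surrogate features are deterministic and can reproduce keypoints", {
  X2d <- fx_mat("2D", small = TRUE)
  f1 <- surrogateFeatureMatrix(X2d, 30, seed = 4)
  f2 <- surrogateFeatureMatrix(X2d, 30, seed = 4)
  expect_identical(f1, f2)
  ident <- surrogateFeatureMatrix(X2d, ncol(dataMatrix(X2d)),
                                  nonlinearity = "identity",
                                  projection = "identity", seed = 1)
  expect_equal(unname(ident), unname(dataMatrix(X2d)), tolerance = 1e-15)
})

test_that("silhouette-derived features retain pose information", {
  ps <- fx_pose8()
  sil <- renderSilhouettes(ps, 25)
  feats <- surrogateFeatureMatrix(sil, 500, seed = 2)
  # treat features as noise-free units, two identical trials each
  rates <- lapply(seq_len(ncol(feats)), function(j) {
    rbind(feats[, j], feats[, j]) + 10 # shift off zero for correlations
  })
  d <- decodePoses(rates, stimulusInfo(ps)$pose_id, nResamples = 2,
                   pseudoTrialsPerClass = 32, seed = 3)
  # pose is decodable across views far above the 12.5% chance level
  expect_gt(d@accuracy, 50)
})
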