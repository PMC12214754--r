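# Shared fixtures, built once per run and memoised.

.fx <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

# full-scale stimulus grid (45 poses x 16 views)
fx_pose45 <- function() memo("pose45", function() {
  generatePoseSet(45, 16, seed = 7)
})

# small grid for cheap structural tests
fx_pose8 <- function() memo("pose8", function() {
  generatePoseSet(8, 16, seed = 11)
})

fx_mat <- function(variant, small = FALSE) {
  key <- paste0("mat_", variant, if (small) "_s")
  memo(key, function() {
    buildDataMatrix(if (small) fx_pose8() else fx_pose45(), variant)
  })
}

fx_basis <- function(variant, small = FALSE) {
  key <- paste0("basis_", variant, if (small) "_s")
  memo(key, function() fitPCA(fx_mat(variant, small), 10))
}

fx_scores <- function(variant, small = FALSE) {
  key <- paste0("scores_", variant, if (small) "_s")
  memo(key, function() {
    projectScores(fx_basis(variant, small), fx_mat(variant, small))
  })
}

# calibrated 3D_VD population at target reliability 0.7 (the workhorse of the
# recovery and null-calibration checks)
fx_units_vd <- function() memo("units_vd", function() {
  simulateEncodingUnits(fx_basis("3D_VD"), fx_mat("3D_VD"), nUnits = 50,
                        targetReliability = 0.7, nTrials = 8, seed = 202)
})

# a manually built PoseSet with known coordinates (for scaling examples)
fx_const_pose_set <- function(value = 175, imageSize = 350) {
  n <- 16
  info <- data.frame(stimulus_index = seq_len(n),
                     pose_id = 1L, pose_class = 1L,
                     azimuth = rep(seq(0, 315, by = 45), 2),
                     elevation = rep(c(0, 45), each = 8))
  info$pose_id <- rep(1L, n)
  co <- array(value, dim = c(22, 3, n))
  methods::new("PoseSet", coords = co, stimInfo = info,
               keypointLabels = poseAxes:::kp_labels,
               bones = poseAxes:::kp_bones(), imageSize = imageSize,
               globalScale = 1)
}

# partition-equality up to relabeling, with exact noise agreement
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a == -1) == (b == -1))) return(FALSE)
  a2 <- a[a != -1]
  b2 <- b[b != -1]
  if (!length(a2)) return(TRUE)
  all(outer(a2, a2, `==`) == outer(b2, b2, `==`))
}

cosine_sim <- function(a, b) {
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}
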