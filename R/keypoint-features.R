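#' Build a keypoint data matrix for one model variant
#'
#' Reshapes the keypoint coordinates of every stimulus into one row of a
#' stimuli-by-coordinates design matrix, interleaving coordinates per keypoint
#' (`x1, y1, x2, y2, ...` for 2D variants; `x1, y1, z1, ...` for 3D), and
#' divides every coordinate by the image size. View-flipped (`2D_VF`,
#' `3D_VF`) and view-invariant (`3D_VI`) variants are produced by delegating
#' to [applyViewFlip()] / [applyViewInvariance()] on the corresponding base
#' matrix.
#'
#' @param poseSet a complete [PoseSet-class].
#' @param variant `"2D"`, `"3D_VD"`, `"2D_VF"`, `"3D_VF"` or `"3D_VI"`.
#' @return A [KeypointMatrix-class]; 44 columns for 2D variants, 66 for 3D.
#' @examples
#' ps <- generatePoseSet(nPoses = 4, nViews = 16, seed = 1)
#' dim(dataMatrix(buildDataMatrix(ps, "3D_VD")))
#' @export
buildDataMatrix <- function(poseSet, variant = c("2D", "3D_VD", "2D_VF",
                                                 "3D_VF", "3D_VI")) {
  variant <- match.arg(variant)
  stopifnot(methods::is(poseSet, "PoseSet"))
  coords <- poseSet@coords
  if (anyNA(coords)) stop("incomplete-input: missing keypoint coordinates")
  n <- dim(coords)[3]
  nk <- dim(coords)[1]
  use3d <- variant %in% c("3D_VD", "3D_VF", "3D_VI")
  ncoord <- if (use3d) 3L else 2L
  X <- matrix(NA_real_, n, nk * ncoord)
  for (i in seq_len(n)) {
    X[i, ] <- as.vector(t(coords[, seq_len(ncoord), i]))
  }
  X <- X / poseSet@imageSize
  layout <- if (use3d) "xyz" else "xy"
  cn <- as.vector(t(outer(seq_len(nk), c("x", "y", "z")[seq_len(ncoord)],
                          function(i, a) paste0(a, i))))
  colnames(X) <- cn
  base <- methods::new("KeypointMatrix", X = X,
                       variant = if (use3d) "3D_VD" else "2D",
                       columnLayout = layout, stimInfo = poseSet@stimInfo,
                       imageSize = poseSet@imageSize)
  switch(variant,
    "2D" = , "3D_VD" = base,
    "2D_VF" = , "3D_VF" = applyViewFlip(base),
    "3D_VI" = applyViewInvariance(base)
  )
}

# Check that every (pose, elevation) group carries the full azimuth grid.
check_complete_grid <- function(stimInfo) {
  az <- sort(unique(stimInfo$azimuth))
  grp <- split(stimInfo$azimuth, paste(stimInfo$pose_id, stimInfo$elevation))
  ok <- vapply(grp, function(a) identical(sort(a), az), logical(1))
  if (!all(ok)) stop("incomplete-grid: a (pose, elevation) group misses azimuths")
  az
}

# Row-replacement core shared by the matrix- and score-level constructions:
# for each (pose, elevation), rows at azimuth a > 180 take the values of the
# mirror azimuth 360 - a (or the reverse direction).
view_flip_rows <- function(M, stimInfo,
                           direction = c("late_from_early",
                                         "early_from_late")) {
  direction <- match.arg(direction)
  check_complete_grid(stimInfo)
  out <- M
  key <- paste(stimInfo$pose_id, stimInfo$elevation, stimInfo$azimuth)
  idx <- function(pose, elev, az) {
    match(paste(pose, elev, az), key)
  }
  for (i in seq_len(nrow(stimInfo))) {
    az <- stimInfo$azimuth[i]
    mirror <- (360 - az) %% 360
    if (mirror == az) next
    replace_late <- direction == "late_from_early"
    if ((replace_late && az > 180) || (!replace_late && az < 180)) {
      j <- idx(stimInfo$pose_id[i], stimInfo$elevation[i], mirror)
      out[i, ] <- M[j, ]
    }
  }
  out
}

view_invariance_rows <- function(M, stimInfo) {
  check_complete_grid(stimInfo)
  key <- paste(stimInfo$pose_id, stimInfo$elevation, stimInfo$azimuth)
  ref <- match(paste(stimInfo$pose_id, stimInfo$elevation, 0), key)
  M[ref, , drop = FALSE]
}

#' Equate mirror-symmetric viewpoints of a data matrix
#'
#' Produces the view-flipped (VF) variant: for each pose and camera
#' elevation, the rows of the azimuths beyond 180 degrees are replaced by
#' (copied from, not mirrored) the rows of their mirror azimuths
#' (315 <- 45, 270 <- 90, 225 <- 135 on the standard grid); 0- and 180-degree
#' rows are untouched. `direction = "early_from_late"` applies the reverse
#' replacement (the control construction).
#'
#' @param kpMatrix a base (non-VF, non-VI) [KeypointMatrix-class] with a
#'   complete azimuth grid.
#' @param direction replacement direction (default `"late_from_early"`).
#' @return A [KeypointMatrix-class] with variant `2D_VF` or `3D_VF`.
#' @export
applyViewFlip <- function(kpMatrix, direction = c("late_from_early",
                                                  "early_from_late")) {
  direction <- match.arg(direction)
  stopifnot(methods::is(kpMatrix, "KeypointMatrix"))
  if (kpMatrix@variant %in% c("3D_VI")) {
    stop("invalid-argument: view flip requires a base or VF variant")
  }
  X <- view_flip_rows(kpMatrix@X, kpMatrix@stimInfo, direction)
  methods::new("KeypointMatrix", X = X,
               variant = if (kpMatrix@columnLayout == "xyz") "3D_VF"
                         else "2D_VF",
               columnLayout = kpMatrix@columnLayout,
               stimInfo = kpMatrix@stimInfo, imageSize = kpMatrix@imageSize)
}

#' Equate all viewpoints of a data matrix to the frontal view
#'
#' Produces the view-invariant (VI) variant: for each pose and camera
#' elevation, all azimuth rows are replaced by that group's 0-degree row.
#'
#' @param kpMatrix a base 3D [KeypointMatrix-class] with a complete azimuth
#'   grid.
#' @return A [KeypointMatrix-class] with variant `3D_VI`.
#' @export
applyViewInvariance <- function(kpMatrix) {
  stopifnot(methods::is(kpMatrix, "KeypointMatrix"))
  if (kpMatrix@columnLayout != "xyz") {
    stop("invalid-argument: the view-invariant variant is defined for 3D matrices")
  }
  X <- view_invariance_rows(kpMatrix@X, kpMatrix@stimInfo)
  methods::new("KeypointMatrix", X = X, variant = "3D_VI",
               columnLayout = "xyz", stimInfo = kpMatrix@stimInfo,
               imageSize = kpMatrix@imageSize)
}

#' Vectorize silhouettes into a pixel data matrix
#'
#' @param silhouettes a [SilhouetteStack-class].
#' @return A numeric matrix, stimuli x grid^2, one vectorized image per row.
#' @export
buildPixelMatrix <- function(silhouettes) {
  stopifnot(methods::is(silhouettes, "SilhouetteStack"))
  s <- silhouettes@silhouettes
  n <- dim(s)[1]
  matrix(s, n, dim(s)[2] * dim(s)[3])
}

#' Fit a principal-component basis
#'
#' Columns of `X` are centered (demeaned, never rescaled) and a PCA is
#' applied. The sign of each component is fixed deterministically by making
#' its largest-magnitude loading positive. If the matrix rank falls below
#' `nComponents`, the available components are returned with a warning.
#'
#' @param X a numeric matrix or a [KeypointMatrix-class].
#' @param nComponents number of components to keep (default 10, the standard
#'   choice for keypoint matrices; feature banks typically use 50).
#' @return A [PCBasis-class].
#' @export
fitPCA <- function(X, nComponents = 10) {
  if (methods::is(X, "KeypointMatrix")) X <- X@X
  X <- as.matrix(X)
  if (nComponents > min(nrow(X) - 1, ncol(X))) {
    stop("invalid-argument: nComponents must be <= min(rows - 1, cols)")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-10 * pc$sdev[1])
  K <- as.integer(min(nComponents, rank))
  if (K < nComponents) {
    warning(sprintf("reduced-rank: only %d components available", K))
  }
  P <- pc$rotation[, seq_len(K), drop = FALSE]
  flip <- vapply(seq_len(K), function(j) {
    sign(P[which.max(abs(P[, j])), j])
  }, numeric(1))
  P <- sweep(P, 2, flip, `*`)
  methods::new("PCBasis",
    center = as.numeric(pc$center),
    components = unname(P),
    sds = pc$sdev[seq_len(K)],
    explainedVarianceRatio = pc$sdev[seq_len(K)]^2 / sum(pc$sdev^2),
    K = K)
}

#' Project stimuli into a PC basis
#'
#' @param basis a [PCBasis-class].
#' @param X a numeric matrix or [KeypointMatrix-class] with the basis's
#'   column dimension.
#' @return The score matrix `Z = (X - center) P`, stimuli x K.
#' @export
projectScores <- function(basis, X) {
  stopifnot(methods::is(basis, "PCBasis"))
  if (methods::is(X, "KeypointMatrix")) X <- X@X
  X <- as.matrix(X)
  if (ncol(X) != length(basis@center)) {
    stop("invalid-argument: column dimension does not match the basis")
  }
  sweep(X, 2, basis@center) %*% basis@components
}

#' Reconstruct stimuli from PC scores
#'
#' @param basis a [PCBasis-class].
#' @param Z a score matrix (stimuli x K).
#' @return The reconstruction `Z P' + center`.
#' @export
reconstructFromScores <- function(basis, Z) {
  stopifnot(methods::is(basis, "PCBasis"))
  sweep(as.matrix(Z) %*% t(basis@components), 2, basis@center, `+`)
}

#' Equate PC scores across mirrored or all viewpoints
#'
#' The complementary construction of the view-flipped / view-invariant
#' models: instead of flipping keypoint coordinates before the PCA, the PCA
#' of the base (view-dependent) matrix is kept and the PC-score rows of
#' mirrored views (type `"flip"`) or of all views (type `"invariance"`) are
#' equated before the regression.
#'
#' Row replacement shifts the column means away from zero, so the result is
#' re-centered by default: the downstream regression carries no intercept and
#' expects centered predictors, exactly as PCA scores are centered by
#' construction in the first approach.
#'
#' @param Z a score matrix (stimuli x K).
#' @param stimInfo stimulus table aligned with the rows of `Z`.
#' @param type `"flip"` or `"invariance"`.
#' @param direction replacement direction for `"flip"` (see
#'   [applyViewFlip()]).
#' @param recenter demean the columns after equating (default `TRUE`).
#' @return The score matrix with equated rows.
#' @export
equateViewScores <- function(Z, stimInfo, type = c("flip", "invariance"),
                             direction = c("late_from_early",
                                           "early_from_late"),
                             recenter = TRUE) {
  type <- match.arg(type)
  direction <- match.arg(direction)
  Z <- as.matrix(Z)
  if (nrow(Z) != nrow(stimInfo)) {
    stop("invalid-argument: Z rows must match stimInfo rows")
  }
  out <- if (type == "flip") view_flip_rows(Z, stimInfo, direction)
         else view_invariance_rows(Z, stimInfo)
  if (recenter) out <- scale(out, scale = FALSE)
  out[, , drop = FALSE]
}
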