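# Inversion of fitted encoding models: eigenposes, the preferred-axis
# keypoint transform, per-keypoint weights with permutation significance,
# and poses along the preferred axis.

reshape_pose <- function(vec, nKeypoints = 22) {
  ncoord <- length(vec) / nKeypoints
  if (!ncoord %in% c(2, 3)) {
    stop("invalid-argument: not a keypoint-space vector (expected 22 x 2 or 22 x 3)")
  }
  m <- matrix(vec, nKeypoints, ncoord, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")[seq_len(ncoord)]
  m
}

#' Eigenpose along one principal component
#'
#' The keypoint configuration `kappa` standard deviations along component
#' `i` from the mean pose: `e = center + kappa * sd_i * p_i`, reshaped to a
#' keypoints x coordinates matrix.
#'
#' @param basis a [PCBasis-class] fitted on a keypoint matrix.
#' @param i component index (1..K).
#' @param kappa standard-deviation step (0 returns the mean pose).
#' @param nKeypoints number of keypoints (default 22).
#' @return A `nKeypoints x 2` (or `x 3`) matrix.
#' @export
eigenpose <- function(basis, i, kappa, nKeypoints = 22) {
  stopifnot(methods::is(basis, "PCBasis"))
  if (i < 1 || i > basis@K) stop("invalid-argument: component index out of range")
  reshape_pose(basis@center + kappa * basis@sds[i] * basis@components[, i],
               nKeypoints)
}

#' Transform a preferred axis to keypoint space
#'
#' `t = P beta` (the coefficient-weighted sum of components), reshaped to a
#' keypoints x coordinates matrix whose row norms are the per-keypoint
#' contribution weights.
#'
#' @param basis a [PCBasis-class].
#' @param beta coefficient vector of length K (e.g.
#'   [preferredAxis()] of an [EncodingFit-class]).
#' @param nKeypoints number of keypoints (default 22).
#' @return A `nKeypoints x 2` (or `x 3`) matrix `T`.
#' @export
axisToKeypoints <- function(basis, beta, nKeypoints = 22) {
  stopifnot(methods::is(basis, "PCBasis"))
  if (length(beta) != basis@K) {
    stop("invalid-argument: beta length must equal the basis K")
  }
  reshape_pose(drop(basis@components %*% beta), nKeypoints)
}

#' Per-keypoint contribution weights
#'
#' The magnitude of each keypoint's row of the transformed axis `T`:
#' `w_i = sqrt(t_x^2 + t_y^2 (+ t_z^2))`.
#'
#' @param T a keypoints x coordinates matrix (see [axisToKeypoints()]).
#' @return Nonnegative weights, one per keypoint.
#' @export
keypointWeights <- function(T) {
  sqrt(rowSums(as.matrix(T)^2))
}

#' Pose at kappa standard deviations along a preferred axis
#'
#' `a_kappa = center + sum_i b_i kappa sd_i p_i` with `b_i = sd_i beta_i`
#' (the coefficients rescaled from score space to standard-deviation units).
#'
#' @param basis a [PCBasis-class].
#' @param beta coefficient vector of length K.
#' @param kappa standard-deviation step (0 returns the mean pose).
#' @param nKeypoints number of keypoints (default 22).
#' @return A `nKeypoints x 2` (or `x 3`) matrix.
#' @export
poseAlongAxis <- function(basis, beta, kappa, nKeypoints = 22) {
  stopifnot(methods::is(basis, "PCBasis"))
  vec <- basis@center +
    kappa * drop(basis@components %*% (basis@sds^2 * beta))
  reshape_pose(vec, nKeypoints)
}

#' Permutation significance of keypoint weights
#'
#' Permutes the stimulus labels of the response, refits the model per
#' permutation (full cross-validated refit by default; a cheaper full-data
#' fit via `refit = "full"`), and recomputes the keypoint weights. The
#' one-sided p-value of each keypoint is the fraction of null weights at or
#' above the observed weight; Benjamini-Hochberg FDR correction is applied
#' across the keypoints. Non-significant weights are reported as 0 in the
#' display column, and display weights are max-normalized after zeroing.
#'
#' @param scores stimuli x K PC-score matrix.
#' @param y stimulus-mean responses.
#' @param basis the [PCBasis-class] behind the scores.
#' @param nPerm number of permutations (default 1000).
#' @param alpha FDR level (default 0.05).
#' @param seed RNG seed.
#' @param nFolds CV folds for the refits (default 10).
#' @param refit `"cv"` (default) or `"full"` (single full-data fit per
#'   permutation).
#' @param nKeypoints number of keypoints (default 22).
#' @return A data.frame with one row per keypoint: observed `weight`,
#'   permutation `p`, `significant` flag and max-normalized
#'   `display_weight` (zeroed when not significant).
#' @export
weightSignificance <- function(scores, y, basis, nPerm = 1000, alpha = 0.05,
                               seed = 1, nFolds = 10,
                               refit = c("cv", "full"), nKeypoints = 22) {
  refit <- match.arg(refit)
  if (nPerm < 20) warning("p-value resolution is coarse below 20 permutations")
  Z <- as.matrix(scores)
  n <- length(y)
  y <- (y - mean(y)) / stats::sd(y)
  folds <- make_folds(n, nFolds, seed)

  fit_beta <- function(yy) {
    if (refit == "cv") {
      rowMeans(pcr_cv_core(Z, yy, folds, nFolds)$betas)
    } else {
      solve_normal(Z, yy)
    }
  }
  obs_w <- keypointWeights(axisToKeypoints(basis, fit_beta(y), nKeypoints))

  null_w <- with_rng(child_seed(seed, 29), {
    vapply(seq_len(nPerm), function(p) {
      perm <- if (nPerm == 1) seq_len(n) else sample.int(n)
      keypointWeights(axisToKeypoints(basis, fit_beta(y[perm]), nKeypoints))
    }, numeric(nKeypoints))
  })
  null_w <- matrix(null_w, nKeypoints, nPerm)

  pvals <- rowMeans(null_w >= obs_w)
  sig <- stats::p.adjust(pvals, method = "BH") <= alpha
  disp <- obs_w * sig
  if (max(disp) > 0) disp <- disp / max(disp)
  data.frame(keypoint = seq_len(nKeypoints), weight = obs_w, p = pvals,
             significant = sig, display_weight = disp)
}

#' Full inversion of a fitted encoding model
#'
#' Bundles the keypoint transform of the preferred axis, the contribution
#' weights (optionally with permutation significance) and the poses along
#' the axis at a grid of standard-deviation steps into an
#' [AxisVisualization-class].
#'
#' @param basis a [PCBasis-class].
#' @param fit an [EncodingFit-class].
#' @param kappaGrid standard-deviation steps (default -3..3).
#' @param significance optional result of [weightSignificance()] for this
#'   unit.
#' @param nKeypoints number of keypoints (default 22).
#' @return An [AxisVisualization-class].
#' @export
visualizePreferredAxis <- function(basis, fit, kappaGrid = -3:3,
                                   significance = NULL, nKeypoints = 22) {
  stopifnot(methods::is(fit, "EncodingFit"))
  beta <- fit@beta
  T <- axisToKeypoints(basis, beta, nKeypoints)
  w <- keypointWeights(T)
  if (is.null(significance)) {
    sig <- rep(NA, nKeypoints)
    pv <- rep(NA_real_, nKeypoints)
    disp <- if (max(w) > 0) w / max(w) else w
  } else {
    sig <- significance$significant
    pv <- significance$p
    disp <- significance$display_weight
  }
  poses <- lapply(kappaGrid, function(k) {
    poseAlongAxis(basis, beta, k, nKeypoints)
  })
  names(poses) <- paste0("kappa_", kappaGrid)
  methods::new("AxisVisualization", unitId = fit@unitId, T = T, weights = w,
               displayWeights = disp, significant = as.logical(sig),
               pvalues = pv, poses = poses, kappa = as.numeric(kappaGrid),
               b = basis@sds * beta)
}
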