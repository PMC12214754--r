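#' Generate a synthetic pose stimulus grid
#'
#' Builds an articulated 22-keypoint skeleton, draws joint angles for
#' `nPoses` poses from class-specific distributions (up to 9 classes with an
#' equal number of exemplars each), and renders every pose at
#' `nViews` viewpoints: `nViews / 2` azimuths in equal steps starting at 0
#' degrees, each at camera elevations of 0 and 45 degrees. Projection is
#' orthographic, aimed at the pelvis. One designated "hanging" pose class is
#' rendered with the camera displaced downward and looking up by the same
#' tilt. A single global scale maps the maximum horizontal/vertical extent
#' across all stimuli to `imageSize` pixels.
#'
#' @param nPoses number of distinct poses (default 45).
#' @param nViews number of viewpoints per pose; must be even (default 16:
#'   8 azimuths x 2 elevations).
#' @param seed integer RNG seed.
#' @param imageSize image side length in pixels (default 350).
#' @return A [PoseSet-class] with `nPoses * nViews` stimuli.
#' @examples
#' ps <- generatePoseSet(nPoses = 6, nViews = 16, seed = 1)
#' nrow(stimulusInfo(ps))
#' @export
generatePoseSet <- function(nPoses = 45, nViews = 16, seed = 1,
                            imageSize = 350) {
  if (nPoses < 1) stop("invalid-argument: nPoses must be >= 1")
  if (nViews < 2 || nViews %% 2 != 0) {
    stop("invalid-argument: nViews must be a positive multiple of 2")
  }
  nAz <- nViews %/% 2L
  azimuths <- seq(0, 360, length.out = nAz + 1)[seq_len(nAz)]
  if (!all(azimuths %in% seq(0, 315, by = 45))) {
    stop("invalid-argument: nViews must place azimuths on the 45-degree grid")
  }
  elevations <- c(0, 45)

  drawn <- with_rng(seed, sample_pose_angles(nPoses))
  poses3d <- lapply(drawn$angles, kp_forward)

  n_stim <- nPoses * nViews
  raw <- array(NA_real_, dim = c(length(kp_labels), 3, n_stim))
  info <- data.frame(
    stimulus_index = seq_len(n_stim),
    pose_id = integer(n_stim), pose_class = integer(n_stim),
    azimuth = numeric(n_stim), elevation = numeric(n_stim)
  )
  i <- 0L
  for (p in seq_len(nPoses)) {
    hanging <- drawn$pose_class[p] == drawn$hanging_class
    for (el in elevations) {
      for (az in azimuths) {
        i <- i + 1L
        raw[, , i] <- project_pose(poses3d[[p]], az, el,
                                   hanging = hanging && el != 0)
        info$pose_id[i] <- p
        info$pose_class[i] <- drawn$pose_class[p]
        info$azimuth[i] <- az
        info$elevation[i] <- el
      }
    }
  }

  m <- max(abs(raw[, 1:2, ]))
  if (!is.finite(m) || m <= 0) {
    stop("generation-failure: degenerate skeleton (all keypoints coincident)")
  }
  scale <- imageSize / (2 * m)
  coords <- raw * scale
  coords[, 1, ] <- coords[, 1, ] + imageSize / 2
  coords[, 2, ] <- coords[, 2, ] + imageSize / 2
  coords[, 3, ] <- coords[, 3, ] + imageSize / 2
  dimnames(coords) <- list(kp_labels, c("x", "y", "z"), NULL)

  methods::new("PoseSet", coords = coords, stimInfo = info,
               keypointLabels = kp_labels, bones = kp_bones(),
               imageSize = imageSize, globalScale = scale)
}

# Rasterize skeleton bones as thick segments on a full-resolution canvas,
# then block-max downsample to grid x grid. Exposed internally so tests can
# rasterize arbitrary 2D keypoints.
rasterize_bones <- function(xy, bones, imageSize, grid,
                            thickness = max(3, imageSize / 70)) {
  canvas <- matrix(0L, imageSize, imageSize) # [row = y, col = x]
  r <- thickness / 2
  for (b in seq_len(nrow(bones))) {
    p1 <- xy[bones[b, 1], ]
    p2 <- xy[bones[b, 2], ]
    xr <- range(p1[1], p2[1])
    yr <- range(p1[2], p2[2])
    xs <- seq(max(1, floor(xr[1] - r)), min(imageSize, ceiling(xr[2] + r)))
    ys <- seq(max(1, floor(yr[1] - r)), min(imageSize, ceiling(yr[2] + r)))
    if (!length(xs) || !length(ys) ||
        xr[2] < 1 - r || xr[1] > imageSize + r ||
        yr[2] < 1 - r || yr[1] > imageSize + r) next
    px <- rep(xs, each = length(ys))
    py <- rep(ys, times = length(xs))
    v <- p2 - p1
    len2 <- sum(v^2)
    if (len2 < 1e-12) {
      d2 <- (px - p1[1])^2 + (py - p1[2])^2
    } else {
      t <- pmin(1, pmax(0, ((px - p1[1]) * v[1] + (py - p1[2]) * v[2]) / len2))
      d2 <- (px - (p1[1] + t * v[1]))^2 + (py - (p1[2] + t * v[2]))^2
    }
    hit <- d2 <= r^2
    if (any(hit)) canvas[cbind(py[hit], px[hit])] <- 1L
  }
  # block-max downsample
  row_cell <- ceiling(seq_len(imageSize) * grid / imageSize)
  col_cell <- row_cell
  out <- matrix(0, grid, grid)
  nz <- which(canvas == 1L, arr.ind = TRUE)
  if (nrow(nz)) {
    cells <- unique(cbind(row_cell[nz[, 1]], col_cell[nz[, 2]]))
    out[cells] <- 1
  }
  out
}

#' Render binary silhouettes of a pose set
#'
#' Draws each stimulus by rasterizing the skeleton bones as thick line
#' segments on the full-resolution canvas and downsampling by block maximum
#' to a `grid x grid` binary image.
#'
#' @param poseSet a [PoseSet-class].
#' @param grid output image side length (default 25, minimum 8).
#' @return A [SilhouetteStack-class] (`n_stimuli x grid x grid`, values 0/1).
#' @export
renderSilhouettes <- function(poseSet, grid = 25) {
  if (grid < 8) stop("invalid-argument: grid must be >= 8")
  stopifnot(methods::is(poseSet, "PoseSet"))
  n <- dim(poseSet@coords)[3]
  sil <- array(0, dim = c(n, grid, grid))
  for (i in seq_len(n)) {
    sil[i, , ] <- rasterize_bones(poseSet@coords[, 1:2, i], poseSet@bones,
                                  poseSet@imageSize, grid)
  }
  methods::new("SilhouetteStack", silhouettes = sil, grid = as.integer(grid),
               stimInfo = poseSet@stimInfo)
}

# Simulate trial rates for given per-stimulus mean rates.
sim_trials <- function(meanRates, nTrials, noise, windowS, gaussianSd) {
  nStim <- length(meanRates)
  switch(noise,
    poisson = matrix(
      stats::rpois(nTrials * nStim, rep(meanRates * windowS, each = nTrials)) /
        windowS,
      nTrials, nStim),
    gaussian = pmax(matrix(
      stats::rnorm(nTrials * nStim, rep(meanRates, each = nTrials),
                   gaussianSd),
      nTrials, nStim), 0),
    none = matrix(rep(meanRates, each = nTrials), nTrials, nStim)
  )
}

#' Simulate spiking units tuned along axes in keypoint-PC space
#'
#' Each simulated unit carries a ground-truth axis `beta_true` drawn uniformly
#' on the unit sphere in the PC space of the supplied basis. Its mean response
#' to stimulus `s` is `max(0, baseline + gain * z_s' beta_true)` where `z_s`
#' are the stimulus PC scores; trials are drawn from the chosen noise model
#' (default: Poisson spike counts over the response window, converted to
#' rates). When `targetReliability` is given, `gain` is calibrated by
#' bisection so the median simulated Spearman-Brown split-half reliability
#' falls within 0.05 of the target.
#'
#' @param basis a [PCBasis-class] fitted on the generative variant's data
#'   matrix.
#' @param keypointMatrix the [KeypointMatrix-class] the basis was fitted on
#'   (source of the PC scores and of the generative variant label).
#' @param nUnits number of units to simulate.
#' @param targetReliability desired median split-half reliability in (0, 1),
#'   or `NULL` to use `gain` as given.
#' @param nTrials trials per stimulus (default 8).
#' @param gain spikes/s per unit PC score; ignored when `targetReliability`
#'   is given (default 5).
#' @param baseline baseline firing rate, spikes/s (default 10).
#' @param noise `"poisson"` (default), `"gaussian"` or `"none"`.
#' @param gaussianSd trial standard deviation for Gaussian noise, spikes/s.
#' @param windowS response-window length in seconds (default 0.2).
#' @param seed integer RNG seed.
#' @param nCalibrationSplits split-half splits used inside the calibration
#'   loop (default 20).
#' @return A list of [UnitRecording-class] objects; ground truth (variant,
#'   `beta_true`, gain, baseline, noise model, seed) is stored in each
#'   unit's `groundTruth` slot.
#' @export
simulateEncodingUnits <- function(basis, keypointMatrix, nUnits,
                                  targetReliability = NULL, nTrials = 8,
                                  gain = 5, baseline = 10,
                                  noise = c("poisson", "gaussian", "none"),
                                  gaussianSd = 2, windowS = 0.2, seed = 1,
                                  nCalibrationSplits = 20) {
  noise <- match.arg(noise)
  if (baseline < 0) stop("invalid-argument: baseline must be >= 0")
  if (!is.null(targetReliability) &&
      (targetReliability <= 0 || targetReliability >= 1)) {
    stop("invalid-argument: targetReliability must lie in (0, 1)")
  }
  Z <- projectScores(basis, keypointMatrix)
  K <- ncol(Z)
  variant <- if (methods::is(keypointMatrix, "KeypointMatrix")) {
    keypointMatrix@variant
  } else "custom"

  betas <- with_rng(child_seed(seed, 1), {
    B <- matrix(stats::rnorm(nUnits * K), nUnits, K)
    B / sqrt(rowSums(B^2))
  })
  drive <- Z %*% t(betas) # nStim x nUnits

  median_rel <- function(g, sim_seed) {
    rates <- pmax(baseline + g * drive, 0)
    rel <- with_rng(sim_seed, {
      vapply(seq_len(nUnits), function(u) {
        tr <- sim_trials(rates[, u], nTrials, noise, windowS, gaussianSd)
        splitHalfReliability(tr, nSplits = nCalibrationSplits,
                             seed = child_seed(sim_seed, u))
      }, numeric(1))
    })
    stats::median(rel)
  }

  if (!is.null(targetReliability)) {
    if (noise == "none") {
      stop("invalid-argument: cannot calibrate reliability for noise-free trials")
    }
    cal_seed <- child_seed(seed, 2)
    lo <- 0
    hi <- baseline + 1
    it <- 0L
    while (median_rel(hi, cal_seed) < targetReliability) {
      hi <- hi * 2
      it <- it + 1L
      if (it > 40L) {
        stop(sprintf(
          "calibration-failure: cannot bracket target %.2f (reached gain %.1f, median reliability %.3f)",
          targetReliability, hi, median_rel(hi, cal_seed)))
      }
    }
    for (i in seq_len(30)) {
      mid <- (lo + hi) / 2
      r <- median_rel(mid, cal_seed)
      if (abs(r - targetReliability) <= 0.01) {
        lo <- hi <- mid
        break
      }
      if (r < targetReliability) lo <- mid else hi <- mid
    }
    gain <- (lo + hi) / 2
  }

  meanRates <- pmax(baseline + gain * drive, 0)
  units <- with_rng(child_seed(seed, 3), {
    lapply(seq_len(nUnits), function(u) {
      resp <- sim_trials(meanRates[, u], nTrials, noise, windowS, gaussianSd)
      base <- sim_trials(rep(baseline, nrow(Z)), nTrials, noise, windowS,
                         gaussianSd)
      methods::new("UnitRecording",
        unitId = sprintf("sim_%s_%03d", variant, u),
        responseRates = resp, baselineRates = base, categoryRates = NULL,
        groundTruth = list(variant = variant, beta_true = betas[u, ],
                           gain = gain, baseline = baseline, noise = noise,
                           windowS = windowS, seed = seed))
    })
  })
  units
}

#' Simulate the body/face/object category test of one unit
#'
#' 20 body, 20 face and 20 object stimuli with constant mean net rates
#' (`bodyGain` above baseline for bodies, `nonbodyGain` for faces and
#' objects) and Poisson trial noise. Feeds [computeBsi()].
#'
#' @param bodyGain mean net response to body stimuli, spikes/s (>= 0).
#' @param nonbodyGain mean net response to face and object stimuli, spikes/s.
#' @param nTrials trials per stimulus (default 5).
#' @param baseline baseline rate, spikes/s.
#' @param noise `"poisson"` (default) or `"none"`.
#' @param windowS response-window length in seconds (default 1).
#' @param seed integer RNG seed.
#' @return A [CategoryRates-class].
#' @export
simulateCategoryResponses <- function(bodyGain, nonbodyGain, nTrials = 5,
                                      baseline = 10,
                                      noise = c("poisson", "none"),
                                      windowS = 1, seed = 1) {
  noise <- match.arg(noise)
  if (bodyGain < 0 || nonbodyGain < 0) {
    stop("invalid-argument: gains must be >= 0")
  }
  category <- rep(c("body", "face", "object"), each = 20)
  means <- baseline + ifelse(category == "body", bodyGain, nonbodyGain)
  with_rng(seed, {
    resp <- sim_trials(means, nTrials, noise, windowS, gaussianSd = 0)
    base <- sim_trials(rep(baseline, 60), nTrials, noise, windowS,
                       gaussianSd = 0)
    methods::new("CategoryRates", response = resp, baseline = base,
                 category = category)
  })
}

#' Surrogate feature bank from silhouettes or keypoints
#'
#' Seeded random projections of silhouette pixels (or keypoint coordinates)
#' passed through a pointwise nonlinearity. The result has the same matrix
#' interface as any other feature bank, so principal-component regression and
#' variance partitioning run on it unchanged.
#'
#' @param x a [SilhouetteStack-class], a [KeypointMatrix-class] or a plain
#'   stimuli-by-features matrix.
#' @param nFeatures number of output features (>= 1).
#' @param nonlinearity `"relu"` (default), `"identity"`, `"tanh"` or
#'   `"square"`.
#' @param projection `"gaussian"` (default) or `"identity"` (requires
#'   `nFeatures` equal to the input width).
#' @param seed integer RNG seed.
#' @return A numeric matrix, stimuli x `nFeatures`.
#' @export
surrogateFeatureMatrix <- function(x, nFeatures,
                                   nonlinearity = c("relu", "identity",
                                                    "tanh", "square"),
                                   projection = c("gaussian", "identity"),
                                   seed = 1) {
  nonlinearity <- match.arg(nonlinearity)
  projection <- match.arg(projection)
  if (nFeatures < 1) stop("invalid-argument: nFeatures must be >= 1")
  X <- if (methods::is(x, "SilhouetteStack")) {
    buildPixelMatrix(x)
  } else if (methods::is(x, "KeypointMatrix")) {
    x@X
  } else {
    as.matrix(x)
  }
  H <- if (projection == "identity") {
    if (nFeatures != ncol(X)) {
      stop("invalid-argument: identity projection requires nFeatures == input width")
    }
    X
  } else {
    W <- with_rng(seed, matrix(stats::rnorm(ncol(X) * nFeatures,
                                            sd = 1 / sqrt(ncol(X))),
                               ncol(X), nFeatures))
    X %*% W
  }
  switch(nonlinearity,
    relu = pmax(H, 0),
    identity = H,
    tanh = tanh(H),
    square = H^2
  )
}
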