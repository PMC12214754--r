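#' @import methods
NULL

# ---------------------------------------------------------------------------
# Stimuli

#' PoseSet: a grid of rendered keypoint skeletons
#'
#' Holds the full stimulus grid of an experiment: every pose rendered at every
#' (azimuth, elevation) viewpoint, as camera-aligned keypoint coordinates in
#' pixels. `x` and `y` are image-plane coordinates (origin top-left, `y`
#' increasing downward); `z` is the signed distance from the frontal plane,
#' expressed in the same pixel units and offset to the image center.
#'
#' @slot coords numeric array `n_keypoints x 3 x n_stimuli` (x, y, z in pixels).
#' @slot stimInfo data.frame with one row per stimulus: `stimulus_index`,
#'   `pose_id`, `pose_class`, `azimuth`, `elevation`.
#' @slot keypointLabels character vector of keypoint names.
#' @slot bones integer matrix (bones x 2) of keypoint indices (kinematic tree).
#' @slot imageSize image side length in pixels.
#' @slot globalScale pixels per model unit, shared by the whole set.
#'
#' @export
setClass("PoseSet",
  representation(
    coords = "array",
    stimInfo = "data.frame",
    keypointLabels = "character",
    bones = "matrix",
    imageSize = "numeric",
    globalScale = "numeric"
  )
)

setValidity("PoseSet", function(object) {
  msg <- character()
  nk <- length(object@keypointLabels)
  d <- dim(object@coords)
  if (length(d) != 3 || d[1] != nk || d[2] != 3) {
    msg <- c(msg, "coords must be n_keypoints x 3 x n_stimuli")
  }
  if (nrow(object@stimInfo) != d[3]) {
    msg <- c(msg, "stimInfo rows must match number of stimuli")
  }
  key <- with(object@stimInfo, paste(pose_id, azimuth, elevation))
  if (anyDuplicated(key)) {
    msg <- c(msg, "(pose_id, azimuth, elevation) combinations must be unique")
  }
  if (!all(object@stimInfo$elevation %in% c(0, 45))) {
    msg <- c(msg, "elevation must be 0 or 45 degrees")
  }
  if (!all(object@stimInfo$azimuth %in% seq(0, 315, by = 45))) {
    msg <- c(msg, "azimuth must lie on the 45-degree grid [0, 315]")
  }
  if (!all(is.finite(object@coords))) {
    msg <- c(msg, "all coordinates must be finite")
  } else {
    xy <- object@coords[, 1:2, , drop = FALSE]
    if (min(xy) < -1e-8 || max(xy) > object@imageSize + 1e-8) {
      msg <- c(msg, "x and y must lie within [0, imageSize]")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PoseSet", function(object) {
  si <- object@stimInfo
  cat("PoseSet:", nrow(si), "stimuli (",
      length(unique(si$pose_id)), "poses x",
      length(unique(paste(si$azimuth, si$elevation))), "views ),",
      length(object@keypointLabels), "keypoints,",
      "image", object@imageSize, "px\n")
})

#' SilhouetteStack: binary silhouette images of a PoseSet
#'
#' @slot silhouettes numeric array `n_stimuli x grid x grid` with values in
#'   \{0, 1\}; first image dimension is `y` (top-left origin).
#' @slot grid side length of the downsampled image, pixels.
#' @slot stimInfo stimulus table copied from the source [PoseSet-class].
#' @export
setClass("SilhouetteStack",
  representation(silhouettes = "array", grid = "integer",
                 stimInfo = "data.frame")
)

setValidity("SilhouetteStack", function(object) {
  d <- dim(object@silhouettes)
  if (length(d) != 3 || d[2] != object@grid || d[3] != object@grid) {
    return("silhouettes must be n_stimuli x grid x grid")
  }
  if (!all(object@silhouettes %in% c(0, 1))) {
    return("silhouette values must be 0 or 1")
  }
  TRUE
})

setMethod("show", "SilhouetteStack", function(object) {
  cat("SilhouetteStack:", dim(object@silhouettes)[1], "images of",
      object@grid, "x", object@grid, "pixels\n")
})

# ---------------------------------------------------------------------------
# Feature matrices

#' KeypointMatrix: a stimuli-by-coordinates data matrix
#'
#' The regression design matrix of one model variant. Coordinates are divided
#' by the image size, so entries are unitless. Variants: `2D` (x, y columns),
#' `3D_VD` (view-dependent x, y, z), `2D_VF`/`3D_VF` (view-flipped: rows of
#' mirror-symmetric azimuths equated) and `3D_VI` (view-invariant: all
#' azimuths of a pose share the 0-degree row).
#'
#' @slot X numeric matrix, stimuli x coordinate columns.
#' @slot variant one of `"2D"`, `"3D_VD"`, `"2D_VF"`, `"3D_VF"`, `"3D_VI"`.
#' @slot columnLayout `"xy"` or `"xyz"` (keypoint-interleaved columns).
#' @slot stimInfo stimulus table aligned with the rows of `X`.
#' @slot imageSize the divisor used for scaling, pixels.
#' @export
setClass("KeypointMatrix",
  representation(X = "matrix", variant = "character",
                 columnLayout = "character", stimInfo = "data.frame",
                 imageSize = "numeric")
)

setValidity("KeypointMatrix", function(object) {
  msg <- character()
  ncoord <- switch(object@columnLayout, xy = 2L, xyz = 3L, NA_integer_)
  if (is.na(ncoord)) msg <- c(msg, "columnLayout must be 'xy' or 'xyz'")
  if (!object@variant %in% c("2D", "3D_VD", "2D_VF", "3D_VF", "3D_VI")) {
    msg <- c(msg, "unknown variant")
  }
  if (nrow(object@X) != nrow(object@stimInfo)) {
    msg <- c(msg, "X rows must match stimInfo rows")
  }
  if (!is.na(ncoord) && ncol(object@X) %% ncoord != 0) {
    msg <- c(msg, "column count incompatible with layout")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "KeypointMatrix", function(object) {
  cat("KeypointMatrix (", object@variant, "): ",
      nrow(object@X), " x ", ncol(object@X),
      ", layout ", object@columnLayout, "\n", sep = "")
})

#' PCBasis: a principal-component basis of a data matrix
#'
#' @slot center column means of the source matrix (the mean pose for keypoint
#'   matrices).
#' @slot components d x K matrix of orthonormal loadings.
#' @slot sds standard deviations of the scores along each component.
#' @slot explainedVarianceRatio fraction of total variance per kept component.
#' @slot K number of components kept.
#' @export
setClass("PCBasis",
  representation(center = "numeric", components = "matrix", sds = "numeric",
                 explainedVarianceRatio = "numeric", K = "integer")
)

setValidity("PCBasis", function(object) {
  msg <- character()
  P <- object@components
  if (ncol(P) != object@K) msg <- c(msg, "K must equal ncol(components)")
  if (length(object@center) != nrow(P)) {
    msg <- c(msg, "center length must equal nrow(components)")
  }
  G <- crossprod(P)
  if (max(abs(G - diag(ncol(P)))) > 1e-10) {
    msg <- c(msg, "components must be orthonormal (1e-10)")
  }
  if (is.unsorted(rev(object@sds))) msg <- c(msg, "sds must be non-increasing")
  if (sum(object@explainedVarianceRatio) > 1 + 1e-8) {
    msg <- c(msg, "explained variance ratios must sum to <= 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PCBasis", function(object) {
  cat("PCBasis:", object@K, "components over", nrow(object@components),
      "dimensions;", sprintf("%.1f%%", 100 * sum(object@explainedVarianceRatio)),
      "variance explained\n")
})

# ---------------------------------------------------------------------------
# Recordings

#' CategoryRates: trial rates for the body/face/object category test
#'
#' @slot response trials x 60 response-window rates (spikes/s).
#' @slot baseline trials x 60 baseline-window rates (spikes/s).
#' @slot category character vector of length 60 (`"body"`, `"face"`,
#'   `"object"`; 20 each).
#' @export
setClass("CategoryRates",
  representation(response = "matrix", baseline = "matrix",
                 category = "character")
)

setValidity("CategoryRates", function(object) {
  msg <- character()
  if (ncol(object@response) != length(object@category)) {
    msg <- c(msg, "one category label per stimulus column required")
  }
  if (!identical(dim(object@response), dim(object@baseline))) {
    msg <- c(msg, "response and baseline must have identical shape")
  }
  tab <- table(object@category)
  if (!all(c("body", "face", "object") %in% names(tab)) ||
      length(unique(tab)) != 1) {
    msg <- c(msg, "categories must partition stimuli evenly into body/face/object")
  }
  if (min(object@response) < 0 || min(object@baseline) < 0) {
    msg <- c(msg, "rates must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' UnitRecording: trial-level window rates of one unit
#'
#' @slot unitId unit identifier.
#' @slot responseRates trials x stimuli response-window rates (spikes/s).
#' @slot baselineRates trials x stimuli baseline-window rates (spikes/s).
#' @slot categoryRates a [CategoryRates-class] object or `NULL`.
#' @slot groundTruth list with generative metadata for synthetic units
#'   (variant, `beta_true`, gain, baseline, noise model, seed); empty for
#'   recorded units.
#' @export
setClass("UnitRecording",
  representation(unitId = "character", responseRates = "matrix",
                 baselineRates = "matrix", categoryRates = "ANY",
                 groundTruth = "list")
)

setValidity("UnitRecording", function(object) {
  msg <- character()
  if (!identical(dim(object@responseRates), dim(object@baselineRates))) {
    msg <- c(msg, "response and baseline rate matrices must match in shape")
  }
  if (min(object@responseRates) < 0 || min(object@baselineRates) < 0) {
    msg <- c(msg, "rates must be nonnegative")
  }
  if (!is.null(object@categoryRates) &&
      !methods::is(object@categoryRates, "CategoryRates")) {
    msg <- c(msg, "categoryRates must be a CategoryRates object or NULL")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "UnitRecording", function(object) {
  cat("UnitRecording", object@unitId, ":",
      nrow(object@responseRates), "trials x",
      ncol(object@responseRates), "stimuli",
      if (length(object@groundTruth)) "(synthetic)" else "", "\n")
})

# ---------------------------------------------------------------------------
# Model fits and derived results

#' EncodingFit: a cross-validated principal-component regression fit
#'
#' @slot unitId unit identifier.
#' @slot variant data-matrix variant used as predictors.
#' @slot M number of predictors (principal components).
#' @slot nStimuli number of stimuli N.
#' @slot foldAssignment integer fold label per stimulus.
#' @slot betasByFold M x nFolds matrix of per-fold coefficients.
#' @slot r2ByFold out-of-fold coefficient of determination per fold.
#' @slot beta fold-mean coefficients: the unit's preferred axis.
#' @slot r2 fold-mean cross-validated R^2.
#' @slot r2Adj adjusted R^2 (predictor-count corrected).
#' @slot reliability split-half reliability used for normalization (NA if
#'   none supplied).
#' @slot r2Norm reliability-normalized R^2 (R^2 / reliability).
#' @slot r2AdjNorm reliability-normalized adjusted R^2.
#' @slot seed fold-assignment seed.
#' @export
setClass("EncodingFit",
  representation(unitId = "character", variant = "character", M = "integer",
                 nStimuli = "integer", foldAssignment = "integer",
                 betasByFold = "matrix", r2ByFold = "numeric",
                 beta = "numeric", r2 = "numeric", r2Adj = "numeric",
                 reliability = "numeric", r2Norm = "numeric",
                 r2AdjNorm = "numeric", seed = "integer")
)

setValidity("EncodingFit", function(object) {
  msg <- character()
  if (length(object@beta) != object@M) {
    msg <- c(msg, "beta length must equal M")
  }
  if (nrow(object@betasByFold) != object@M) {
    msg <- c(msg, "betasByFold must be M x nFolds")
  }
  if (length(object@foldAssignment) != object@nStimuli) {
    msg <- c(msg, "one fold label per stimulus required")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EncodingFit", function(object) {
  cat(sprintf(
    "EncodingFit %s [%s]: M = %d, R2 = %.3f, R2adj = %.3f%s\n",
    object@unitId, object@variant, object@M, object@r2, object@r2Adj,
    if (is.finite(object@r2Norm)) sprintf(", R2/rel = %.3f", object@r2Norm)
    else ""
  ))
})

#' NullDistribution: a permutation null of model performance
#'
#' @slot method `"label_shuffle_prefit"`, `"test_label_shuffle"` or
#'   `"beta_permutation"`.
#' @slot values the permuted reliability-normalized R^2 values.
#' @slot percentiles named numeric: 2.5th and 97.5th percentiles.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed.
#' @export
setClass("NullDistribution",
  representation(method = "character", values = "numeric",
                 percentiles = "numeric", nPerm = "integer", seed = "integer")
)

setValidity("NullDistribution", function(object) {
  if (length(object@values) != object@nPerm) {
    return("values must have length nPerm")
  }
  TRUE
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution [%s]: %d permutations, 95%% band [%.3f, %.3f]\n",
              object@method, object@nPerm,
              object@percentiles[1], object@percentiles[2]))
})

#' AxisVisualization: model inversion of a preferred axis
#'
#' @slot unitId unit identifier.
#' @slot T 22 x 2 (or 3) matrix of preferred-axis keypoint components.
#' @slot weights nonnegative per-keypoint contribution magnitudes.
#' @slot displayWeights weights zeroed where non-significant (when a
#'   significance test was run) and max-normalized for display.
#' @slot significant per-keypoint logical (NA when no test was run).
#' @slot pvalues per-keypoint permutation p-values (NA when no test was run).
#' @slot poses named list of 22 x c matrices: poses along the preferred axis
#'   at each kappa step.
#' @slot kappa the standard-deviation steps of `poses`.
#' @slot b per-component scaled coefficients (sds * beta).
#' @export
setClass("AxisVisualization",
  representation(unitId = "character", T = "matrix", weights = "numeric",
                 displayWeights = "numeric", significant = "logical",
                 pvalues = "numeric", poses = "list", kappa = "numeric",
                 b = "numeric")
)

setValidity("AxisVisualization", function(object) {
  msg <- character()
  if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
  w <- sqrt(rowSums(object@T^2))
  if (max(abs(w - object@weights)) > 1e-12) {
    msg <- c(msg, "weights must equal row norms of T (1e-12)")
  }
  if (length(msg)) msg else TRUE
})

#' VIIResult: the view invariance index of one unit
#'
#' @slot unitId unit identifier.
#' @slot modelResponses model response per stimulus (distance along the
#'   preferred axis).
#' @slot bestPose pose id of the maximal model response.
#' @slot bestElevation elevation of the maximal model response.
#' @slot observedRange response range over the 8 views of the best
#'   (pose, elevation).
#' @slot nullRanges ranges of the resampled null draws.
#' @slot nullMean,nullSd moments of the null.
#' @slot zObserved z-score of the observed range in the null.
#' @slot vii the view invariance index (-zObserved).
#' @slot seed RNG seed of the resampling.
#' @export
setClass("VIIResult",
  representation(unitId = "character", modelResponses = "numeric",
                 bestPose = "integer", bestElevation = "numeric",
                 observedRange = "numeric", nullRanges = "numeric",
                 nullMean = "numeric", nullSd = "numeric",
                 zObserved = "numeric", vii = "numeric", seed = "integer")
)

setValidity("VIIResult", function(object) {
  if (object@observedRange < 0) return("observed range must be nonnegative")
  TRUE
})

setMethod("show", "VIIResult", function(object) {
  cat(sprintf("VIIResult %s: best pose %d (elev %g), VII = %.3f\n",
              object@unitId, object@bestPose, object@bestElevation,
              object@vii))
})

#' VariancePartition: unique and shared explained variance of two models
#'
#' @slot unitId unit identifier.
#' @slot bankNames names of the two feature banks (a, b).
#' @slot r2A,r2B,r2Combined cross-validated R^2 of the single and combined
#'   fits.
#' @slot uniqueA,uniqueB,shared partition components; they sum to
#'   `r2Combined` by construction.
#' @export
setClass("VariancePartition",
  representation(unitId = "character", bankNames = "character",
                 r2A = "numeric", r2B = "numeric", r2Combined = "numeric",
                 uniqueA = "numeric", uniqueB = "numeric", shared = "numeric")
)

setValidity("VariancePartition", function(object) {
  if (abs(object@uniqueA + object@uniqueB + object@shared -
          object@r2Combined) > 1e-12) {
    return("partition components must sum to combined R^2 (1e-12)")
  }
  TRUE
})

setMethod("show", "VariancePartition", function(object) {
  cat(sprintf(
    "VariancePartition %s: unique %s = %.3f, unique %s = %.3f, shared = %.3f\n",
    object@unitId, object@bankNames[1], object@uniqueA,
    object@bankNames[2], object@uniqueB, object@shared))
})

#' ClusterResult: HDBSCAN clustering of preferred axes
#'
#' @slot labels integer cluster label per unit; `-1` marks unclustered
#'   ("None") units, `NA` marks units excluded by the R^2 gate.
#' @slot medoids named integer vector: index (into the input units) of each
#'   cluster's medoid.
#' @slot summary per-cluster data.frame (size, medoid, medians and quartiles
#'   of R^2 and VII when supplied).
#' @slot minClusterSize,minSamples HDBSCAN parameters.
#' @export
setClass("ClusterResult",
  representation(labels = "integer", medoids = "integer",
                 summary = "data.frame", minClusterSize = "integer",
                 minSamples = "integer")
)

setMethod("show", "ClusterResult", function(object) {
  k <- sum(unique(object@labels[!is.na(object@labels)]) > 0)
  cat("ClusterResult:", k, "clusters,",
      sum(object@labels == -1, na.rm = TRUE), "noise units,",
      sum(is.na(object@labels)), "gated out\n")
})

#' DecodingResult: pose decoding from pseudo-population responses
#'
#' @slot accuracy mean percent-correct across resamples.
#' @slot accuracySd standard deviation of accuracy across resamples.
#' @slot confusion predicted x true confusion matrix in percent; each column
#'   (true class) sums to 100.
#' @slot nResamples number of pseudo-population resamples.
#' @slot permutationMax maximum mean accuracy over label permutations
#'   (NA when no permutation test was run).
#' @slot classifier `"max_correlation"` or `"linear_svm"`.
#' @slot chanceLevel 100 / number of classes, percent.
#' @slot seed RNG seed.
#' @export
setClass("DecodingResult",
  representation(accuracy = "numeric", accuracySd = "numeric",
                 confusion = "matrix", nResamples = "integer",
                 permutationMax = "numeric", classifier = "character",
                 chanceLevel = "numeric", seed = "integer")
)

setValidity("DecodingResult", function(object) {
  msg <- character()
  if (object@accuracy < 0 || object@accuracy > 100) {
    msg <- c(msg, "accuracy must lie in [0, 100]")
  }
  cs <- colSums(object@confusion)
  if (max(abs(cs - 100)) > 1e-9) {
    msg <- c(msg, "confusion columns must sum to 100 (1e-9)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf(
    "DecodingResult [%s]: %.1f%% correct (sd %.2f, chance %.2f%%, %d resamples)\n",
    object@classifier, object@accuracy, object@accuracySd,
    object@chanceLevel, object@nResamples))
})

# ---------------------------------------------------------------------------
# Accessors

#' Accessors for poseAxes objects
#'
#' Small generic accessors so downstream code never touches slots directly:
#' `dataMatrix()` returns the numeric design matrix of a [KeypointMatrix-class]
#' (or the silhouette-derived pixel matrix), `stimulusInfo()` the stimulus
#' table, `poseCoords()` the keypoint coordinate array of a [PoseSet-class],
#' `pcComponents()`, `pcSds()` and `pcCenter()` the parts of a
#' [PCBasis-class], `preferredAxis()` the fold-mean coefficients of an
#' [EncodingFit-class], `modelR2()` its four performance scores,
#' `clusterLabels()` the labels of a [ClusterResult-class],
#' `viewInvarianceIndex()` the scalar index of a [VIIResult-class] and
#' `confusionMatrix()` the percent confusion matrix of a
#' [DecodingResult-class].
#'
#' @param x an object of the documented classes.
#' @return See details above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dataMatrix", function(x) standardGeneric("dataMatrix"))
#' @rdname accessors
#' @export
setMethod("dataMatrix", "KeypointMatrix", function(x) x@X)

#' @rdname accessors
#' @export
setGeneric("stimulusInfo", function(x) standardGeneric("stimulusInfo"))
#' @rdname accessors
#' @export
setMethod("stimulusInfo", "PoseSet", function(x) x@stimInfo)
#' @rdname accessors
#' @export
setMethod("stimulusInfo", "KeypointMatrix", function(x) x@stimInfo)
#' @rdname accessors
#' @export
setMethod("stimulusInfo", "SilhouetteStack", function(x) x@stimInfo)

#' @rdname accessors
#' @export
setGeneric("poseCoords", function(x) standardGeneric("poseCoords"))
#' @rdname accessors
#' @export
setMethod("poseCoords", "PoseSet", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("pcComponents", function(x) standardGeneric("pcComponents"))
#' @rdname accessors
#' @export
setMethod("pcComponents", "PCBasis", function(x) x@components)

#' @rdname accessors
#' @export
setGeneric("pcSds", function(x) standardGeneric("pcSds"))
#' @rdname accessors
#' @export
setMethod("pcSds", "PCBasis", function(x) x@sds)

#' @rdname accessors
#' @export
setGeneric("pcCenter", function(x) standardGeneric("pcCenter"))
#' @rdname accessors
#' @export
setMethod("pcCenter", "PCBasis", function(x) x@center)

#' @rdname accessors
#' @export
setGeneric("preferredAxis", function(x) standardGeneric("preferredAxis"))
#' @rdname accessors
#' @export
setMethod("preferredAxis", "EncodingFit", function(x) x@beta)

#' @rdname accessors
#' @export
setGeneric("modelR2", function(x) standardGeneric("modelR2"))
#' @rdname accessors
#' @export
setMethod("modelR2", "EncodingFit", function(x) {
  c(r2 = x@r2, r2Adj = x@r2Adj, r2Norm = x@r2Norm, r2AdjNorm = x@r2AdjNorm)
})

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("viewInvarianceIndex", function(x) {
  standardGeneric("viewInvarianceIndex")
})
#' @rdname accessors
#' @export
setMethod("viewInvarianceIndex", "VIIResult", function(x) x@vii)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setMethod("confusionMatrix", "DecodingResult", function(x) x@confusion)
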