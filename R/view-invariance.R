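# Model responses along a preferred axis and the View Invariance Index.

#' Model responses along a preferred axis
#'
#' The model unit's response to every stimulus of a data matrix:
#' `yhat = (X - center) P beta`, i.e. the stimulus distances along the
#' preferred axis.
#'
#' @param X a [KeypointMatrix-class] or numeric matrix.
#' @param basis the [PCBasis-class] of the model.
#' @param beta the preferred axis (length K).
#' @return Numeric vector, one model response per stimulus.
#' @export
predictModelResponses <- function(X, basis, beta) {
  drop(projectScores(basis, X) %*% beta)
}

#' View Invariance Index
#'
#' Finds the (pose, elevation) combination with the maximal model response,
#' takes the range of responses over its 8 views as the observed range `r_o`,
#' and builds a null of ranges from seeded random draws of 7 responses from
#' the remaining stimuli (the best combination's views are excluded from the
#' pool) plus the maximum itself. The index is minus the z-score of `r_o` in
#' that null: positive values mean the response varies less across the best
#' pose's views than random response sets containing the maximum, i.e. more
#' viewpoint tolerance.
#'
#' @param yhat model responses, one per stimulus (see
#'   [predictModelResponses()]).
#' @param stimInfo stimulus table aligned with `yhat` (needs `pose_id`,
#'   `azimuth`, `elevation`). Every (pose, elevation) must carry the complete
#'   azimuth grid.
#' @param nResamples null draws (default 1000).
#' @param seed RNG seed.
#' @param unitId unit identifier (metadata).
#' @return A [VIIResult-class].
#' @export
computeVII <- function(yhat, stimInfo, nResamples = 1000, seed = 1,
                       unitId = "unit") {
  if (length(yhat) != nrow(stimInfo)) {
    stop("invalid-argument: yhat must align with stimInfo")
  }
  check_complete_grid(stimInfo)
  best <- which.max(yhat) # ties: lowest stimulus index
  grp <- stimInfo$pose_id == stimInfo$pose_id[best] &
    stimInfo$elevation == stimInfo$elevation[best]
  members <- which(grp)
  r_o <- diff(range(yhat[members]))
  pool <- yhat[-members]
  draw_size <- length(members) - 1L
  if (length(pool) < draw_size) {
    stop("insufficient-data: not enough stimuli outside the best combination")
  }
  y_max <- yhat[best]
  r_n <- with_rng(seed, {
    vapply(seq_len(nResamples), function(i) {
      diff(range(c(sample(pool, draw_size), y_max)))
    }, numeric(1))
  })
  mu <- mean(r_n)
  sdev <- stats::sd(r_n)
  if (sdev == 0) stop("degenerate-null: null ranges have zero variance")
  z <- (r_o - mu) / sdev
  methods::new("VIIResult", unitId = unitId, modelResponses = yhat,
               bestPose = as.integer(stimInfo$pose_id[best]),
               bestElevation = stimInfo$elevation[best],
               observedRange = r_o, nullRanges = r_n, nullMean = mu,
               nullSd = sdev, zObserved = z, vii = -z,
               seed = as.integer(seed))
}
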