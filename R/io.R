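# Plain-text serialization of the core objects. Keypoint tables and trial
# rates are CSV; structured metadata travels in JSON sidecars.

# CSV writer preserving full double precision (17 significant digits), so a
# written table rebuilds bit-identical objects.
write_csv17 <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write / read a keypoint table
#'
#' Long-format CSV with columns `stimulus_index, pose_id, pose_class,
#' azimuth_deg, elevation_deg, keypoint_label, x_px, y_px, z_px`.
#' Coordinates are 0-based pixels, origin top-left, y increasing downward.
#'
#' @param poseSet a [PoseSet-class].
#' @param path output CSV path.
#' @return `writeKeypointTable` returns `path` invisibly;
#'   `readKeypointTable` returns a [PoseSet-class].
#' @export
writeKeypointTable <- function(poseSet, path) {
  stopifnot(methods::is(poseSet, "PoseSet"))
  co <- poseSet@coords
  n <- dim(co)[3]
  nk <- dim(co)[1]
  info <- poseSet@stimInfo
  df <- data.frame(
    stimulus_index = rep(info$stimulus_index, each = nk),
    pose_id = rep(info$pose_id, each = nk),
    pose_class = rep(info$pose_class, each = nk),
    azimuth_deg = rep(info$azimuth, each = nk),
    elevation_deg = rep(info$elevation, each = nk),
    keypoint_label = rep(poseSet@keypointLabels, n),
    x_px = as.vector(co[, 1, ]),
    y_px = as.vector(co[, 2, ]),
    z_px = as.vector(co[, 3, ])
  )
  write_csv17(df, path)
  meta <- list(image_size = poseSet@imageSize,
               global_scale = poseSet@globalScale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeKeypointTable
#' @export
readKeypointTable <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- unique(df$keypoint_label)
  nk <- length(labels)
  idx <- sort(unique(df$stimulus_index))
  n <- length(idx)
  co <- array(NA_real_, dim = c(nk, 3, n),
              dimnames = list(labels, c("x", "y", "z"), NULL))
  df <- df[order(df$stimulus_index, match(df$keypoint_label, labels)), ]
  co[, 1, ] <- df$x_px
  co[, 2, ] <- df$y_px
  co[, 3, ] <- df$z_px
  first <- df[!duplicated(df$stimulus_index), ]
  info <- data.frame(stimulus_index = first$stimulus_index,
                     pose_id = first$pose_id, pose_class = first$pose_class,
                     azimuth = first$azimuth_deg,
                     elevation = first$elevation_deg)
  bones <- if (identical(labels, kp_labels)) kp_bones() else {
    matrix(integer(0), 0, 2)
  }
  methods::new("PoseSet", coords = co, stimInfo = info,
               keypointLabels = labels, bones = bones,
               imageSize = as.numeric(meta$image_size),
               globalScale = as.numeric(meta$global_scale))
}

#' Write / read trial-level window rates
#'
#' Long-format CSV with columns `unit_id, stimulus_index, trial_index,
#' window` (`baseline` or `response`) `, rate_hz`. Ground truth of synthetic
#' units travels in a JSON sidecar.
#'
#' @param units list of [UnitRecording-class] objects.
#' @param path output CSV path.
#' @return `writeTrialRates` returns `path` invisibly; `readTrialRates`
#'   returns a list of [UnitRecording-class] objects (category tests are not
#'   serialized here).
#' @export
writeTrialRates <- function(units, path) {
  rows <- lapply(units, function(u) {
    nT <- nrow(u@responseRates)
    nS <- ncol(u@responseRates)
    data.frame(
      unit_id = u@unitId,
      stimulus_index = rep(rep(seq_len(nS), each = nT), 2),
      trial_index = rep(rep(seq_len(nT), nS), 2),
      window = rep(c("baseline", "response"), each = nT * nS),
      rate_hz = c(as.vector(u@baselineRates), as.vector(u@responseRates))
    )
  })
  write_csv17(do.call(rbind, rows), path)
  gt <- lapply(units, function(u) u@groundTruth)
  names(gt) <- vapply(units, function(u) u@unitId, character(1))
  jsonlite::write_json(gt, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTrialRates
#' @export
readTrialRates <- function(path) {
  df <- utils::read.csv(path)
  gt_path <- paste0(path, ".json")
  gt <- if (file.exists(gt_path)) {
    jsonlite::read_json(gt_path, simplifyVector = TRUE)
  } else list()
  lapply(unique(df$unit_id), function(id) {
    d <- df[df$unit_id == id, ]
    nS <- max(d$stimulus_index)
    nT <- max(d$trial_index)
    get <- function(w) {
      dd <- d[d$window == w, ]
      m <- matrix(NA_real_, nT, nS)
      m[cbind(dd$trial_index, dd$stimulus_index)] <- dd$rate_hz
      m
    }
    methods::new("UnitRecording", unitId = id, responseRates = get("response"),
                 baselineRates = get("baseline"), categoryRates = NULL,
                 groundTruth = if (id %in% names(gt)) {
                   as.list(gt[[id]])
                 } else list())
  })
}

#' Write / read a data matrix with its JSON header
#'
#' @param kpMatrix a [KeypointMatrix-class].
#' @param path output CSV path (the JSON header is written alongside).
#' @return `writeDataMatrix` returns `path` invisibly; `readDataMatrix`
#'   returns a [KeypointMatrix-class].
#' @export
writeDataMatrix <- function(kpMatrix, path) {
  stopifnot(methods::is(kpMatrix, "KeypointMatrix"))
  write_csv17(cbind(kpMatrix@stimInfo, as.data.frame(kpMatrix@X)), path)
  jsonlite::write_json(
    list(variant = kpMatrix@variant, column_layout = kpMatrix@columnLayout,
         image_size = kpMatrix@imageSize),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDataMatrix
#' @export
readDataMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  info_cols <- c("stimulus_index", "pose_id", "pose_class", "azimuth",
                 "elevation")
  X <- as.matrix(df[, setdiff(names(df), info_cols), drop = FALSE])
  methods::new("KeypointMatrix", X = X, variant = meta$variant,
               columnLayout = meta$column_layout,
               stimInfo = df[, info_cols],
               imageSize = as.numeric(meta$image_size))
}
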