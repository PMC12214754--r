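# End-to-end orchestration of the synthetic study: simulate stimuli and
# units, select units, build all data-matrix variants, fit every model,
# invert the fits, compute view invariance, partition variance against a
# pixel feature bank, cluster the preferred axes and decode pose.

#' Default pipeline configuration
#'
#' All defaults equal the standard analysis settings: a 45-pose x 16-view
#' stimulus grid at 350 px, 10 keypoint PCs and 50 feature-bank PCs, 10
#' cross-validation folds, 1000 permutations, the standard unit-selection
#' thresholds and an R^2 > 0.25 gate for view-invariance and clustering
#' summaries. `testMode = TRUE` lowers permutation/resample counts (never the
#' formulas) for desk-scale runs.
#'
#' @param seed master RNG seed.
#' @param testMode lower permutation and resample counts.
#' @return Named list of configuration blocks.
#' @export
defaultRunConfig <- function(seed = 7, testMode = FALSE) {
  list(
    seed = seed,
    stimulus = list(nPoses = 45, nViews = 16, imageSize = 350,
                    silhouetteGrid = 25),
    population = list(
      nUnitsPerVariant = c("3D_VD" = 20, "3D_VF" = 20, "3D_VI" = 20),
      targetReliability = 0.7, nTrials = 6, baseline = 10,
      bodyGain = 20, nonbodyGain = 2
    ),
    model = list(nPcsKeypoint = 10, nPcsFeatureBank = 50, nFolds = 10,
                 nPerm = if (testMode) 100 else 1000),
    gates = list(r2Gate = 0.25),
    decoding = list(nResamples = if (testMode) 5 else 50,
                    pseudoTrialsPerClass = if (testMode) 8 else NULL),
    testMode = testMode
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values found in the file override the defaults of [defaultRunConfig()].
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) {
  utils::modifyList(defaultRunConfig(), yaml::read_yaml(path))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages, in order: stimulus generation, silhouette rendering, the five
#' keypoint data matrices plus the pixel matrix, PCA bases, unit simulation
#' per generative variant, category tests and unit selection, encoding fits
#' of all five variants per selected unit, axis inversion, view invariance,
#' variance partitioning against the pixel bank, clustering of preferred
#' axes, and pose decoding. Every tabular artifact is written as CSV and
#' structured results as JSON under `outputDir`; the returned manifest lists
#' every artifact path, the seed, and per-stage wall time and summaries.
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @param outputDir writable output directory.
#' @return The run manifest (also written to `manifest.json`), invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), outputDir = tempfile()) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outputDir, 2) != 0) {
    stop("invalid-argument: output directory is not writable")
  }
  seed <- config$seed
  manifest <- list(seed = seed, version = as.character(
    utils::packageVersion("poseAxes")), stages = list(), artifacts = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf(
        "stage '%s' failed: %s\nRe-run with runPipeline(config, \"%s\") after fixing.",
        name, conditionMessage(e), outputDir), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      summary = attr(res, "summary") %||% NULL)
    res
  }
  art <- function(name, path) {
    manifest$artifacts[[name]] <<- path
    path
  }

  ## stimuli
  poseSet <- stage("stimuli", {
    ps <- generatePoseSet(config$stimulus$nPoses, config$stimulus$nViews,
                          seed = child_seed(seed, 1),
                          imageSize = config$stimulus$imageSize)
    writeKeypointTable(ps, art("keypoints", file.path(outputDir,
                                                      "keypoints.csv")))
    structure(ps, summary = list(n_stimuli = nrow(stimulusInfo(ps))))
  })
  silhouettes <- stage("silhouettes", {
    renderSilhouettes(poseSet, config$stimulus$silhouetteGrid)
  })

  ## data matrices + bases
  variants <- c("2D", "3D_VD", "2D_VF", "3D_VF", "3D_VI")
  matrices <- stage("matrices", {
    ms <- lapply(variants, function(v) buildDataMatrix(poseSet, v))
    names(ms) <- variants
    for (v in variants) {
      writeDataMatrix(ms[[v]], art(paste0("matrix_", v),
                                   file.path(outputDir,
                                             paste0("matrix_", v, ".csv"))))
    }
    structure(ms, summary = list(
      widths = vapply(ms, function(m) ncol(dataMatrix(m)), numeric(1))))
  })
  pixelMatrix <- buildPixelMatrix(silhouettes)
  bases <- stage("pca", {
    b <- lapply(matrices, fitPCA, nComponents = config$model$nPcsKeypoint)
    b$pixel <- fitPCA(pixelMatrix,
                      nComponents = min(config$model$nPcsFeatureBank,
                                        ncol(pixelMatrix)))
    b
  })

  ## units
  nPer <- config$population$nUnitsPerVariant
  units <- stage("units", {
    us <- list()
    for (v in names(nPer)) {
      if (nPer[[v]] < 1) next
      us <- c(us, simulateEncodingUnits(
        bases[[v]], matrices[[v]], nUnits = nPer[[v]],
        targetReliability = config$population$targetReliability,
        nTrials = config$population$nTrials,
        baseline = config$population$baseline,
        seed = child_seed(seed, 10 + match(v, names(nPer)))))
    }
    us <- lapply(seq_along(us), function(i) {
      u <- us[[i]]
      u@categoryRates <- simulateCategoryResponses(
        config$population$bodyGain, config$population$nonbodyGain,
        baseline = config$population$baseline,
        seed = child_seed(seed, 1000 + i))
      u
    })
    if (length(us)) {
      writeTrialRates(us, art("trial_rates",
                              file.path(outputDir, "trial_rates.csv")))
    }
    structure(us, summary = list(n_units = length(us)))
  })

  if (length(units) == 0) {
    manifest$stages$selection <- list(summary = list(note = "no units"))
    man_path <- file.path(outputDir, "manifest.json")
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
    return(invisible(manifest))
  }

  ## selection
  selection <- stage("selection", {
    rep <- selectUnits(units, seed = child_seed(seed, 20))
    utils::write.csv(rep, art("selection",
                              file.path(outputDir, "selection.csv")),
                     row.names = FALSE)
    structure(rep, summary = list(n_selected = sum(rep$passed)))
  })
  kept <- which(selection$passed)

  ## encoding fits (all five variants per kept unit)
  fits <- stage("fits", {
    out <- list()
    rows <- list()
    for (i in kept) {
      u <- units[[i]]
      y <- colMeans(u@responseRates)
      rel <- selection$reliability[i]
      fseed <- child_seed(seed, 30 + i)
      for (v in variants) {
        fit <- fitPcrCv(projectScores(bases[[v]], matrices[[v]]), y,
                        nFolds = config$model$nFolds, seed = fseed,
                        reliability = rel, variant = v, unitId = u@unitId)
        out[[paste(u@unitId, v, sep = ".")]] <- fit
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = u@unitId, variant = v, r2 = fit@r2, r2_adj = fit@r2Adj,
          r2_norm = fit@r2Norm, r2_adj_norm = fit@r2AdjNorm,
          reliability = rel)
      }
    }
    scores <- do.call(rbind, rows)
    utils::write.csv(scores, art("fit_scores",
                                 file.path(outputDir, "fit_scores.csv")),
                     row.names = FALSE)
    structure(out, summary = list(n_fits = length(out)))
  })

  ## inversion + VII on the preferred (3D_VD) axes
  inv <- stage("inversion", {
    lapply(kept, function(i) {
      u <- units[[i]]
      fit <- fits[[paste(u@unitId, "3D_VD", sep = ".")]]
      visualizePreferredAxis(bases[["3D_VD"]], fit)
    })
  })
  vii <- stage("vii", {
    res <- lapply(kept, function(i) {
      u <- units[[i]]
      fit <- fits[[paste(u@unitId, "3D_VD", sep = ".")]]
      if (fit@r2 <= config$gates$r2Gate) return(NULL)
      yhat <- predictModelResponses(matrices[["3D_VD"]], bases[["3D_VD"]],
                                    preferredAxis(fit))
      computeVII(yhat, stimulusInfo(matrices[["3D_VD"]]),
                 seed = child_seed(seed, 50 + i), unitId = u@unitId)
    })
    keep <- !vapply(res, is.null, logical(1))
    viidf <- data.frame(
      unit_id = vapply(res[keep], function(r) r@unitId, character(1)),
      vii = vapply(res[keep], viewInvarianceIndex, numeric(1)))
    if (nrow(viidf)) {
      utils::write.csv(viidf, art("vii", file.path(outputDir, "vii.csv")),
                       row.names = FALSE)
    }
    structure(res, summary = list(n_gated_in = sum(keep)))
  })

  ## variance partitioning: 3D_VD keypoints vs pixel bank
  partition <- stage("partition", {
    res <- lapply(kept, function(i) {
      u <- units[[i]]
      y <- colMeans(u@responseRates)
      fseed <- child_seed(seed, 30 + i)
      Za <- projectScores(bases[["3D_VD"]], matrices[["3D_VD"]])
      Zb <- projectScores(bases$pixel, pixelMatrix)
      fa <- fits[[paste(u@unitId, "3D_VD", sep = ".")]]
      fb <- fitPcrCv(Zb, y, nFolds = config$model$nFolds, seed = fseed,
                     variant = "pixel", unitId = u@unitId)
      fc <- fitCombinedModel(Za, Zb, y, nFolds = config$model$nFolds,
                             seed = fseed, unitId = u@unitId)
      variancePartition(fa, fb, fc, bankNames = c("keypoint", "pixel"))
    })
    pdf <- do.call(rbind, lapply(res, function(p) {
      data.frame(unit_id = p@unitId, r2_kp = p@r2A, r2_pixel = p@r2B,
                 r2_combined = p@r2Combined, unique_kp = p@uniqueA,
                 unique_pixel = p@uniqueB, shared = p@shared)
    }))
    utils::write.csv(pdf, art("partition",
                              file.path(outputDir, "partition.csv")),
                     row.names = FALSE)
    res
  })

  ## clustering of preferred axes
  clusters <- stage("clustering", {
    betas <- t(vapply(kept, function(i) {
      preferredAxis(fits[[paste(units[[i]]@unitId, "3D_VD", sep = ".")]])
    }, numeric(config$model$nPcsKeypoint)))
    r2s <- vapply(kept, function(i) {
      fits[[paste(units[[i]]@unitId, "3D_VD", sep = ".")]]@r2
    }, numeric(1))
    if (nrow(betas) >= 2 && sum(r2s > config$gates$r2Gate) >= 2) {
      cl <- clusterAxes(betas, r2 = r2s, r2Gate = config$gates$r2Gate)
      utils::write.csv(cl@summary, art("clusters",
                                       file.path(outputDir, "clusters.csv")),
                       row.names = FALSE)
      structure(cl, summary = list(n_clusters = nrow(cl@summary)))
    } else NULL
  })

  ## pose decoding
  decoding <- stage("decoding", {
    rates <- lapply(units[kept], function(u) u@responseRates)
    if (length(rates) < 2) return(NULL)
    dec <- decodePoses(rates, stimulusInfo(poseSet)$pose_id,
                       nResamples = config$decoding$nResamples,
                       pseudoTrialsPerClass =
                         config$decoding$pseudoTrialsPerClass,
                       seed = child_seed(seed, 60))
    utils::write.csv(confusionMatrix(dec),
                     art("confusion", file.path(outputDir, "confusion.csv")))
    jsonlite::write_json(
      list(accuracy = dec@accuracy, accuracy_sd = dec@accuracySd,
           chance = dec@chanceLevel, n_resamples = dec@nResamples),
      art("decoding", file.path(outputDir, "decoding.json")),
      auto_unbox = TRUE, digits = NA)
    structure(dec, summary = list(accuracy = dec@accuracy,
                                  chance = dec@chanceLevel))
  })

  man_path <- file.path(outputDir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
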