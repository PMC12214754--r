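# Population-level analyses: variance partitioning between feature banks and
# view-tolerant pose decoding from pseudo-population responses.

#' Partition explained variance between two feature banks
#'
#' From the cross-validated R^2 of two single-bank fits and their combined
#' fit: `unique_a = R2_combined - R2_b`, `unique_b = R2_combined - R2_a`,
#' `shared = R2_a + R2_b - R2_combined`. Components can be negative
#' (cross-validated R^2 is not bounded below) and are reported as-is; they
#' sum to the combined R^2 by construction.
#'
#' @param fitA,fitB single-bank [EncodingFit-class] objects.
#' @param fitCombined the combined fit (same response, same fold seed).
#' @param bankNames labels of the two banks.
#' @return A [VariancePartition-class].
#' @export
variancePartition <- function(fitA, fitB, fitCombined,
                              bankNames = c(fitA@variant, fitB@variant)) {
  for (f in list(fitA, fitB, fitCombined)) {
    stopifnot(methods::is(f, "EncodingFit"))
  }
  if (!identical(fitA@foldAssignment, fitB@foldAssignment) ||
      !identical(fitA@foldAssignment, fitCombined@foldAssignment)) {
    stop("invalid-argument: all three fits must share the fold assignment")
  }
  methods::new("VariancePartition", unitId = fitCombined@unitId,
               bankNames = bankNames,
               r2A = fitA@r2, r2B = fitB@r2, r2Combined = fitCombined@r2,
               uniqueA = fitCombined@r2 - fitB@r2,
               uniqueB = fitCombined@r2 - fitA@r2,
               shared = fitA@r2 + fitB@r2 - fitCombined@r2)
}

# leave-one-out max-correlation classification of a pseudo-trial matrix.
# X: trials x units, labels: integer class per trial (1..k).
loo_max_correlation <- function(X, labels, nClasses) {
  n <- nrow(X)
  counts <- tabulate(labels, nClasses)
  if (any(counts < 2)) stop("insufficient-data: a class has < 2 pseudo-trials")
  sums <- rowsum(X, labels) # k x units
  means <- sums / counts
  # correlations against the full-data class means (wrong only for the
  # trial's own class, corrected below)
  C <- suppressWarnings(stats::cor(t(X), t(means))) # n x k
  for (c in seq_len(nClasses)) {
    idx <- which(labels == c)
    Tc <- (matrix(sums[c, ], length(idx), ncol(X), byrow = TRUE) -
             X[idx, , drop = FALSE]) / (counts[c] - 1)
    A <- X[idx, , drop = FALSE]
    mA <- rowMeans(A)
    mT <- rowMeans(Tc)
    cov <- rowSums((A - mA) * (Tc - mT))
    den <- sqrt(rowSums((A - mA)^2) * rowSums((Tc - mT)^2))
    C[idx, c] <- ifelse(den > 0, cov / den, NA)
  }
  C[is.na(C)] <- -Inf
  pred <- max.col(C, ties.method = "first")
  pred
}

loo_linear_svm <- function(X, labels, nClasses, cost = 1) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("the linear_svm classifier requires the e1071 package")
  }
  n <- nrow(X)
  pred <- integer(n)
  f <- factor(labels, levels = seq_len(nClasses))
  for (i in seq_len(n)) {
    m <- e1071::svm(X[-i, , drop = FALSE], f[-i], kernel = "linear",
                    cost = cost, scale = FALSE)
    pred[i] <- as.integer(as.character(
      stats::predict(m, X[i, , drop = FALSE])))
  }
  pred
}

# One decoding resample: build pseudo-trials and run LOO classification.
# rates: list over units of trials x stimuli matrices.
decode_once <- function(rates, classes, classLevels, pseudoPerClass,
                        classifier) {
  nUnits <- length(rates)
  nTrials <- nrow(rates[[1]])
  Xs <- vector("list", length(classLevels))
  labs <- vector("list", length(classLevels))
  for (ci in seq_along(classLevels)) {
    stim <- which(classes == classLevels[ci])
    nPres <- length(stim) * nTrials
    take <- min(pseudoPerClass %||% nPres, nPres)
    M <- matrix(NA_real_, take, nUnits)
    for (u in seq_len(nUnits)) {
      pres <- as.vector(rates[[u]][, stim]) # all presentations of the class
      M[, u] <- pres[sample.int(nPres)][seq_len(take)]
    }
    Xs[[ci]] <- M
    labs[[ci]] <- rep(ci, take)
  }
  X <- do.call(rbind, Xs)
  labels <- unlist(labs)
  pred <- if (classifier == "max_correlation") {
    loo_max_correlation(X, labels, length(classLevels))
  } else {
    loo_linear_svm(X, labels, length(classLevels))
  }
  list(labels = labels, pred = pred)
}

#' Decode pose irrespective of viewpoint from pseudo-populations
#'
#' All views of a pose share that pose's label. Per resample, each unit's
#' presentations of a pose (all views x all trials) are independently
#' shuffled and concatenated into pseudo-population trials; a classifier is
#' trained and tested with leave-one-pseudo-trial-out cross-validation. The
#' default max-correlation classifier assigns the class whose training-mean
#' template has the highest Pearson correlation with the test vector (ties
#' broken by lowest class index). Accuracy and the confusion matrix are
#' averaged over resamples. An optional permutation test permutes the pose
#' labels across stimuli and reruns the whole procedure, reporting the
#' maximum mean accuracy over permutations.
#'
#' @param rates list over units of trials x stimuli response-window rate
#'   matrices (identical stimulus ordering).
#' @param poseLabels pose id per stimulus.
#' @param classifier `"max_correlation"` (default) or `"linear_svm"`.
#' @param nResamples pseudo-population resamples (default 50).
#' @param nLabelPerms label permutations for the null (default 0: skip).
#' @param pseudoTrialsPerClass optional cap on pseudo-trials per pose (the
#'   full count is views x trials).
#' @param seed RNG seed.
#' @return A [DecodingResult-class]; the confusion matrix is predicted x
#'   true in percent, each column summing to 100.
#' @export
decodePoses <- function(rates, poseLabels,
                        classifier = c("max_correlation", "linear_svm"),
                        nResamples = 50, nLabelPerms = 0,
                        pseudoTrialsPerClass = NULL, seed = 1) {
  classifier <- match.arg(classifier)
  if (!is.list(rates)) stop("invalid-argument: rates must be a list of units")
  nStim <- ncol(rates[[1]])
  if (length(poseLabels) != nStim) {
    stop("invalid-argument: one pose label per stimulus required")
  }
  if (nrow(rates[[1]]) < 2 && is.null(pseudoTrialsPerClass)) {
    stop("insufficient-data: need >= 2 trials per stimulus")
  }
  classLevels <- sort(unique(poseLabels))
  k <- length(classLevels)

  run <- function(classes, run_seed, nRes) {
    acc <- numeric(nRes)
    conf <- matrix(0, k, k)
    with_rng(run_seed, {
      for (r in seq_len(nRes)) {
        out <- decode_once(rates, classes, classLevels,
                           pseudoTrialsPerClass, classifier)
        acc[r] <- 100 * mean(out$pred == out$labels)
        for (i in seq_along(out$labels)) {
          conf[out$pred[i], out$labels[i]] <- conf[out$pred[i],
                                                   out$labels[i]] + 1
        }
      }
    })
    conf <- sweep(conf, 2, colSums(conf), `/`) * 100
    list(acc = acc, conf = conf)
  }

  obs <- run(poseLabels, child_seed(seed, 1), nResamples)

  permMax <- NA_real_
  if (nLabelPerms > 0) {
    permAcc <- vapply(seq_len(nLabelPerms), function(p) {
      perm <- with_rng(child_seed(seed, 100 + p),
                       poseLabels[sample.int(nStim)])
      mean(run(perm, child_seed(seed, 200 + p), nResamples)$acc)
    }, numeric(1))
    permMax <- max(permAcc)
  }

  dimnames(obs$conf) <- list(predicted = classLevels, true = classLevels)
  methods::new("DecodingResult",
               accuracy = mean(obs$acc), accuracySd = stats::sd(obs$acc),
               confusion = obs$conf, nResamples = as.integer(nResamples),
               permutationMax = permMax, classifier = classifier,
               chanceLevel = 100 / k, seed = as.integer(seed))
}
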