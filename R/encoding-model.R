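# Cross-validated principal-component regression (PCR) per unit, with
# adjusted and reliability-normalized performance scores and permutation
# nulls.

# Seeded unstratified partition of n stimuli into nFolds near-equal folds.
make_folds <- function(n, nFolds, seed) {
  with_rng(seed, sample(rep(seq_len(nFolds), length.out = n)))
}

# One full CV pass: returns per-fold betas and out-of-fold R^2.
pcr_cv_core <- function(Z, y, folds, nFolds) {
  K <- ncol(Z)
  betas <- matrix(NA_real_, K, nFolds)
  r2 <- numeric(nFolds)
  for (k in seq_len(nFolds)) {
    tr <- folds != k
    beta <- solve_normal(Z[tr, , drop = FALSE], y[tr])
    te <- !tr
    pred <- Z[te, , drop = FALSE] %*% beta
    yt <- y[te]
    r2[k] <- 1 - sum((yt - pred)^2) / sum((yt - mean(yt))^2)
    betas[, k] <- beta
  }
  list(betas = betas, r2 = r2)
}

#' Fit a 10-fold cross-validated PC regression for one unit
#'
#' Regresses the unit's z-scored stimulus-mean response on the stimulus PC
#' scores without an intercept: per fold, `beta_k = (Z'Z)^-1 Z'y` on the
#' training stimuli, predictions on the held-out stimuli, and the out-of-fold
#' coefficient of determination `R2_k = 1 - SS_res / SS_tot` (total around
#' the held-out mean). The final preferred axis and R^2 are fold means. The
#' response is z-scored once across all stimuli (a single fixed
#' transformation; per-training-fold standardization is available via
#' `zscore = "per_fold"`). Folds are a seeded unstratified random partition.
#'
#' @param scores stimuli x K PC-score matrix (columns centered).
#' @param y stimulus-mean responses, one per stimulus.
#' @param nFolds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param zscore `"global"` (default), `"per_fold"` or `"none"`.
#' @param reliability split-half reliability of the unit; when supplied the
#'   reliability-normalized scores are populated.
#' @param variant label of the predictor variant (metadata).
#' @param unitId unit identifier (metadata).
#' @return An [EncodingFit-class].
#' @export
fitPcrCv <- function(scores, y, nFolds = 10, seed = 1,
                     zscore = c("global", "per_fold", "none"),
                     reliability = NA_real_, variant = "custom",
                     unitId = "unit") {
  zscore <- match.arg(zscore)
  Z <- as.matrix(scores)
  n <- length(y)
  if (nrow(Z) != n) stop("invalid-argument: scores rows must match length(y)")
  if (stats::sd(y) == 0) stop("undefined: constant response (zero variance)")
  K <- ncol(Z)
  if (K >= n - ceiling(n / nFolds)) {
    stop("invalid-argument: predictor count must be below the training-fold size")
  }
  if (zscore == "global") y <- (y - mean(y)) / stats::sd(y)
  folds <- make_folds(n, nFolds, seed)
  if (zscore == "per_fold") {
    yz <- y
    for (k in seq_len(nFolds)) {
      idx <- folds == k
      yz[idx] <- (y[idx] - mean(y[idx])) / stats::sd(y[idx])
    }
    y <- yz
  }
  fit <- pcr_cv_core(Z, y, folds, nFolds)
  r2 <- mean(fit$r2)
  r2Adj <- adjust_r2(r2, n, K)
  methods::new("EncodingFit",
    unitId = unitId, variant = variant, M = as.integer(K),
    nStimuli = as.integer(n), foldAssignment = as.integer(folds),
    betasByFold = fit$betas, r2ByFold = fit$r2,
    beta = rowMeans(fit$betas), r2 = r2, r2Adj = r2Adj,
    reliability = as.numeric(reliability),
    r2Norm = if (is.finite(reliability) && reliability > 0) {
      r2 / reliability
    } else NA_real_,
    r2AdjNorm = if (is.finite(reliability) && reliability > 0) {
      r2Adj / reliability
    } else NA_real_,
    seed = as.integer(seed))
}

adjust_r2 <- function(r2, N, M) {
  1 - (1 - r2) * (N - 1) / (N - M - 1)
}

#' Performance scores of an encoding fit
#'
#' Computes the adjusted coefficient of determination
#' `R2_adj = 1 - (1 - R2)(N - 1)/(N - M - 1)` and the reliability-normalized
#' scores obtained by dividing `R2` and `R2_adj` by the unit's split-half
#' reliability (the noise ceiling). Negative cross-validated `R2` (model
#' worse than the held-out mean) is propagated as-is.
#'
#' @param r2 cross-validated R^2, or an [EncodingFit-class].
#' @param reliability Spearman-Brown corrected split-half reliability (> 0).
#' @param N number of stimuli (ignored when `r2` is an EncodingFit).
#' @param M number of predictors (ignored when `r2` is an EncodingFit).
#' @return Named numeric: `r2`, `r2Adj`, `r2Norm`, `r2AdjNorm`.
#' @export
performanceMetrics <- function(r2, reliability, N = NULL, M = NULL) {
  if (methods::is(r2, "EncodingFit")) {
    N <- r2@nStimuli
    M <- r2@M
    r2 <- r2@r2
  }
  if (is.null(N) || is.null(M)) stop("invalid-argument: N and M required")
  if (N <= M + 1) stop("invalid-argument: need N > M + 1")
  if (!is.finite(reliability) || reliability <= 0) {
    stop("reliability-error: reliability must be positive")
  }
  r2Adj <- adjust_r2(r2, N, M)
  c(r2 = r2, r2Adj = r2Adj, r2Norm = r2 / reliability,
    r2AdjNorm = r2Adj / reliability)
}

#' Permutation null distribution of model performance
#'
#' Three null constructions: `"label_shuffle_prefit"` permutes the stimulus
#' labels of the response before the full cross-validated fit (the standard
#' null); `"test_label_shuffle"` fits on the true labels and shuffles only
#' the held-out labels before scoring; `"beta_permutation"` permutes the
#' fitted coefficients across the K components before prediction. Values are
#' reliability-normalized when a reliability is supplied.
#'
#' @param scores stimuli x K PC-score matrix.
#' @param y stimulus-mean responses.
#' @param method null construction (see above).
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed; permutation p draws its own substream. The special
#'   value `nPerm = 1` with `identityFirst = TRUE` applies the identity
#'   permutation (a self-check: the null value equals the observed
#'   statistic).
#' @param nFolds folds of the CV protocol (default 10).
#' @param foldSeed fold-assignment seed (defaults to `seed`, matching the
#'   observed fit).
#' @param reliability noise ceiling used for normalization (default 1).
#' @param identityFirst use the identity permutation for the first draw.
#' @return A [NullDistribution-class].
#' @export
permutationNull <- function(scores, y,
                            method = c("label_shuffle_prefit",
                                       "test_label_shuffle",
                                       "beta_permutation"),
                            nPerm = 1000, seed = 1, nFolds = 10,
                            foldSeed = seed, reliability = 1,
                            identityFirst = FALSE) {
  method <- match.arg(method)
  Z <- as.matrix(scores)
  n <- length(y)
  y <- (y - mean(y)) / stats::sd(y)
  folds <- make_folds(n, nFolds, foldSeed)
  base_fit <- pcr_cv_core(Z, y, folds, nFolds)
  K <- ncol(Z)

  one_perm <- function(p) {
    perm <- if (identityFirst && p == 1) seq_len(n) else sample.int(n)
    switch(method,
      label_shuffle_prefit = mean(pcr_cv_core(Z, y[perm], folds, nFolds)$r2),
      test_label_shuffle = {
        yp <- y[perm]
        r2 <- vapply(seq_len(nFolds), function(k) {
          te <- folds == k
          pred <- Z[te, , drop = FALSE] %*% base_fit$betas[, k]
          yt <- yp[te]
          1 - sum((yt - pred)^2) / sum((yt - mean(yt))^2)
        }, numeric(1))
        mean(r2)
      },
      beta_permutation = {
        bperm <- if (identityFirst && p == 1) seq_len(K) else sample.int(K)
        r2 <- vapply(seq_len(nFolds), function(k) {
          te <- folds == k
          pred <- Z[te, , drop = FALSE] %*% base_fit$betas[bperm, k]
          yt <- y[te]
          1 - sum((yt - pred)^2) / sum((yt - mean(yt))^2)
        }, numeric(1))
        mean(r2)
      })
  }

  vals <- with_rng(child_seed(seed, 17),
                   vapply(seq_len(nPerm), one_perm, numeric(1)))
  vals <- vals / reliability
  methods::new("NullDistribution", method = method, values = vals,
               percentiles = stats::quantile(vals, c(0.025, 0.975),
                                             names = FALSE),
               nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Fit a combined model from two predictor banks
#'
#' Concatenates the PC scores of two feature banks (e.g. 10 keypoint + 50
#' feature-bank components = 60 predictors) and runs the identical CV
#' protocol with the same fold seed, so variance partitioning against the
#' single-bank fits is coherent.
#'
#' @param scoresA,scoresB stimuli x K_a and stimuli x K_b score matrices with
#'   identical stimulus ordering.
#' @param y stimulus-mean responses.
#' @param nFolds,seed,zscore,reliability,unitId as in [fitPcrCv()].
#' @return An [EncodingFit-class] with `M = K_a + K_b`.
#' @export
fitCombinedModel <- function(scoresA, scoresB, y, nFolds = 10, seed = 1,
                             zscore = c("global", "per_fold", "none"),
                             reliability = NA_real_, unitId = "unit") {
  if (nrow(scoresA) != nrow(scoresB)) {
    stop("invalid-argument: score banks must share the stimulus ordering")
  }
  fitPcrCv(cbind(as.matrix(scoresA), as.matrix(scoresB)), y,
           nFolds = nFolds, seed = seed, zscore = match.arg(zscore),
           reliability = reliability, variant = "combined", unitId = unitId)
}
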