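#' Responsivity test: split-plot ANOVA of baseline vs response windows
#'
#' Mixed two-way ANOVA with the analysis window (baseline vs response) as a
#' repeated factor and the stimulus as a between-presentation factor;
#' presentations are the subjects. With exactly two window levels the
#' within-subject stratum reduces exactly to an analysis of the per-
#' presentation difference scores, which is how it is computed here (the
#' reduction avoids materializing the full subject design matrix at the
#' 720-stimulus scale). A unit passes when either the window main effect or
#' the window-by-stimulus interaction is significant.
#'
#' @param baselineRates trials x stimuli baseline-window rates.
#' @param responseRates trials x stimuli response-window rates (matched
#'   trial structure).
#' @return Named numeric: `p_window` (main effect of window) and
#'   `p_interaction` (window x stimulus).
#' @export
responsivityAnova <- function(baselineRates, responseRates) {
  if (!identical(dim(baselineRates), dim(responseRates))) {
    stop("invalid-argument: matched trial structure required across windows")
  }
  nTrials <- nrow(responseRates)
  nStim <- ncol(responseRates)
  if (nStim < 2 || nTrials < 2) {
    stop("insufficient-data: need >= 2 stimuli and >= 2 trials")
  }
  d <- responseRates - baselineRates # per-presentation difference
  N <- length(d)
  dbar_stim <- colMeans(d)
  dbar <- mean(d)
  ss_stim <- nTrials * sum((dbar_stim - dbar)^2)
  ss_res <- sum(sweep(d, 2, dbar_stim)^2)
  df_stim <- nStim - 1
  df_res <- N - nStim
  if (ss_res <= 0) {
    # degenerate noise-free case: any nonzero effect is infinitely significant
    return(c(p_window = if (abs(dbar) > 0) 0 else 1,
             p_interaction = if (ss_stim > 0) 0 else 1))
  }
  ms_res <- ss_res / df_res
  f_window <- N * dbar^2 / ms_res
  f_int <- (ss_stim / df_stim) / ms_res
  c(p_window = stats::pf(f_window, 1, df_res, lower.tail = FALSE),
    p_interaction = stats::pf(f_int, df_stim, df_res, lower.tail = FALSE))
}

#' Fano-factor slope of spike-count variance on mean
#'
#' Ordinary least-squares slope of the per-stimulus trial-to-trial variance
#' of the spike count on the per-stimulus mean count. Rates are converted to
#' counts with the response-window length. Units pass selection when the
#' slope is below 4.
#'
#' @param responseRates trials x stimuli response-window rates (spikes/s).
#' @param windowS response-window length in seconds (default 0.2).
#' @return The regression slope (unitless).
#' @export
fanoFactor <- function(responseRates, windowS = 0.2) {
  counts <- responseRates * windowS
  mu <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  if (length(unique(round(mu, 12))) < 3) {
    stop("insufficient-data: need >= 3 distinct stimulus means")
  }
  if (stats::var(mu) == 0) stop("undefined-slope: zero variance in means")
  unname(stats::coef(stats::lm(v ~ mu))[2])
}

#' Selectivity test for pose/viewpoint
#'
#' Kruskal-Wallis ANOVA of the response-window rates across stimuli.
#'
#' @param responseRates trials x stimuli response-window rates.
#' @return The Kruskal-Wallis p-value.
#' @export
selectivityTest <- function(responseRates) {
  if (nrow(responseRates) < 2) {
    stop("insufficient-data: need >= 2 trials per stimulus")
  }
  g <- factor(rep(seq_len(ncol(responseRates)), each = nrow(responseRates)))
  stats::kruskal.test(as.vector(responseRates), g)$p.value
}

#' Spearman-Brown corrected split-half reliability
#'
#' Trials are randomly halved per stimulus; the per-half stimulus means are
#' correlated (Pearson) across stimuli and the correlation is boosted to
#' full length with the Spearman-Brown formula `2r / (1 + r)`. The corrected
#' value is averaged over `nSplits` seeded random splits. For odd trial
#' counts the extra trial is assigned to either half at random per split.
#'
#' @param responseRates trials x stimuli response-window rates.
#' @param nSplits number of random splits to average (default 100).
#' @param seed integer RNG seed.
#' @return The mean corrected reliability in \[-1, 1\].
#' @export
splitHalfReliability <- function(responseRates, nSplits = 100, seed = 1) {
  nTrials <- nrow(responseRates)
  nStim <- ncol(responseRates)
  if (nTrials < 2) stop("insufficient-data: need >= 2 trials per stimulus")
  half <- nTrials %/% 2
  x <- as.numeric(responseRates)
  colblock <- rep(seq_len(nStim), each = nTrials)
  offsets <- (seq_len(nStim) - 1L) * nTrials
  with_rng(seed, {
    vals <- vapply(seq_len(nSplits), function(s) {
      extra_first <- nTrials %% 2 == 1 && stats::runif(1) < 0.5
      n1 <- if (extra_first) nTrials - half else half
      # one independent random trial order per stimulus, vectorized
      o <- order(colblock, stats::runif(nTrials * nStim))
      sel1 <- as.vector(outer(seq_len(n1), offsets, `+`))
      sel2 <- as.vector(outer((n1 + 1L):nTrials, offsets, `+`))
      m1 <- colMeans(matrix(x[o[sel1]], n1, nStim))
      m2 <- colMeans(matrix(x[o[sel2]], nTrials - n1, nStim))
      if (stats::sd(m1) == 0 || stats::sd(m2) == 0) {
        stop("undefined-correlation: constant half-means")
      }
      r <- stats::cor(m1, m2)
      2 * r / (1 + r)
    }, numeric(1))
    mean(vals)
  })
}

#' Body Selectivity Index
#'
#' `BSI = (net_body - net_nonbody) / (|net_body| + |net_nonbody|)` where the
#' net rate of a stimulus is its mean response-window rate minus its mean
#' baseline-window rate, and means are taken over the 20 body stimuli and
#' over the 40 face + object stimuli. A BSI of 0.33 corresponds to a twofold
#' stronger response to bodies.
#'
#' @param categoryRates a [CategoryRates-class].
#' @return The BSI, in \[-1, 1\] when both denominator terms are positive.
#' @export
computeBsi <- function(categoryRates) {
  stopifnot(methods::is(categoryRates, "CategoryRates"))
  net <- colMeans(categoryRates@response) - colMeans(categoryRates@baseline)
  body <- mean(net[categoryRates@category == "body"])
  nonbody <- mean(net[categoryRates@category != "body"])
  den <- abs(body) + abs(nonbody)
  if (den == 0) stop("undefined-BSI: zero denominator")
  (body - nonbody) / den
}

#' Default unit-selection thresholds
#'
#' The standard inclusion criteria: responsivity p < 0.05 (window main effect
#' or interaction), Fano-factor slope < 4, maximal mean net rate > 5
#' spikes/s, Kruskal-Wallis selectivity p < 0.05, split-half reliability
#' > 0.5, and (when a category test is present) BSI >= 0.33 with a
#' significant category response.
#'
#' @return Named list of thresholds.
#' @export
selectionThresholds <- function() {
  list(responsivity_alpha = 0.05, fano_max = 4, min_net_rate = 5,
       selectivity_alpha = 0.05, min_reliability = 0.5, min_bsi = 0.33,
       bsi_alpha = 0.05)
}

#' Apply the unit-inclusion criteria to a population
#'
#' Computes every screening statistic per unit (split-plot responsivity,
#' Fano-factor slope, maximal mean net rate, Kruskal-Wallis selectivity,
#' split-half reliability and, when category-test rates are attached, the
#' Body Selectivity Index with its own responsivity test) and combines the
#' per-criterion passes with an AND.
#'
#' @param units list of [UnitRecording-class] objects.
#' @param thresholds named list as returned by [selectionThresholds()].
#' @param windowS response-window length in seconds for spike counts.
#' @param nSplits split-half splits (default 100).
#' @param seed integer RNG seed for the reliability splits.
#' @return A data.frame (one row per unit) with all statistics, per-criterion
#'   logical columns and the overall `passed` flag.
#' @export
selectUnits <- function(units, thresholds = selectionThresholds(),
                        windowS = 0.2, nSplits = 100, seed = 1) {
  th <- utils::modifyList(selectionThresholds(), thresholds)
  rows <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    p <- responsivityAnova(u@baselineRates, u@responseRates)
    fano <- fanoFactor(u@responseRates, windowS)
    net <- colMeans(u@responseRates) - colMeans(u@baselineRates)
    max_net <- max(net)
    sel_p <- selectivityTest(u@responseRates)
    rel <- splitHalfReliability(u@responseRates, nSplits,
                                seed = child_seed(seed, i))
    if (!is.null(u@categoryRates)) {
      bsi <- computeBsi(u@categoryRates)
      bsi_p <- responsivityAnova(u@categoryRates@baseline,
                                 u@categoryRates@response)
      bsi_resp_p <- min(bsi_p)
    } else {
      bsi <- NA_real_
      bsi_resp_p <- NA_real_
    }
    pass <- c(
      responsive = min(p) < th$responsivity_alpha,
      stable = fano < th$fano_max,
      driven = max_net > th$min_net_rate,
      selective = sel_p < th$selectivity_alpha,
      reliable = rel > th$min_reliability,
      body_selective = if (is.na(bsi)) TRUE else {
        bsi >= th$min_bsi && bsi_resp_p < th$bsi_alpha
      }
    )
    data.frame(unit_id = u@unitId, responsivity_p = min(p),
               p_window = p[["p_window"]], p_interaction = p[["p_interaction"]],
               fano = fano, max_net_rate = max_net, selectivity_p = sel_p,
               reliability = rel, bsi = bsi, bsi_response_p = bsi_resp_p,
               pass_responsive = pass[["responsive"]],
               pass_stable = pass[["stable"]],
               pass_driven = pass[["driven"]],
               pass_selective = pass[["selective"]],
               pass_reliable = pass[["reliable"]],
               pass_body_selective = pass[["body_selective"]],
               passed = all(pass))
  })
  do.call(rbind, rows)
}
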