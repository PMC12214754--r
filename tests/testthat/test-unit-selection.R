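test_that("responsivity ANOVA matches the aov split-plot oracle", {
  set.seed(2)
  nS <- 6
  nT <- 5
  base <- matrix(rnorm(nT * nS, 10, 2), nT, nS)
  resp <- matrix(rnorm(nT * nS, 12, 2), nT, nS) +
    rep(seq_len(nS), each = nT) * 0.5
  p <- responsivityAnova(base, resp)
  df <- data.frame(
    y = c(as.vector(base), as.vector(resp)),
    window = rep(c("b", "r"), each = nT * nS),
    stim = factor(rep(rep(seq_len(nS), each = nT), 2)),
    pres = factor(rep(seq_len(nT * nS), 2)))
  a <- summary(stats::aov(y ~ window * stim + Error(pres), data = df))
  within <- a[["Error: Within"]][[1]]
  rn <- trimws(rownames(within))
  expect_equal(unname(p["p_window"]),
               within[match("window", rn), "Pr(>F)"], tolerance = 1e-10)
  expect_equal(unname(p["p_interaction"]),
               within[match("window:stim", rn), "Pr(>F)"], tolerance = 1e-10)
})

test_that("responsivity detects forced window and interaction effects", {
  set.seed(3)
  base <- matrix(rnorm(8 * 20, 10, 0.01), 8, 20)
  resp <- base + 10
  p <- responsivityAnova(base, resp)
  expect_lt(p["p_window"], 1e-10)
  # stimulus-dependent increment, constant baseline
  resp2 <- base + matrix(rep(seq_len(20), each = 8), 8, 20) +
    matrix(rnorm(160, sd = 0.1), 8, 20)
  expect_lt(responsivityAnova(base, resp2)["p_interaction"], 0.05)
  expect_error(responsivityAnova(base[, 1, drop = FALSE],
                                 resp[, 1, drop = FALSE]),
               "insufficient-data")
})

test_that("responsivity OR-rule holds its null rejection rate", {
  set.seed(4)
  rej <- mean(replicate(1000, {
    b <- matrix(rnorm(4 * 10, 10, 2), 4, 10)
    r <- matrix(rnorm(4 * 10, 10, 2), 4, 10)
    min(responsivityAnova(b, r)) < 0.05
  }))
  # two positively dependent tests at alpha = 0.05: between 0.05 and 0.0975,
  # plus Monte Carlo slack at n = 1000
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.115)
})

test_that("the Fano slope recovers the generative count dispersion", {
  set.seed(5)
  mu <- seq(1, 20, length.out = 20)
  counts <- vapply(mu, function(m) stats::rpois(10000, m), numeric(10000))
  expect_equal(fanoFactor(counts / 0.2, windowS = 0.2), 1, tolerance = 0.1)
  # doubled Poisson counts: var = 4 mu vs mean 2 mu -> slope 2 (oracle:
  # brute-force simulation of the variance/mean relation)
  counts2 <- 2 * vapply(mu, function(m) stats::rpois(10000, m),
                        numeric(10000))
  expect_equal(fanoFactor(counts2 / 0.2, windowS = 0.2), 2, tolerance = 0.2)
  # deterministic counts -> slope 0
  det <- matrix(rep(seq_len(10), each = 4), 4, 10)
  expect_equal(fanoFactor(det / 0.2, windowS = 0.2), 0, tolerance = 1e-12)
  expect_error(fanoFactor(matrix(5, 4, 10)), "insufficient-data")
})

test_that("selectivity test calibrates under the null and detects effects", {
  set.seed(6)
  p_null <- replicate(1000, {
    selectivityTest(matrix(rnorm(10 * 20, 10, 2), 10, 20))
  })
  rej <- mean(p_null < 0.05)
  expect_gt(rej, 0.032)
  expect_lt(rej, 0.072)
  # rates scale with the stimulus -> overwhelming selectivity
  strong <- matrix(rnorm(10 * 20, 10, 1), 10, 20) +
    rep(seq(0, 95, by = 5), each = 10)
  expect_lt(selectivityTest(strong), 1e-10)
  # a single 10x stimulus among 8 is detected too
  one <- matrix(rnorm(10 * 8, 10, 1), 10, 8)
  one[, 3] <- one[, 3] * 10
  expect_lt(selectivityTest(one), 0.01)
  expect_error(selectivityTest(matrix(1:10, 1, 10)), "insufficient-data")
})

test_that("split-half reliability has the documented limiting behavior", {
  set.seed(7)
  m <- matrix(rep(rnorm(40, 10, 3), each = 6), 6, 40)
  expect_equal(splitHalfReliability(m, nSplits = 10, seed = 1), 1)
  # Spearman-Brown of r = 0.5 is 2/3 (closed form sanity via correction)
  expect_equal(2 * 0.5 / (1 + 0.5), 2 / 3)
  # stimulus-independent noise: median |r| below 0.1 across units
  rels <- vapply(seq_len(100), function(i) {
    splitHalfReliability(matrix(rnorm(6 * 300, 10, 2), 6, 300),
                         nSplits = 20, seed = i)
  }, numeric(1))
  expect_lt(median(abs(rels)), 0.1)
  expect_error(splitHalfReliability(matrix(1, 1, 10)), "insufficient-data")
  expect_error(splitHalfReliability(matrix(1, 4, 10), 5, 1),
               "undefined-correlation")
})

test_that("odd trial counts split with a randomly assigned extra trial", {
  set.seed(8)
  m <- matrix(rnorm(5 * 30, 10, 2), 5, 30) +
    rep(rnorm(30, 0, 5), each = 5)
  r <- splitHalfReliability(m, nSplits = 50, seed = 3)
  expect_true(is.finite(r) && r > 0.5)
})

test_that("selection recovers a planted population composition", {
  b <- fx_basis("3D_VD", small = TRUE)
  X <- fx_mat("3D_VD", small = TRUE)
  strong <- simulateEncodingUnits(b, X, 30, gain = 40, nTrials = 8,
                                  baseline = 10, seed = 21)
  noisy <- simulateEncodingUnits(b, X, 10, gain = 0, nTrials = 8,
                                 baseline = 10, seed = 22)
  # unresponsive: response window indistinguishable from baseline and weak
  unresp <- lapply(1:10, function(i) {
    u <- noisy[[1]]
    br <- matrix(stats::rpois(8 * 128, 0.2 * 1) / 0.2, 8, 128)
    rr <- matrix(stats::rpois(8 * 128, 0.2 * 1) / 0.2, 8, 128)
    methods::new("UnitRecording", unitId = sprintf("dead_%02d", i),
                 responseRates = rr, baselineRates = br,
                 categoryRates = NULL, groundTruth = list())
  })
  rep <- selectUnits(c(strong, noisy, unresp), seed = 31)
  expect_equal(sum(rep$passed), 30)
  expect_true(all(rep$passed[1:30]))
  # thresholds relaxed to +/- infinity pass everything
  loose <- list(responsivity_alpha = Inf, fano_max = Inf, min_net_rate = -Inf,
                selectivity_alpha = Inf, min_reliability = -Inf,
                min_bsi = -Inf, bsi_alpha = Inf)
  expect_true(all(selectUnits(c(strong[1:3], noisy[1:3]), loose,
                              seed = 32)$passed))
  # an unattainable reliability threshold rejects everything
  none <- selectUnits(strong[1:5], list(min_reliability = 1.01), seed = 33)
  expect_false(any(none$passed))
})

test_that("tightening any threshold never admits more units", {
  b <- fx_basis("3D_VD", small = TRUE)
  X <- fx_mat("3D_VD", small = TRUE)
  units <- simulateEncodingUnits(b, X, 20, gain = 3, nTrials = 6, seed = 41)
  base <- selectUnits(units, seed = 51)
  tighter <- list(
    list(responsivity_alpha = 0.01), list(fano_max = 1.2),
    list(min_net_rate = 12), list(selectivity_alpha = 0.01),
    list(min_reliability = 0.8))
  for (th in tighter) {
    expect_lte(sum(selectUnits(units, th, seed = 51)$passed),
               sum(base$passed))
  }
})

test_that("the BSI equals its closed forms on constructed category rates", {
  mk <- function(body, nonbody) {
    simulateCategoryResponses(body, nonbody, noise = "none", seed = 1)
  }
  expect_equal(computeBsi(mk(2, 1)), 1 / 3, tolerance = 1e-12)
  expect_equal(computeBsi(mk(5, 5)), 0, tolerance = 1e-12)
  expect_equal(computeBsi(mk(3, 0)), 1, tolerance = 1e-12)
})
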