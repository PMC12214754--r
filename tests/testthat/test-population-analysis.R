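test_that("variance partitioning satisfies its algebraic identity", {
  set.seed(3)
  Za <- fx_scores("3D_VD", small = TRUE)
  Zb <- matrix(rnorm(nrow(Za) * 8), ncol = 8)
  y <- drop(Za %*% rnorm(10)) + 0.3 * drop(Zb %*% rnorm(8)) +
    rnorm(nrow(Za), sd = 0.3)
  fa <- fitPcrCv(Za, y, seed = 4)
  fb <- fitPcrCv(Zb, y, seed = 4)
  fc <- fitCombinedModel(Za, Zb, y, seed = 4)
  vp <- variancePartition(fa, fb, fc)
  expect_equal(vp@uniqueA + vp@uniqueB + vp@shared, vp@r2Combined,
               tolerance = 1e-12)
  # mismatched folds are rejected
  expect_error(variancePartition(fa, fitPcrCv(Zb, y, seed = 5), fc),
               "fold assignment")
})

test_that("partition components reflect planted dependencies", {
  set.seed(5)
  Za <- fx_scores("3D_VD", small = TRUE)
  Zb <- matrix(rnorm(nrow(Za) * 8), ncol = 8)
  # response driven only by bank a, noise-free
  y <- drop(Za %*% rnorm(10))
  fa <- fitPcrCv(Za, y, seed = 6)
  fb <- fitPcrCv(Zb, y, seed = 6)
  fc <- fitCombinedModel(Za, Zb, y, seed = 6)
  vp <- variancePartition(fa, fb, fc)
  expect_lt(abs(vp@uniqueB), 0.02)
  expect_lt(abs(vp@shared - vp@r2B), 0.02)
  # identical banks share everything
  fdup <- fitCombinedModel(Za, Za, y, seed = 6)
  vdup <- variancePartition(fa, fa, fdup)
  expect_lt(abs(vdup@uniqueA), 0.02)
  expect_lt(abs(vdup@uniqueB), 0.02)
  expect_lt(abs(vdup@shared - vdup@r2Combined), 0.02)
})

test_that("axis clustering finds planted structure", {
  set.seed(7)
  g1 <- matrix(rnorm(10 * 5, 0, 0.05), 10, 5)
  g2 <- matrix(rnorm(10 * 5, 0, 0.05), 10, 5)
  g2[, 1] <- g2[, 1] + 5 # separation ~ 100x internal spread
  cl <- clusterAxes(rbind(g1, g2))
  labs <- clusterLabels(cl)
  expect_equal(length(unique(labs)), 2)
  expect_false(any(labs == -1))
  expect_true(all(labs[1:10] == labs[1]) && all(labs[11:20] == labs[11]))
  expect_equal(nrow(cl@summary), 2)
  expect_equal(sort(cl@summary$n), c(10L, 10L))

  # identical axes collapse to a single cluster
  same <- clusterAxes(matrix(1, 8, 4))
  expect_equal(unique(clusterLabels(same)), 1L)

  # one isolated axis far from a tight group is noise
  iso <- clusterAxes(rbind(matrix(rnorm(30, 0, 0.05), 10, 3),
                           c(50, 50, 50)))
  expect_equal(clusterLabels(iso)[11], -1L)
  expect_error(clusterAxes(matrix(1, 1, 3)), "insufficient-data")
})

test_that("clustering matches the scikit-learn reference implementation", {
  set.seed(11)
  X <- matrix(rnorm(35 * 5), 35, 5)
  ours <- clusterLabels(clusterAxes(X))
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(X, csv, row.names = FALSE)
  script <- paste0(
    "import pandas as pd; from sklearn.cluster import HDBSCAN; ",
    "X = pd.read_csv('", csv, "').values; ",
    "print(' '.join(map(str, HDBSCAN(min_cluster_size=2, min_samples=2)",
    ".fit(X).labels_)))")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = FALSE))
  theirs <- as.integer(strsplit(out[length(out)], " ")[[1]])
  theirs[theirs >= 0] <- theirs[theirs >= 0] + 1L # 0- vs 1-based labels
  expect_true(same_partition(ours, theirs))
})

test_that("clustering respects the R2 gate and is deterministic", {
  set.seed(13)
  betas <- rbind(matrix(rnorm(12 * 4, 0, 0.05), 12, 4),
                 matrix(rnorm(12 * 4, 3, 0.05), 12, 4))
  r2 <- c(rep(0.6, 12), rep(0.1, 12)) # second group gated out
  cl <- clusterAxes(betas, r2 = r2)
  expect_true(all(is.na(clusterLabels(cl)[13:24])))
  expect_true(all(!is.na(clusterLabels(cl)[1:12])))
  cl2 <- clusterAxes(betas, r2 = r2)
  expect_identical(clusterLabels(cl), clusterLabels(cl2))
  # medoid minimizes the summed within-cluster distance
  m <- cl@summary$medoid[1]
  members <- which(!is.na(clusterLabels(cl)) &
                     clusterLabels(cl) == cl@summary$cluster[1])
  D <- as.matrix(dist(betas))
  expect_equal(sum(D[m, members]),
               min(rowSums(D[members, members, drop = FALSE])))
})

test_that("decoding is perfect for separable populations and fair in format", {
  set.seed(17)
  nPoses <- 10
  pose <- rep(seq_len(nPoses), each = 16)
  rates <- lapply(1:8, function(u) {
    m <- 10 + 5 * sin(seq_len(nPoses) + u)
    matrix(rep(m[pose], each = 3), 3, length(pose))
  })
  d <- decodePoses(rates, pose, nResamples = 2, seed = 1)
  expect_equal(d@accuracy, 100)
  expect_equal(unname(diag(confusionMatrix(d))), rep(100, nPoses))
  expect_equal(unname(colSums(confusionMatrix(d))), rep(100, nPoses),
               tolerance = 1e-9)
  expect_equal(d@chanceLevel, 10)
  expect_error(decodePoses(rates, pose[-1]), "invalid-argument")
  expect_error(decodePoses(rates, pose, classifier = "nope"))
})

test_that("label-permuted decoding of noise sits at chance", {
  set.seed(19)
  nPoses <- 45
  pose <- rep(seq_len(nPoses), each = 16)
  rates <- lapply(1:6, function(u) matrix(rnorm(2 * 720, 10, 2), 2, 720))
  perm <- sample(pose)
  d <- decodePoses(rates, perm, nResamples = 4, pseudoTrialsPerClass = 6,
                   seed = 2)
  # binomial sd of the mean accuracy around 100/45
  n_dec <- 45 * 6 * 4
  sd3 <- 3 * sqrt((100 / 45) * (100 - 100 / 45) / n_dec)
  expect_lt(abs(d@accuracy - 100 / 45), sd3)
  expect_equal(d@chanceLevel, 100 / 45, tolerance = 1e-12)
})

test_that("the label-permutation null brackets chance and real signal", {
  set.seed(23)
  nPoses <- 6
  pose <- rep(seq_len(nPoses), each = 16)
  rates <- lapply(1:6, function(u) {
    m <- 10 + 4 * sin(seq_len(nPoses) * u)
    matrix(rep(m[pose], each = 2), 2, length(pose)) +
      matrix(rnorm(2 * length(pose), 0, 1), 2, length(pose))
  })
  d <- decodePoses(rates, pose, nResamples = 2, nLabelPerms = 5,
                   pseudoTrialsPerClass = 8, seed = 3)
  expect_gt(d@accuracy, d@permutationMax)
})

test_that("decoding accuracy is non-decreasing in population size", {
  set.seed(29)
  nPoses <- 8
  pose <- rep(seq_len(nPoses), each = 16)
  all_rates <- lapply(1:60, function(u) {
    m <- 10 + rnorm(nPoses, 0, 1.5)
    matrix(rep(m[pose], each = 2), 2, length(pose)) +
      matrix(rnorm(2 * length(pose), 0, 4), 2, length(pose))
  })
  accs <- vapply(c(6, 20, 60), function(n) {
    decodePoses(all_rates[seq_len(n)], pose, nResamples = 4,
                pseudoTrialsPerClass = 10, seed = 4)@accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})

test_that("the linear SVM variant agrees with the template classifier", {
  set.seed(31)
  nPoses <- 5
  pose <- rep(seq_len(nPoses), each = 16)
  rates <- lapply(1:6, function(u) {
    m <- 10 + 5 * sin(seq_len(nPoses) + u)
    matrix(rep(m[pose], each = 2), 2, length(pose))
  })
  d <- decodePoses(rates, pose, classifier = "linear_svm", nResamples = 1,
                   pseudoTrialsPerClass = 4, seed = 5)
  expect_gt(d@accuracy, 90)
})
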