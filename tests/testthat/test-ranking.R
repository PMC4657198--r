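# Regression rankers: training, prediction, cross-validation,
# serialization, the shipped hetero-dimer weights.

fakeFeatures <- function(n, seed, d = 4) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  colnames(X) <- c("z_svc", "z_nbc", "z_potential", "z_energy",
                   "z_cbs")[seq_len(d)]
  data.frame(pose_id = sprintf("p%04d", seq_len(n)), X,
             stringsAsFactors = FALSE)
}

test_that("linear training recovers planted weights", {
  f <- fakeFeatures(400, seed = 1)
  y <- 2 * f$z_svc + 1e-9 * rnorm(400)
  m <- trainRanker(f, setNames(y, f$pose_id), kind = "linear")
  w <- m@fit$weights
  expect_equal(unname(w["z_svc"]), 2, tolerance = 1e-3)
  expect_lt(max(abs(w[names(w) != "z_svc"])), 1e-3)
  expect_lt(abs(m@fit$intercept), 1e-3)

  # duplicating the training set leaves the least-squares fit unchanged
  f2 <- rbind(f, transform(f, pose_id = paste0(pose_id, "_dup")))
  y2 <- setNames(c(y, y), f2$pose_id)
  m2 <- trainRanker(f2, y2, kind = "linear")
  expect_equal(m2@fit$weights, m@fit$weights, tolerance = 1e-10)
})

test_that("linear weights land within 3 standard errors across seeds", {
  truth <- c(z_svc = 1.5, z_nbc = -0.8, z_potential = 0.3,
             z_energy = 0.6)
  ok <- logical(0)
  for (seed in 1:20) {
    f <- fakeFeatures(500, seed = seed)
    X <- as.matrix(f[, names(truth)])
    y <- drop(X %*% truth) + rnorm(500, sd = 0.5)
    m <- trainRanker(f, setNames(y, f$pose_id), kind = "linear")
    lmfit <- lm(y ~ X)  # reference standard errors
    se <- coef(summary(lmfit))[-1, "Std. Error"]
    ok <- c(ok, abs(m@fit$weights - truth) <= 3 * se)
  }
  # a 3-sigma band should capture essentially all recoveries
  expect_gt(mean(ok), 0.97)
})

test_that("RBF SVR fits a smooth function below the noise floor", {
  set.seed(12)
  n <- 300
  f <- data.frame(pose_id = sprintf("p%03d", 1:n),
                  z_svc = seq(-2, 2, length.out = n))
  sigma <- 0.15
  y <- sin(2 * f$z_svc) + rnorm(n, sd = sigma)
  m <- trainRanker(f, setNames(y, f$pose_id), kind = "svr_rbf",
                   featureOrder = "z_svc",
                   hyperparams = list(gamma = 2, cost = 10,
                                      epsilon = 0.05))
  pred <- poseRank:::.predictRaw(m, as.matrix(f[, "z_svc", drop = FALSE]))
  rmseToTruth <- sqrt(mean((pred - sin(2 * f$z_svc))^2))
  expect_lt(rmseToTruth, sigma)
})

test_that("ranking sorts ascending with a stable pose-id tie-break", {
  m <- defaultHeteroModel("irmsd")
  f <- fakeFeatures(5, seed = 3)
  f[] <- f  # constant features -> constant predictions
  f[, -1] <- 0
  r <- predictRank(m, f)
  expect_identical(r$pose_id, sort(f$pose_id))
  expect_identical(r$rank, 1:5)

  one <- fakeFeatures(1, seed = 4)
  expect_identical(predictRank(m, one)$rank, 1L)

  # a linear model's ranking equals ordering by the weighted sum
  # (ascending: this model predicts iRMSD)
  f2 <- fakeFeatures(50, seed = 5)
  r2 <- predictRank(m, f2)
  s <- as.matrix(f2[, m@featureOrder]) %*% m@fit$weights
  expect_identical(r2$pose_id,
                   f2$pose_id[order(s, f2$pose_id)])

  # adding a worst-prediction pose leaves existing ranks unchanged
  worst <- f2[1, ]
  worst$pose_id <- "zzz_worst"
  worst[, m@featureOrder] <- 100  # all weights positive: huge predicted iRMSD
  r3 <- predictRank(m, rbind(f2, worst))
  expect_identical(r3$pose_id[r3$rank <= 50], r2$pose_id)
  expect_identical(r3$pose_id[51], "zzz_worst")

  expect_error(predictRank(m, f2[, -2]), "lacks attribute")
})

test_that("the shipped hetero model carries the published weights", {
  m <- defaultHeteroModel()
  expect_identical(m@kind, "linear")
  expect_identical(m@featureOrder,
                   c("z_svc", "z_nbc", "z_potential", "z_energy"))
  expect_identical(unname(m@fit$weights), c(171.9, 891.8, 122.7, 2.2))
  expect_identical(m@fit$intercept, 0)
  f <- withr::local_tempfile(fileext = ".json")
  writeRankingModel(m, f)
  m2 <- readRankingModel(f)
  expect_identical(m2@fit$weights, m@fit$weights)
  expect_identical(m2@featureOrder, m@featureOrder)
  expect_identical(m2@trainingMeta$orientation, "quality")
  # both orientations produce reversed orders on the same features
  fx <- fakeFeatures(10, seed = 9)
  rq <- predictRank(defaultHeteroModel("quality"), fx)
  ri <- predictRank(defaultHeteroModel("irmsd"), fx)
  expect_identical(rq$pose_id, rev(ri$pose_id))
})

test_that("SVR models serialize losslessly for prediction", {
  f <- fakeFeatures(120, seed = 6)
  y <- setNames(f$z_svc^2 + 0.5 * f$z_nbc + rnorm(120, sd = 0.1),
                f$pose_id)
  m <- trainRanker(f, y, kind = "svr_rbf")
  # the stored support-vector expansion must agree with the fitted
  # libsvm object's own predictions
  X <- as.matrix(f[, m@featureOrder])
  expect_equal(unname(poseRank:::.predictRaw(m, X)),
               unname(predict(m@fit$svm, X)), tolerance = 1e-10)
  fp <- withr::local_tempfile(fileext = ".json")
  writeRankingModel(m, fp)
  m2 <- readRankingModel(fp)
  expect_equal(predictRank(m2, f), predictRank(m, f), tolerance = 1e-12)
})

test_that("cross-validation never leaks a target into its own model", {
  targets <- lapply(1:4, function(i) {
    f <- fakeFeatures(30, seed = 100 + i)
    list(features = f,
         labels = setNames(abs(f$z_svc) * 3 + rnorm(30, sd = 0.2),
                           f$pose_id))
  })
  names(targets) <- paste0("t", 1:4)
  cv <- crossValidate(targets, kind = "linear", seed = 11)
  expect_setequal(names(cv$rankings), names(targets))
  for (tn in names(targets)) {
    f <- cv$folds[tn]
    trained <- cv$models[[f]]@trainingMeta$trainTargets
    expect_false(tn %in% trained)
  }
  # determinism of the fold split
  cv2 <- crossValidate(targets, kind = "linear", seed = 11)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$rankings, cv2$rankings)
  expect_error(crossValidate(targets[1], kind = "linear"), "fewer targets")
})
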