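# Pose-quality metrics and ranking-quality curves.

test_that("irmsd is zero on self and equals |t| for a pure translation", {
  native <- c2pose20()
  expect_lt(irmsd(native, native), 1e-9)
  for (t in list(c(3, 0, 0), c(0, -4, 3))) {
    lig <- poseRank:::.transformChain(ligand(native), t = t)
    pose <- toyPose(receptor(native), lig)
    expect_equal(irmsd(pose, native), sqrt(sum(t^2)), tolerance = 1e-9)
  }
})

test_that("irmsd is invariant to rigid motion of the whole pose", {
  native <- c2pose20()
  ens <- makeDecoyEnsemble(native, 3, c(2, 8, 15), seed = 21)
  for (p in ens$poses) {
    R <- poseRank:::.rotationMatrix(c(2, -1, 1), 2.2)
    moved <- poseRank:::.transformPose(p, R = R, t = c(12, 5, -9))
    expect_equal(irmsd(moved, native), irmsd(p, native),
                 tolerance = 1e-9)
  }
})

test_that("irmsd agrees with an independent quaternion superposition", {
  native <- c2pose20()
  ens <- makeDecoyEnsemble(native, 6, c(1, 3, 6, 10, 18, 25), seed = 13)
  for (p in ens$poses) {
    # also rotate the whole pose so the receptor superposition is
    # non-trivial for both algorithms
    moved <- poseRank:::.transformPose(
      p, R = poseRank:::.rotationMatrix(c(1, 1, 0), 1.3), t = c(4, 4, 4))
    expect_equal(irmsd(moved, native), quatIrmsd(moved, native),
                 tolerance = 1e-6)
  }
})

test_that("contact quality reproduces the hand-computed MCC case", {
  # universe engineered to TP=3, FP=1, FN=1, TN=5: receptor 2 x ligand 5
  # native contacts: (1,1) (1,2) (1,3) (2,1); pose: (1,1) (1,2) (1,3) (1,4)
  resAt <- function(xy) rbind(c(xy, 0))
  rec <- toyChain("A", list(resAt(c(0, 0)), resAt(c(0, 40))))
  mkLig <- function(contacts) {
    # ligand residue j contacts receptor residue i when placed near it
    pos <- list(`1` = c(5, 0), `2` = c(-5, 0), `3` = c(0, 5),
                `4` = c(0, -5), far = c(200, 200))
    coords <- lapply(1:5, function(j) {
      at <- contacts[[as.character(j)]]
      if (is.null(at)) resAt(c(200, 200 + 20 * j))
      else resAt(pos[[at]] + c(0, if (at == "rec2") 40 else 0))
    })
    toyChain("B", coords)
  }
  # native: ligand 1,2,3 near receptor1; ligand 4 near receptor2
  natLig <- toyChain("B", list(resAt(c(5, 0)), resAt(c(-5, 0)),
                               resAt(c(0, 5)), resAt(c(0, 40 + 5)),
                               resAt(c(300, 300))))
  # pose: ligand 1,2,3 near receptor1 (TPs), ligand 5 near receptor1
  # (FP), ligand 4 far from receptor2 (FN)
  poseLig <- toyChain("B", list(resAt(c(5, 0)), resAt(c(-5, 0)),
                                resAt(c(0, 5)), resAt(c(400, 400)),
                                resAt(c(0, -5))))
  native <- toyPose(rec, natLig)
  pose <- toyPose(rec, poseLig)
  cq <- contactQuality(pose, native)
  expect_identical(c(cq$tp, cq$fp, cq$fn, cq$tn), c(3, 1, 1, 5))
  expect_equal(cq$pcs, 14 / 24)
  expect_equal(cq$fnat, 3 / 4)
  expect_equal(cq$fnonnat, 1 / 4)
  # the printed denominator variant differs on the same counts
  cqp <- contactQuality(pose, native, mccVariant = "printed")
  expect_equal(cqp$pcs, 14 / sqrt(4 * 8 * 2 * 6))

  # identity: perfect scores
  self <- contactQuality(native, native)
  expect_equal(c(self$fnat, self$fnonnat, self$pcs), c(1, 0, 1))

  # degenerate: pose with no contacts
  emptyLig <- toyChain("B", lapply(1:5, function(j) resAt(c(900, 900 + 30 * j))))
  deg <- contactQuality(toyPose(rec, emptyLig), native)
  expect_equal(c(deg$fnat, deg$pcs), c(0, 0))
  expect_true(deg$degenerate)
})

test_that("ranking curves match hand enumeration on a synthetic set", {
  # 3 targets, 4 poses each, known ranks and qualities
  mkRank <- function(ids) data.frame(pose_id = ids, pred = seq_along(ids),
                                     rank = seq_along(ids))
  rankings <- list(
    t1 = mkRank(c("a", "b", "c", "d")),
    t2 = mkRank(c("e", "f", "g", "h")),
    t3 = mkRank(c("i", "j", "k", "l")))
  qualities <- list(
    t1 = data.frame(pose_id = c("a", "b", "c", "d"),
                    irmsd = c(1, 9, 12, 30), pcs = c(0.9, 0.2, 0.1, 0)),
    t2 = data.frame(pose_id = c("e", "f", "g", "h"),
                    irmsd = c(20, 3, 11, 30), pcs = c(0.1, 0.6, 0.2, 0)),
    t3 = data.frame(pose_id = c("i", "j", "k", "l"),
                    irmsd = c(15, 14, 13, 12), pcs = c(0.2, 0.2, 0.2, 0.2)))
  # top-2, cutoff 2.5: only t1 has a hit in the top 2 -> 1/3
  ps <- percentageSuccessful(rankings, qualities, "irmsd",
                             cutoffs = c(2.5, 10, Inf), topK = 2)
  expect_equal(ps$pct, c(100 / 3, 200 / 3, 100))
  # pcs criterion at 0.5: t1 (0.9) and t2 (0.6) -> 2/3
  psp <- percentageSuccessful(rankings, qualities, "pcs",
                              cutoffs = 0.5, topK = 2)
  expect_equal(psp$pct, 200 / 3)
  # hit counts at 10 A, top 2: t1 has 2, t2 has 1, t3 has 0
  expect_equal(hitCount(rankings, qualities, 10, topK = 2), 1)
  expect_equal(hitCount(rankings, qualities, 0.5), 0)
  # success rate at 2.5: t1 from n=1; others never
  sr <- successRate(rankings, qualities, "irmsd", 2.5, nMax = 4)
  expect_equal(sr$pct, rep(100 / 3, 4))
  # t3 first hits at rank 3 (irmsd 13 <= 13, inclusive)
  sr13 <- successRate(rankings, qualities, "irmsd", 13, nMax = 4)
  expect_equal(sr13$pct, c(100 / 3, 200 / 3, 100, 100))
  expect_true(all(diff(sr13$pct) >= 0))
  # consistency: percentage successful at top_k = n equals the curve
  expect_equal(percentageSuccessful(rankings, qualities, "irmsd",
                                    13, topK = 4)$pct,
               sr13$pct[4])
  expect_error(percentageSuccessful(list(), list(), "irmsd", 1), "empty")
})

test_that("success-rate curves are monotone on random inputs", {
  set.seed(77)
  rankings <- list(); qualities <- list()
  for (t in 1:6) {
    ids <- sprintf("p%02d", 1:30)
    rankings[[paste0("t", t)]] <- data.frame(
      pose_id = ids, pred = runif(30), rank = sample(30))
    qualities[[paste0("t", t)]] <- data.frame(
      pose_id = ids, irmsd = runif(30, 0, 30), pcs = runif(30))
  }
  sr <- successRate(rankings, qualities, "irmsd", 5, nMax = 30)
  expect_true(all(diff(sr$pct) >= 0))
})

test_that("cbs distribution is the sort-and-count cumulative fraction", {
  expect_equal(cbsDistribution(c(1, 1, 1), thresholds = c(0, 0.5, 1))$fraction,
               c(1, 1, 1))
  expect_equal(cbsDistribution(c(0.2, 0.8), thresholds = 0.5)$fraction, 0.5)
  set.seed(3)
  v <- runif(200)
  d <- cbsDistribution(v, thresholds = seq(0, 1, 0.1))
  ref <- vapply(seq(0, 1, 0.1), function(th) sum(sort(v) >= th) / 200,
                numeric(1))
  expect_equal(d$fraction, ref)
  expect_true(all(diff(d$fraction) <= 0))
})
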