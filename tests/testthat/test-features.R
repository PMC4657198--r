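# Interface scores, potential score, standardization, featurize.

probsFor <- function(chain, p_svc, p_nbc = p_svc) {
  rt <- poseRank:::.residueTable(chain)
  data.frame(chain = chainId(chain), resno = rt$resno, icode = rt$icode,
             p_svc = rep_len(p_svc, nrow(rt)),
             p_nbc = rep_len(p_nbc, nrow(rt)), stringsAsFactors = FALSE)
}

test_that("interface score is the sum of probabilities over the interface", {
  # receptor residues 1 and 2 both contact the ligand, residue 3 does not
  rec <- toyChain("A", list(rbind(c(0, 0, 0)), rbind(c(0, 5, 0)),
                            rbind(c(0, 50, 0))))
  lig <- toyChain("B", list(rbind(c(5, 2, 0))))
  pose <- toyPose(rec, lig)
  probs <- probsFor(rec, c(0.5, 0.25, 0.9))
  expect_equal(as.numeric(interfaceScore(pose, probs, "svc")), 0.75)

  # linearity: doubling every probability doubles the score
  probs2 <- probs
  probs2$p_svc <- probs2$p_svc * 2  # may exceed 1; bypass the reader
  expect_equal(as.numeric(interfaceScore(pose, probs2, "svc")), 1.5)

  # no interface -> 0
  farLig <- toyChain("B", list(rbind(c(500, 0, 0))))
  expect_equal(as.numeric(interfaceScore(toyPose(rec, farLig), probs,
                                         "svc")), 0)

  # missing table entries score 0 with a warning
  short <- probs[1, , drop = FALSE]
  expect_warning(s <- interfaceScore(pose, short, "svc"), "missing")
  expect_equal(as.numeric(s), 0.5)
})

test_that("potential score sums table parameters over site contacts", {
  # single sc-sc contact between an ALA and a GLY pseudo side chain
  rec <- toyChain("A", list(rbind(c(0, 0, 0), c(1, 0, 0))),
                  atomNames = list(c("CA", "CB")), resid = "ALA")
  lig <- toyChain("B", list(rbind(c(5, 0, 0))), atomNames = list("CA"),
                  resid = "GLY")
  pose <- toyPose(rec, lig)
  tbl <- stats::setNames(-1.3, poseRank:::.potKey("ALA", "sc", "GLY", "sc"))
  class(tbl) <- "potentialTable"
  sc <- siteContacts(pose)
  expect_true("sc_sc" %in% sc$class)
  got <- potentialScore(pose, tbl)
  # ALA sc (CB at x=1) to GLY sc (CA fallback at x=5) is 4.0 <= 6.8
  # and is the only site pair present
  expect_equal(as.numeric(got), -1.3)
  expect_identical(attr(got, "nUnknown"), 0L)

  # all-zero table scores 0 on any pose
  zero <- makePotentialTable(seed = 1, sd = 0)
  expect_equal(as.numeric(potentialScore(c2pose20(), zero)), 0)
})

test_that("potential score equals brute-force enumeration times lookup", {
  tbl <- makePotentialTable(seed = 8)
  for (seed in c(2, 6)) {
    pose <- randomPose(nRes = 9, seed = seed, spread = 9)
    ref <- bruteSiteContacts(pose)
    refSum <- if (is.null(ref)) 0 else {
      recA <- poseRank:::.residueTable(receptor(pose))
      ligA <- poseRank:::.residueTable(ligand(pose))
      sum(unclass(tbl)[poseRank:::.potKey(
        recA$resid[ref$recSeqIndex + 1L], ref$recKind,
        ligA$resid[ref$ligSeqIndex + 1L], ref$ligKind)], na.rm = TRUE)
    }
    expect_equal(as.numeric(potentialScore(pose, tbl)), refSum)
  }
})

test_that("potential tables symmetrize and expand the bb class on read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("res_i\tsite_i\tres_j\tsite_j\tvalue",
               "GLY\tsc\tALA\tbb\t2.5",
               "ALA\tsc\tALA\tsc\t-1.0"), f)
  tbl <- readPotentialTable(f)
  u <- unclass(tbl)
  expect_equal(unname(u[poseRank:::.potKey("ALA", "bbO", "GLY", "sc")]), 2.5)
  expect_equal(unname(u[poseRank:::.potKey("GLY", "sc", "ALA", "bbN")]), 2.5)
  expect_equal(unname(u[poseRank:::.potKey("ALA", "sc", "ALA", "sc")]), -1.0)
})

test_that("standardization uses the population sd and handles constants", {
  df <- data.frame(pose_id = c("a", "b", "c"), v = c(1, 2, 3),
                   const = c(5, 5, 5))
  z <- standardizeFeatures(df)
  expect_equal(z$z_v, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(z$z_const, c(0, 0, 0))
  expect_lt(abs(mean(z$z_v)), 1e-12)
  expect_equal(mean(z$z_v^2), 1, tolerance = 1e-12)
  # idempotence: standardizing Z-scores is the identity
  z2 <- standardizeFeatures(data.frame(pose_id = df$pose_id, v = z$z_v))
  expect_equal(z2$z_v, z$z_v, tolerance = 1e-12)
  expect_error(standardizeFeatures(df[1, ]), "at least 2")
})

test_that("featurize yields 5 attributes for homo- and 4 for hetero-dimers", {
  native <- c2pose20()
  ens <- makeDecoyEnsemble(native, 4, c(1, 5, 10, 20), seed = 3)
  probs <- probsFor(receptor(native), 0.5)
  tbl <- makePotentialTable(seed = 2)
  en <- makeEnergyColumn(ens$irmsd, 0.5, seed = 4)
  fh <- featurize(ens$poses, probs, tbl, en, homo = TRUE)
  expect_true(all(c("svc", "nbc", "potential", "energy", "cbs") %in%
                    names(fh)))
  expect_true(all(paste0("z_", c("svc", "nbc", "potential", "energy",
                                 "cbs")) %in% names(fh)))
  ft <- featurize(ens$poses, probs, tbl, en, homo = FALSE)
  expect_false("cbs" %in% names(ft))
  expect_identical(ncol(ft), 1L + 4L + 4L)

  # order-equivariance: permuting the input leaves the output table
  # identical (rows come back sorted by pose id)
  fp <- featurize(rev(ens$poses), probs, tbl, en, homo = TRUE)
  expect_equal(fp, fh)

  # a missing energy is an error
  expect_error(featurize(ens$poses, probs, tbl, en[-2], homo = TRUE),
               "missing external energy")
})
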