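# PDB reading/writing and interaction-site construction.

test_that("write/read round trip preserves inventory and coordinates", {
  pose <- c2pose20()
  f <- withr::local_tempfile(fileext = ".pdb")
  writePosePDB(pose, f)
  back <- readPose(f, c("A", "B"), poseId = "rt")
  for (side in c(receptor, ligand)) {
    a0 <- atoms(side(pose))
    a1 <- atoms(side(back))
    expect_equal(a1$elety, a0$elety)
    expect_equal(a1$resno, a0$resno)
    expect_equal(a1$resid, a0$resid)
    expect_equal(a1$icode, a0$icode)
    expect_equal(a1$x, a0$x, tolerance = 1e-3)
    expect_equal(a1$y, a0$y, tolerance = 1e-3)
    expect_equal(a1$z, a0$z, tolerance = 1e-3)
  }
  lines <- readLines(f)
  expect_identical(sum(startsWith(lines, "TER")), 2L)  # one TER per chain
  # fixed-width: coordinates serialized to 3 decimals
  expect_match(lines[1], "^ATOM  ")
  expect_identical(nchar(lines[1]), 80L)
})

test_that("chain selection returns only the requested chains", {
  pose <- c2pose20()
  f <- withr::local_tempfile(fileext = ".pdb")
  writePosePDB(pose, f)
  only <- readPDBChains(f, chains = "A")
  expect_named(only, "A")
  expect_s4_class(only$A, "ChainModel")
  expect_error(readPDBChains(f, chains = c("A", "Z")), "absent")
  expect_error(readPDBChains(file.path(tempdir(), "nope.pdb")),
               "not found")
})

test_that("parser drops hydrogens and HETATM, keeps highest-occupancy altloc", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  N   ALA A  10    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            1, 0, 0, 0, 1, 0, "N"),
    # two altlocs for CA: B has the higher occupancy and must win
    "ATOM      2  CA AALA A  10       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A  10       2.000   0.000   0.000  0.60  0.00           C",
    # altloc tie on CB: alphabetically first (A) must win
    "ATOM      4  CB AALA A  10       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CB BALA A  10       4.000   0.000   0.000  0.50  0.00           C",
    "ATOM      6  H   ALA A  10       5.000   0.000   0.000  1.00  0.00           H",
    "HETATM    7  O   HOH A 101       6.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  ch <- readPDBChains(f)
  a <- atoms(ch$A)
  expect_setequal(a$elety, c("N", "CA", "CB"))
  expect_equal(a$x[a$elety == "CA"], 2.0)  # occupancy 0.60 altloc
  expect_equal(a$x[a$elety == "CB"], 3.0)  # tie -> altloc A
})

test_that("interaction sites follow the stated conventions", {
  # alanine with a single CB: sc center is the CB position
  ala <- toyChain("A", list(rbind(c(0, 0, 0), c(0.5, 0, 0), c(1, 1, 1))),
                  atomNames = list(c("N", "CA", "CB")))
  s <- buildSites(ala)
  expect_equal(as.numeric(s[1, c("sc.x", "sc.y", "sc.z")]), c(1, 1, 1))
  expect_true(all(is.na(s[1, c("O.x", "O.y", "O.z")])))  # no O atom
  expect_equal(as.numeric(s[1, c("N.x", "N.y", "N.z")]), c(0, 0, 0))

  # glycine: side-chain center falls back to CA
  gly <- toyChain("A", list(rbind(c(2, 2, 2))),
                  atomNames = list("CA"), resid = "GLY")
  sg <- buildSites(gly)
  expect_equal(as.numeric(sg[1, c("sc.x", "sc.y", "sc.z")]), c(2, 2, 2))

  # two side-chain atoms: unweighted mean
  two <- toyChain("A", list(rbind(c(9, 9, 9), c(0, 0, 0), c(2, 0, 0))),
                  atomNames = list(c("CA", "CB", "CG")))
  st <- buildSites(two)
  expect_equal(as.numeric(st[1, c("sc.x", "sc.y", "sc.z")]), c(1, 0, 0))

  # a non-glycine residue with no side-chain atoms gets no sc site
  bare <- toyChain("A", list(rbind(c(0, 0, 0))), atomNames = list("CA"))
  expect_true(all(is.na(buildSites(bare)[1, c("sc.x", "sc.y", "sc.z")])))
})

test_that("mass weighting shifts the side-chain center toward heavy elements", {
  ch <- chainModel("A", elety = c("CA", "CB", "SG"), resid = "CYS",
                   resno = c(1, 1, 1), x = c(9, 0, 2), y = 0, z = 0,
                   elesy = c("C", "C", "S"))
  s0 <- buildSites(ch)
  s1 <- buildSites(ch, massWeighted = TRUE)
  expect_equal(s0$sc.x, 1)
  expect_gt(s1$sc.x, 1)  # sulfur outweighs carbon
})

test_that("coordinates near the width limit serialize at 3 decimals", {
  ch <- chainModel("A", elety = "CA", resid = "ALA", resno = 1,
                   x = 123.4567, y = -0.0004, z = 99.9995, elesy = "C")
  pose <- toyPose(ch, chainModel("B", elety = "CA", resid = "ALA",
                                 resno = 1, x = 0, y = 0, z = 0,
                                 elesy = "C"))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePosePDB(pose, f)
  line <- readLines(f)[1]
  expect_identical(substr(line, 31, 38), " 123.457")
})
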