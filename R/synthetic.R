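# Synthetic benchmark generation: toy monomers, C2-symmetric dimers,
# decoy ensembles at controlled interface RMSD, interface-probability
# tables of tunable accuracy, random potential tables and energy
# columns with a prescribed rank correlation to pose quality. Every
# generator is a pure function of its seed.

.AA20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
           "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
           "THR", "TRP", "TYR", "VAL")

# map 3-letter code to a plausible side-chain pseudo-atom element
.CB_ELEMENT <- "C"

#' Generate a toy monomer chain
#'
#' Builds a self-avoiding CA trace with an idealized backbone amide
#' nitrogen, carbonyl oxygen and a single pseudo side-chain atom (CB)
#' per residue; glycines carry no CB. The "helix" fold is an ideal
#' helical wind (consecutive CA-CA distance about 3.8 Angstrom); the
#' "coil" fold is a seeded self-avoiding random walk with the same CA
#' step. Atom positions are spaced so no two atoms come closer than
#' 2 Angstrom. Residue types are sampled uniformly from the 20 amino
#' acids using the seed; geometry of the helix is deterministic.
#'
#' @param nResidues number of residues (>= 3).
#' @param fold "helix" or "coil".
#' @param seed integer seed.
#' @param chainId chain identifier (default "A").
#' @return a \linkS4class{ChainModel}.
#' @export
makeMonomer <- function(nResidues, fold = c("helix", "coil"), seed = 1L,
                        chainId = "A") {
  fold <- match.arg(fold)
  if (nResidues < 3L) stop("nResidues must be >= 3")
  .withSeed(seed, {
    resid <- sample(.AA20, nResidues, replace = TRUE)
    for (attempt in 1:50) {
      ca <- if (fold == "helix") .helixTrace(nResidues) else
        .coilTrace(nResidues)
      chain <- .decorateTrace(ca, resid, fold, chainId)
      X <- .coords(chain)
      d2 <- .crossDist2(X, X)
      diag(d2) <- Inf
      if (sqrt(min(d2)) >= 2.0) return(chain)
      if (fold == "helix") break  # deterministic; retrying cannot help
    }
    stop("could not build a clash-free ", fold, " of ", nResidues,
         " residues")
  })
}

.helixTrace <- function(n) {
  i <- seq_len(n) - 1L
  theta <- i * 100 * pi / 180
  cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
}

.coilTrace <- function(n) {
  ca <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    placed <- FALSE
    for (try in 1:500) {
      # bias toward the previous direction to keep the walk extended
      cand <- dir + 0.8 * stats::rnorm(3)
      cand <- cand / sqrt(sum(cand^2))
      pos <- ca[i - 1, ] + 3.8 * cand
      prev <- ca[seq_len(max(1L, i - 2L)), , drop = FALSE]
      if (i == 2L || min(sqrt(rowSums(sweep(prev, 2, pos)^2))) >= 6.0) {
        ca[i, ] <- pos
        dir <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("coil trace could not avoid itself at residue ", i)
  }
  ca
}

# add N, O and CB pseudo-atoms around a CA trace
.decorateTrace <- function(ca, resid, fold, chainId) {
  n <- nrow(ca)
  elety <- character(0); el <- character(0); rn <- integer(0)
  rs <- character(0); xyz <- NULL
  for (i in seq_len(n)) {
    if (fold == "helix") {
      theta <- (i - 1L) * 100 * pi / 180
      dirN <- c(cos(theta + pi / 3), sin(theta + pi / 3), 0)
      dirO <- c(cos(theta - pi / 3), sin(theta - pi / 3), 0)
      dirB <- c(cos(theta), sin(theta), 0)
    } else {
      nxt <- ca[min(i + 1L, n), ] - ca[max(i - 1L, 1L), ]
      t <- nxt / sqrt(sum(nxt^2))
      ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      n1 <- c(t[2] * ref[3] - t[3] * ref[2],
              t[3] * ref[1] - t[1] * ref[3],
              t[1] * ref[2] - t[2] * ref[1])
      n1 <- n1 / sqrt(sum(n1^2))
      n2 <- c(t[2] * n1[3] - t[3] * n1[2],
              t[3] * n1[1] - t[1] * n1[3],
              t[1] * n1[2] - t[2] * n1[1])
      dirN <- n1; dirO <- -n1; dirB <- n2
    }
    at <- rbind(N = ca[i, ] + 2.1 * dirN,
                CA = ca[i, ],
                O = ca[i, ] + 2.1 * dirO)
    ael <- c("N", "C", "O")
    if (resid[i] != "GLY") {
      at <- rbind(at, CB = ca[i, ] + 2.4 * dirB)
      ael <- c(ael, .CB_ELEMENT)
    }
    elety <- c(elety, rownames(at)); el <- c(el, ael)
    rn <- c(rn, rep(i, nrow(at))); rs <- c(rs, rep(resid[i], nrow(at)))
    xyz <- rbind(xyz, at)
  }
  chainModel(chainId, elety = elety, resid = rs, resno = rn,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], elesy = el)
}

.minInterDist <- function(A, B) sqrt(min(.crossDist2(A, B)))

#' Build an exact C2-symmetric homo-dimer pose
#'
#' The second chain is the image of the first under a 180-degree
#' rotation about the given axis; the first chain is shifted
#' perpendicular to the axis until the closest inter-chain heavy-atom
#' distance equals \code{contactGap}. Exact C2 symmetry makes the
#' inter-chain contact map closed under index transposition, so the
#' pose's CBS score is 1 whenever any non-self contact exists.
#'
#' @param chain a \linkS4class{ChainModel} (becomes the receptor,
#'   chain id "A"; the rotated copy is the ligand, chain id "B").
#' @param axis rotation axis direction (unit 3-vector; default z).
#' @param contactGap requested closest inter-chain approach in
#'   Angstrom; must be at least 2 to avoid clashing placement.
#' @param poseId pose identifier.
#' @return a \linkS4class{DimerPose}.
#' @export
makeC2Pose <- function(chain, axis = c(0, 0, 1), contactGap = 4,
                       poseId = "native") {
  if (contactGap < 2) stop("clashing placement: contactGap must be >= 2")
  axis <- axis / sqrt(sum(axis^2))
  # a direction perpendicular to the axis to separate the two copies
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- c(axis[2] * ref[3] - axis[3] * ref[2],
         axis[3] * ref[1] - axis[1] * ref[3],
         axis[1] * ref[2] - axis[2] * ref[1])
  v <- v / sqrt(sum(v^2))
  R180 <- .rotationMatrix(axis, pi)
  gapAt <- function(t) {
    A <- .transformChain(chain, t = t * v)
    B <- .transformChain(A, R = R180)
    .minInterDist(.coords(A), .coords(B))
  }
  lo <- 0; hi <- 10
  while (gapAt(hi) < contactGap && hi < 1e4) hi <- hi * 2
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (gapAt(mid) < contactGap) lo <- mid else hi <- mid
  }
  A <- .transformChain(chain, t = hi * v)
  A@chainId <- "A"
  B <- .transformChain(A, R = R180)
  B@chainId <- "B"
  new("DimerPose", poseId = poseId, receptor = A, ligand = B,
      externalEnergy = NA_real_)
}

# fast iRMSD for a fixed receptor: RMS displacement of the native
# ligand interface CA atoms (receptor superposition is the identity)
.fastLigandIrmsd <- function(ifaceCA0, ligand, ifaceIdx) {
  ca <- ligand@atoms[ligand@atoms$elety == "CA", , drop = FALSE]
  X <- cbind(ca$x, ca$y, ca$z)[ifaceIdx, , drop = FALSE]
  sqrt(mean(rowSums((X - ifaceCA0)^2)))
}

#' Generate a decoy ensemble at controlled interface RMSD
#'
#' Each pose keeps the native receptor and applies a random rigid
#' transform (rotation about an axis through the ligand interface
#' centroid plus a translation) to the native ligand. The transform
#' magnitude is bisected until the realized iRMSD matches the
#' requested target within \code{tol}. A target of 0 returns the
#' native ligand placement.
#'
#' @param native a \linkS4class{DimerPose} (the experimental
#'   arrangement).
#' @param nPoses number of poses.
#' @param irmsdTargets numeric vector of requested iRMSD values,
#'   recycled to \code{nPoses}.
#' @param seed integer seed.
#' @param tol accepted |realized - requested| (Angstrom).
#' @param cutoff interface cutoff used for the iRMSD definition.
#' @return list with \code{poses} (list of DimerPose, ids pose0001..)
#'   and \code{irmsd} (named numeric of realized values).
#' @export
makeDecoyEnsemble <- function(native, nPoses, irmsdTargets, seed = 1L,
                              tol = 0.1, cutoff = 10) {
  irmsdTargets <- rep_len(irmsdTargets, nPoses)
  ifaceL <- interfaceResidues(native, cutoff)$ligand
  if (nrow(ifaceL) == 0L) stop("native pose has no ligand interface")
  lig0 <- native@ligand
  caAll <- lig0@atoms[lig0@atoms$elety == "CA", , drop = FALSE]
  ifaceIdx <- match(.resKey(ifaceL$resno, ifaceL$icode),
                    .resKey(caAll$resno, caAll$icode))
  ifaceIdx <- ifaceIdx[!is.na(ifaceIdx)]
  if (length(ifaceIdx) == 0L) stop("ligand interface has no CA atoms")
  ifaceCA0 <- cbind(caAll$x, caAll$y, caAll$z)[ifaceIdx, , drop = FALSE]
  center <- colMeans(ifaceCA0)
  recXYZ <- .coords(native@receptor)
  .withSeed(seed, {
    poses <- vector("list", nPoses)
    realized <- numeric(nPoses)
    for (i in seq_len(nPoses)) {
      target <- irmsdTargets[i]
      id <- sprintf("pose%04d", i)
      if (target == 0) {
        poses[[i]] <- new("DimerPose", poseId = id,
                          receptor = native@receptor, ligand = lig0,
                          externalEnergy = NA_real_)
        realized[i] <- 0
        next
      }
      done <- FALSE
      for (attempt in 1:50) {
        axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
        tdir <- stats::rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
        rotRate <- stats::runif(1, 0, 0.04)  # rad per Angstrom of s
        ligAt <- function(s) {
          .transformChain(lig0, R = .rotationMatrix(axis,
                                                    min(s * rotRate, 2.5)),
                          t = s * tdir, center = center)
        }
        irAt <- function(s) .fastLigandIrmsd(ifaceCA0, ligAt(s), ifaceIdx)
        hi <- max(2 * target, 1)
        ok <- TRUE
        while (irAt(hi) < target) {
          hi <- hi * 2
          if (hi > 1e4) { ok <- FALSE; break }
        }
        if (!ok) next
        lo <- 0
        for (k in 1:50) {
          mid <- (lo + hi) / 2
          if (irAt(mid) < target) lo <- mid else hi <- mid
        }
        lig <- ligAt(hi)
        r <- irAt(hi)
        # avoid gross steric overlap with the receptor
        if (abs(r - target) <= tol &&
            .minInterDist(recXYZ, .coords(lig)) > 1.5) {
          poses[[i]] <- new("DimerPose", poseId = id,
                            receptor = native@receptor, ligand = lig,
                            externalEnergy = NA_real_)
          realized[i] <- r
          done <- TRUE
          break
        }
      }
      if (!done) {
        stop("could not reach iRMSD target ", target, " for pose ", i)
      }
    }
    names(realized) <- vapply(poses, poseId, character(1))
    list(poses = poses, irmsd = realized)
  })
}

# expected MCC when true labels are flipped with per-class rate (1 - q)
.expectedFlipMcc <- function(q, P, N) {
  tp <- P * q; fn <- P * (1 - q); tn <- N * q; fp <- N * (1 - q)
  .mcc(tp, fp, fn, tn)
}

#' Generate an interface-probability table of tunable accuracy
#'
#' True interface residues of the receptor (from the native complex,
#' 10 Angstrom criterion) receive high probabilities and the rest low
#' ones, with a calibrated number of label flips so that thresholding
#' the probabilities at 0.5 realizes a Matthews correlation close to
#' \code{targetMcc} against the true interface. The flip rate is
#' solved from the expected-MCC curve and applied as an exact count
#' per class, so the realized MCC is deterministic given the seed; the
#' SVC and NBC columns get independent flip sets. Realized MCCs are
#' attached as attributes \code{mcc_svc} and \code{mcc_nbc}.
#'
#' @param native a \linkS4class{DimerPose}.
#' @param targetMcc requested MCC in [0, 1).
#' @param seed integer seed.
#' @param cutoff interface cutoff (Angstrom).
#' @return data.frame (chain, resno, icode, p_svc, p_nbc) in the
#'   format of \code{\link{readProbabilityTable}}.
#' @export
makeProbabilityTable <- function(native, targetMcc, seed = 1L,
                                 cutoff = 10) {
  if (targetMcc < 0 || targetMcc >= 1) stop("targetMcc must be in [0, 1)")
  rec <- native@receptor
  rt <- .residueTable(rec)
  iface <- interfaceResidues(native, cutoff)$receptor
  isPos <- .resKey(rt$resno, rt$icode) %in%
    .resKey(iface$resno, iface$icode)
  P <- sum(isPos); N <- sum(!isPos)
  if (P == 0L || N == 0L) {
    stop("infeasible target: receptor has no interface/non-interface split")
  }
  q <- if (targetMcc == 0) 0.5 else {
    stats::uniroot(function(qq) .expectedFlipMcc(qq, P, N) - targetMcc,
                   c(0.5 + 1e-9, 1 - 1e-12), tol = 1e-10)$root
  }
  nFlipP <- round((1 - q) * P)
  nFlipN <- round((1 - q) * N)
  .withSeed(seed, {
    oneColumn <- function() {
      lab <- isPos
      fp_i <- sample(which(isPos), nFlipP)
      fn_i <- sample(which(!isPos), nFlipN)
      lab[fp_i] <- FALSE
      lab[fn_i] <- TRUE
      p <- numeric(length(lab))
      p[lab] <- stats::runif(sum(lab), 0.55, 0.95)
      p[!lab] <- stats::runif(sum(!lab), 0.05, 0.45)
      tp <- sum(lab & isPos); fp <- sum(lab & !isPos)
      fn <- sum(!lab & isPos); tn <- sum(!lab & !isPos)
      list(p = p, mcc = .mcc(tp, fp, fn, tn))
    }
    svc <- oneColumn()
    nbc <- oneColumn()
    if (targetMcc > 0 &&
        (abs(svc$mcc - targetMcc) > 0.05 || abs(nbc$mcc - targetMcc) > 0.05)) {
      stop("infeasible MCC target ", targetMcc, " for this chain size ",
           "(realized ", round(svc$mcc, 3), " / ", round(nbc$mcc, 3), ")")
    }
    out <- data.frame(chain = rec@chainId, resno = rt$resno,
                      icode = rt$icode, p_svc = svc$p, p_nbc = nbc$p,
                      stringsAsFactors = FALSE)
    attr(out, "mcc_svc") <- svc$mcc
    attr(out, "mcc_nbc") <- nbc$mcc
    out
  })
}

#' Generate a random docking-potential parameter table
#'
#' Draws one parameter per unordered pair of (residue type,
#' interaction-site class) tokens over the 20 amino acids and the site
#' classes sc and bb (bb expanded to both backbone sites), from a
#' normal distribution. A stand-in for an externally supplied
#' optimized parameter set, exercising the lookup machinery.
#'
#' @param seed integer seed.
#' @param sd standard deviation of the parameter values.
#' @return a \code{potentialTable} (see
#'   \code{\link{readPotentialTable}}).
#' @export
makePotentialTable <- function(seed = 1L, sd = 1) {
  tokens <- c(outer(.AA20, c("sc", "bbO", "bbN"), paste, sep = ":"))
  tokens <- sort(tokens)
  pairs <- expand.grid(a = tokens, b = tokens,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
  key <- paste(pairs$a, pairs$b, sep = "|")
  .withSeed(seed, {
    out <- stats::setNames(stats::rnorm(length(key), 0, sd), key)
    class(out) <- "potentialTable"
    out
  })
}

#' Generate an energy column rank-correlated with pose quality
#'
#' Draws per-pose energies from a Gaussian copula so that the Spearman
#' correlation between energy and iRMSD is approximately \code{rho}
#' (exactly monotone for |rho| = 1). Emulates an external rigid-body
#' docking energy whose signal quality is controlled.
#'
#' @param irmsdValues named numeric vector (truth per pose).
#' @param rho requested Spearman correlation in [-1, 1].
#' @param seed integer seed.
#' @return named numeric energy vector (same names).
#' @export
makeEnergyColumn <- function(irmsdValues, rho, seed = 1L) {
  n <- length(irmsdValues)
  if (n < 3L) stop("need at least 3 poses")
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  # Pearson correlation on normal scores giving Spearman rho
  r <- 2 * sin(pi * rho / 6)
  .withSeed(seed, {
    z <- stats::qnorm(rank(irmsdValues, ties.method = "first") / (n + 1))
    e <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
    stats::setNames(e, names(irmsdValues))
  })
}

#' Generate a complete synthetic docking benchmark
#'
#' Builds \code{nTargets} homo-dimer targets: a helical toy monomer, a
#' C2-symmetric native complex, an ensemble of rigid-body poses whose
#' iRMSD targets mix a near-native stratum (below 2.5 Angstrom) with
#' decoys spread up to \code{maxIrmsd}, an interface-probability table
#' realizing \code{targetMcc}, one shared random potential table, and
#' an energy column with Spearman correlation \code{energyRho} to the
#' true iRMSD.
#'
#' @param nTargets number of targets (default 20).
#' @param posesPerTarget ensemble size per target (default 200).
#' @param targetMcc accuracy of the probability tables (default 0.5).
#' @param energyRho energy-to-iRMSD Spearman correlation (default
#'   0.4).
#' @param seed integer master seed.
#' @param monomerLength residues per monomer (default 48).
#' @param fracNearNative fraction of poses drawn in the near-native
#'   stratum (default 0.03, emulating the sparseness of hits in real
#'   rigid-body docking ensembles).
#' @param maxIrmsd upper bound of the decoy stratum (default 30).
#' @return a \linkS4class{SyntheticBenchmark}.
#' @export
makeBenchmark <- function(nTargets = 20L, posesPerTarget = 200L,
                          targetMcc = 0.5, energyRho = 0.4, seed = 1L,
                          monomerLength = 48L, fracNearNative = 0.03,
                          maxIrmsd = 30) {
  subseeds <- .withSeed(seed, matrix(sample.int(2^20, nTargets * 5L),
                                     nrow = nTargets))
  potential <- makePotentialTable(seed = seed)
  targets <- vector("list", nTargets)
  names(targets) <- sprintf("target%02d", seq_len(nTargets))
  for (t in seq_len(nTargets)) {
    monomer <- makeMonomer(monomerLength, "helix", seed = subseeds[t, 1])
    native <- makeC2Pose(monomer, contactGap = 4,
                         poseId = paste0(names(targets)[t], "_native"))
    nNear <- max(1L, round(fracNearNative * posesPerTarget))
    irTargets <- .withSeed(subseeds[t, 2], {
      tt <- c(stats::runif(nNear, 0.5, 2.4),
              stats::runif(posesPerTarget - nNear, 3, maxIrmsd))
      sample(tt)
    })
    ens <- makeDecoyEnsemble(native, posesPerTarget, irTargets,
                             seed = subseeds[t, 3])
    probs <- makeProbabilityTable(native, targetMcc,
                                  seed = subseeds[t, 4])
    energies <- makeEnergyColumn(ens$irmsd, energyRho,
                                 seed = subseeds[t, 5])
    targets[[t]] <- list(native = native, ensemble = ens$poses,
                         irmsd = ens$irmsd, probs = probs,
                         potential = potential, energies = energies)
  }
  new("SyntheticBenchmark", targets = targets, seed = as.integer(seed),
      params = list(nTargets = nTargets,
                    posesPerTarget = posesPerTarget,
                    targetMcc = targetMcc, energyRho = energyRho,
                    monomerLength = monomerLength,
                    fracNearNative = fracNearNative,
                    maxIrmsd = maxIrmsd))
}

#' Compute feature tables for every benchmark target
#'
#' Runs \code{\link{featurize}} over each target's ensemble and pairs
#' it with the true iRMSD labels, in the shape
#' \code{\link{crossValidate}} consumes.
#'
#' @param benchmark a \linkS4class{SyntheticBenchmark}.
#' @param homo include the CBS attribute (default TRUE).
#' @return named list of \code{list(features, labels)}.
#' @export
benchmarkFeaturize <- function(benchmark, homo = TRUE) {
  lapply(benchmarkTargets(benchmark), function(tg) {
    list(features = featurize(tg$ensemble, tg$probs, tg$potential,
                              tg$energies, homo = homo),
         labels = tg$irmsd)
  })
}

#' Quality tables of a benchmark (from stored truth)
#'
#' @param benchmark a \linkS4class{SyntheticBenchmark}.
#' @return named list of data.frames (pose_id, irmsd, pcs); pcs is NA
#'   (compute with \code{\link{poseQuality}} when needed).
#' @export
benchmarkQualities <- function(benchmark) {
  lapply(benchmarkTargets(benchmark), function(tg) {
    data.frame(pose_id = names(tg$irmsd), irmsd = unname(tg$irmsd),
               pcs = NA_real_, stringsAsFactors = FALSE)
  })
}

#' Rank poses by a raw score column
#'
#' Builds a ranking data.frame (pose_id, pred, rank) directly from a
#' named score vector, ascending by default (lower = better), ties
#' broken by pose id - used e.g. for the energy-only baseline.
#'
#' @param scores named numeric vector keyed by pose id.
#' @param decreasing sort descending instead.
#' @return data.frame (pose_id, pred, rank).
#' @export
scoreRanking <- function(scores, decreasing = FALSE) {
  v <- if (decreasing) -scores else scores
  ord <- order(v, names(scores))
  data.frame(pose_id = names(scores)[ord], pred = unname(v[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Write a benchmark to a directory of plain-text files
#'
#' Per target: native and pose PDB files, probabilities TSV, energies
#' TSV and a truth TSV (pose_id, irmsd); one shared potential TSV.
#'
#' @param benchmark a \linkS4class{SyntheticBenchmark}.
#' @param dir output directory (created).
#' @param writePoses also write every pose PDB (default TRUE).
#' @return \code{dir}, invisibly.
#' @export
writeBenchmark <- function(benchmark, dir, writePoses = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pot <- benchmarkTargets(benchmark)[[1]]$potential
  toks <- strsplit(names(unclass(pot)), "[|:]")
  potDF <- data.frame(res_i = vapply(toks, `[`, "", 1),
                      site_i = vapply(toks, `[`, "", 2),
                      res_j = vapply(toks, `[`, "", 3),
                      site_j = vapply(toks, `[`, "", 4),
                      value = as.numeric(unclass(pot)),
                      stringsAsFactors = FALSE)
  utils::write.table(potDF, file.path(dir, "potential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (tn in names(benchmarkTargets(benchmark))) {
    tg <- benchmarkTargets(benchmark)[[tn]]
    td <- file.path(dir, tn)
    dir.create(td, showWarnings = FALSE)
    writePosePDB(tg$native, file.path(td, "native.pdb"))
    if (writePoses) {
      for (p in tg$ensemble) {
        writePosePDB(p, file.path(td, paste0(poseId(p), ".pdb")))
      }
    }
    utils::write.table(tg$probs, file.path(td, "probabilities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(pose_id = names(tg$energies),
                                  energy = unname(tg$energies)),
                       file.path(td, "energies.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(pose_id = names(tg$irmsd),
                                  irmsd = unname(tg$irmsd)),
                       file.path(td, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
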