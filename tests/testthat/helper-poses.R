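# Shared fixture builders and independent brute-force oracles.
# Oracles are deliberately written as plain loops, independent of the
# package's vectorized implementations.

# chain with one or more atoms per residue from a coordinate list:
# coords = list of n x 3 matrices (one per residue), names = atom names
toyChain <- function(chainId, coords, atomNames = NULL, resid = "ALA",
                     resno = NULL) {
  nres <- length(coords)
  if (is.null(resno)) resno <- seq_len(nres)
  resid <- rep_len(resid, nres)
  elety <- character(0); rs <- character(0); rn <- integer(0)
  xyz <- NULL
  for (i in seq_len(nres)) {
    m <- rbind(coords[[i]])
    nm <- if (is.null(atomNames)) {
      if (nrow(m) == 1) "CA" else c("N", "CA", "O", "CB")[seq_len(nrow(m))]
    } else atomNames[[i]]
    elety <- c(elety, nm)
    rs <- c(rs, rep(resid[i], nrow(m)))
    rn <- c(rn, rep(resno[i], nrow(m)))
    xyz <- rbind(xyz, m)
  }
  chainModel(chainId, elety = elety, resid = rs, resno = rn,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

toyPose <- function(rec, lig, id = "pose") {
  new("DimerPose", poseId = id, receptor = rec, ligand = lig,
      externalEnergy = NA_real_)
}

# random two-chain pose: residues with 1-4 atoms scattered in a box
randomPose <- function(nRes = 8, seed = 1, spread = 12) {
  set.seed(seed)
  mk <- function(chainId) {
    coords <- lapply(seq_len(nRes), function(i) {
      nat <- sample(1:4, 1)
      center <- runif(3, 0, spread)
      matrix(rep(center, each = nat) + rnorm(nat * 3, sd = 1.2), nat, 3)
    })
    toyChain(chainId, coords)
  }
  toyPose(mk("A"), mk("B"))
}

# O(n^2 a^2) reference contact scan
bruteContacts <- function(pose, cutoff = 10) {
  recA <- atoms(receptor(pose))
  ligA <- atoms(ligand(pose))
  out <- NULL
  for (ri in sort(unique(recA$seqIndex))) {
    for (li in sort(unique(ligA$seqIndex))) {
      ra <- recA[recA$seqIndex == ri, ]
      la <- ligA[ligA$seqIndex == li, ]
      dmin <- Inf
      for (i in seq_len(nrow(ra))) {
        for (j in seq_len(nrow(la))) {
          d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                      (ra$z[i] - la$z[j])^2)
          if (d < dmin) dmin <- d
        }
      }
      if (dmin <= cutoff) {
        out <- rbind(out, data.frame(recSeqIndex = ri, ligSeqIndex = li,
                                     minDist = dmin))
      }
    }
  }
  out
}

# reference site-contact scan with the three class thresholds
bruteSiteContacts <- function(pose) {
  thr <- c(sc_sc = 6.8, bb_bb = 4.0, sc_bb = 5.6)
  siteList <- function(chain) {
    s <- buildSites(chain)
    out <- list()
    for (i in seq_len(nrow(s))) {
      for (kind in c("sc", "bbO", "bbN")) {
        cols <- switch(kind, sc = c("sc.x", "sc.y", "sc.z"),
                       bbO = c("O.x", "O.y", "O.z"),
                       bbN = c("N.x", "N.y", "N.z"))
        p <- as.numeric(s[i, cols])
        if (!any(is.na(p))) {
          out[[length(out) + 1]] <- list(seqIndex = s$seqIndex[i],
                                         kind = kind, p = p)
        }
      }
    }
    out
  }
  R <- siteList(receptor(pose))
  L <- siteList(ligand(pose))
  rows <- NULL
  for (r in R) {
    for (l in L) {
      cls <- if (r$kind == "sc" && l$kind == "sc") "sc_sc"
      else if (r$kind != "sc" && l$kind != "sc") "bb_bb" else "sc_bb"
      d <- sqrt(sum((r$p - l$p)^2))
      if (d <= thr[cls]) {
        rows <- rbind(rows, data.frame(recSeqIndex = r$seqIndex,
                                       recKind = r$kind,
                                       ligSeqIndex = l$seqIndex,
                                       ligKind = l$kind, class = cls,
                                       dist = d))
      }
    }
  }
  rows
}

# pairwise-match CBS oracle: counts matches by direct lookup
bruteCbs <- function(x, y) {
  keep <- !duplicated(paste(x, y)) & x != y
  x <- x[keep]; y <- y[keep]
  s1 <- which(x < y)
  s2 <- which(x > y)
  matched <- 0
  for (i in s1) {
    for (j in s2) {
      if (x[i] == y[j] && y[i] == x[j]) {
        matched <- matched + 1
        break
      }
    }
  }
  union_size <- length(s1) + length(s2) - matched
  if (union_size == 0) 0 else matched / union_size
}

# Horn quaternion absolute-orientation oracle: superpose mobile onto
# fixed over paired rows, return the transformed full set
quatSuperpose <- function(fixed, mobile, mobileAll = mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm)
  B <- sweep(fixed, 2, cf)
  S <- t(A) %*% B
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; xq <- q[2]; yq <- q[3]; zq <- q[4]
  R <- matrix(c(
    1 - 2 * (yq^2 + zq^2), 2 * (xq * yq - w * zq), 2 * (xq * zq + w * yq),
    2 * (xq * yq + w * zq), 1 - 2 * (xq^2 + zq^2), 2 * (yq * zq - w * xq),
    2 * (xq * zq - w * yq), 2 * (yq * zq + w * xq), 1 - 2 * (xq^2 + yq^2)),
    3, 3, byrow = TRUE)
  sweep(sweep(mobileAll, 2, cm) %*% t(R), 2, cf, "+")
}

# iRMSD oracle built on the quaternion superposition
quatIrmsd <- function(pose, native, cutoff = 10) {
  caMat <- function(chain, keys = NULL) {
    a <- atoms(chain)
    ca <- a[a$elety == "CA", ]
    k <- paste0(ca$resno, ca$icode)
    if (!is.null(keys)) ca <- ca[match(keys, k), ]
    as.matrix(ca[, c("x", "y", "z")])
  }
  recKeys <- intersect(
    with(subset(atoms(receptor(pose)), elety == "CA"), paste0(resno, icode)),
    with(subset(atoms(receptor(native)), elety == "CA"), paste0(resno, icode)))
  ifl <- interfaceResidues(native, cutoff)$ligand
  ligKeys <- paste0(ifl$resno, ifl$icode)
  fixed <- caMat(receptor(native), recKeys)
  mobile <- caMat(receptor(pose), recKeys)
  mobAll <- rbind(mobile, caMat(ligand(pose), ligKeys))
  fitted <- quatSuperpose(fixed, mobile, mobAll)
  lt <- fitted[-seq_len(nrow(mobile)), , drop = FALSE]
  ln <- caMat(ligand(native), ligKeys)
  sqrt(mean(rowSums((lt - ln)^2)))
}

# small shared fixtures
helix20 <- function(seed = 11) makeMonomer(20, "helix", seed = seed)
c2pose20 <- function(seed = 11) makeC2Pose(helix20(seed), contactGap = 4)
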