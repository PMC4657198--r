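# Internal geometry and bookkeeping helpers.

# n x 3 coordinate matrix of a chain (all heavy atoms, file order)
.coords <- function(chain) {
  a <- chain@atoms
  cbind(x = a$x, y = a$y, z = a$z)
}

# residue key string used wherever residues are dictionary keys
.resKey <- function(resno, icode) paste0(resno, icode)

# one row per residue: resno, icode, resid, seqIndex
.residueTable <- function(chain) {
  a <- chain@atoms
  first <- !duplicated(a$seqIndex)
  data.frame(resno = a$resno[first], icode = a$icode[first],
             resid = a$resid[first], seqIndex = a$seqIndex[first],
             stringsAsFactors = FALSE)
}

# squared cross-distance matrix between n x 3 and m x 3 coordinate sets
.crossDist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # guard against fp negatives
  d2
}

# rotation matrix about unit axis u by angle theta (Rodrigues)
.rotationMatrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# apply a rigid transform (rotation R about origin `center`, then
# translation t) to a ChainModel
.transformChain <- function(chain, R = diag(3), t = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  X <- .coords(chain)
  Y <- sweep(sweep(X, 2, center) %*% t(R), 2, center + t, "+")
  a <- chain@atoms
  a$x <- Y[, 1]; a$y <- Y[, 2]; a$z <- Y[, 3]
  new("ChainModel", chainId = chain@chainId, atoms = a)
}

.transformPose <- function(pose, R = diag(3), t = c(0, 0, 0),
                           center = c(0, 0, 0), ligandOnly = FALSE) {
  rec <- if (ligandOnly) pose@receptor else
    .transformChain(pose@receptor, R, t, center)
  new("DimerPose", poseId = pose@poseId, receptor = rec,
      ligand = .transformChain(pose@ligand, R, t, center),
      externalEnergy = pose@externalEnergy)
}

# element symbol from a PDB atom name when the element column is absent:
# strip leading digits, take the first letter; two-letter elements are
# not expected among protein heavy atoms apart from SE (selenomethionine)
.elementFromName <- function(name) {
  nm <- toupper(gsub("^[0-9' ]+", "", trimws(name)))
  ifelse(substr(nm, 1, 2) == "SE", "SE", substr(nm, 1, 1))
}

.isHydrogen <- function(elesy) toupper(trimws(elesy)) %in% c("H", "D")

# CA coordinates keyed by residue, for superposition work
.caTable <- function(chain) {
  a <- chain@atoms
  ca <- a[a$elety == "CA", , drop = FALSE]
  data.frame(key = .resKey(ca$resno, ca$icode),
             x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
}

# seeded RNG scope: runs expr with a local RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# three-to-one amino acid code via bio3d, X for unknowns
.aa321 <- function(resid) {
  one <- suppressWarnings(bio3d::aa321(resid))
  one[is.na(one)] <- "X"
  one
}
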