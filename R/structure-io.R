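#' Construct a ChainModel from atom vectors
#'
#' Low-level constructor used by the PDB reader and the synthetic
#' generators. Atoms must be supplied in chain order; the dense 0-based
#' residue index is derived from runs of (resno, icode).
#'
#' @param chainId chain identifier (single character string).
#' @param elety atom names (e.g. "N", "CA", "O", "CB").
#' @param resid 3-letter residue names.
#' @param resno author residue numbers (integer).
#' @param x,y,z coordinates in Angstrom.
#' @param icode insertion codes ("" when none); recycled.
#' @param elesy element symbols; inferred from \code{elety} when NULL.
#' @return a \linkS4class{ChainModel}.
#' @export
chainModel <- function(chainId, elety, resid, resno, x, y, z,
                       icode = "", elesy = NULL) {
  n <- length(elety)
  icode <- rep_len(icode, n)
  if (is.null(elesy)) elesy <- .elementFromName(elety)
  rk <- .resKey(resno, icode)
  seqIndex <- cumsum(c(FALSE, rk[-1] != rk[-n]))
  atoms <- data.frame(elety = as.character(elety),
                      elesy = as.character(elesy),
                      resid = as.character(resid),
                      resno = as.integer(resno),
                      icode = as.character(icode),
                      x = as.numeric(x), y = as.numeric(y),
                      z = as.numeric(z),
                      seqIndex = as.integer(seqIndex),
                      stringsAsFactors = FALSE)
  new("ChainModel", chainId = as.character(chainId), atoms = atoms)
}

#' Read protein chains from a PDB file
#'
#' Parses ATOM records of the first MODEL into \linkS4class{ChainModel}
#' objects. Hydrogens (element H or D) and HETATM records are excluded.
#' When alternate locations are present, the altloc with the highest
#' occupancy is kept per atom; ties go to the alphabetically first
#' altloc character.
#'
#' @param path PDB file path.
#' @param chains optional character vector of chain ids to keep; all
#'   chains when NULL.
#' @return named list of \linkS4class{ChainModel} in file order.
#' @export
readPDBChains <- function(path, chains = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  elesy <- at$elesy
  bad <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[bad] <- .elementFromName(at$elety[bad])
  at$elesy <- toupper(trimws(elesy))
  at <- at[!.isHydrogen(at$elesy), , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy ATOM records in ", path)
  # altloc: per atom identity keep highest occupancy, tie -> first altloc
  atomKey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  pick <- order(atomKey, -at$o, at$alt)
  at <- at[pick, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]
  at <- at[order(match(rownames(at), rownames(pdb$atom))), , drop = FALSE]
  fileChains <- unique(at$chain)
  if (!is.null(chains)) {
    missing <- setdiff(chains, fileChains)
    if (length(missing)) {
      stop("requested chain(s) absent from ", path, ": ",
           paste(missing, collapse = ", "))
    }
    fileChains <- fileChains[fileChains %in% chains]
  }
  out <- lapply(fileChains, function(ch) {
    a <- at[at$chain == ch, , drop = FALSE]
    chainModel(ch, elety = a$elety, resid = a$resid, resno = a$resno,
               x = a$x, y = a$y, z = a$z, icode = a$insert,
               elesy = a$elesy)
  })
  names(out) <- fileChains
  out
}

#' Read a two-chain docking pose from a PDB file
#'
#' @param path PDB file path.
#' @param chains length-2 character vector; the first chain becomes the
#'   receptor, the second the ligand.
#' @param poseId pose identifier (defaults to the file name).
#' @param energy optional external energy score for the pose.
#' @return a \linkS4class{DimerPose}.
#' @export
readPose <- function(path, chains, poseId = basename(path),
                     energy = NA_real_) {
  stopifnot(length(chains) == 2L)
  cm <- readPDBChains(path, chains = chains)
  new("DimerPose", poseId = poseId, receptor = cm[[chains[1]]],
      ligand = cm[[chains[2]]], externalEnergy = as.numeric(energy))
}

.formatAtomName <- function(elety, elesy) {
  # names shorter than 4 chars start in column 14 for 1-letter elements
  ifelse(nchar(elety) >= 4L | nchar(elesy) == 2L,
         sprintf("%-4s", elety), sprintf(" %-3s", elety))
}

.writeChainRecords <- function(chain, serial0, con) {
  a <- chain@atoms
  n <- nrow(a)
  serial <- serial0 + seq_len(n)
  lines <- sprintf("ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s  ",
                   serial, .formatAtomName(a$elety, a$elesy), "", a$resid,
                   chain@chainId, a$resno, a$icode, a$x, a$y, a$z,
                   1, 0, a$elesy)
  last <- n
  ter <- sprintf("TER   %5d      %-3s %1s%4d%1s",
                 serial0 + n + 1L, a$resid[last], chain@chainId,
                 a$resno[last], a$icode[last])
  writeLines(c(lines, ter), con)
  serial0 + n + 1L
}

#' Write a docking pose as a fixed-width PDB file
#'
#' Receptor chain first, one TER record per chain, END last.
#' Coordinates are serialized at the PDB precision of 3 decimals, so a
#' write/read round trip preserves them to within 5e-4 Angstrom.
#'
#' @param pose a \linkS4class{DimerPose}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePosePDB <- function(pose, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  s <- .writeChainRecords(pose@receptor, 0L, con)
  s <- .writeChainRecords(pose@ligand, s, con)
  writeLines("END", con)
  invisible(path)
}

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
.ATOMIC_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  SE = 78.971, P = 30.974)

#' Build per-residue interaction sites
#'
#' Each residue contributes up to three interaction sites: the
#' side-chain center (centroid of side-chain heavy atoms; for glycine,
#' which has no side-chain heavy atoms, the CA coordinate is used by
#' convention), the backbone carbonyl oxygen, and the backbone amide
#' nitrogen. Missing atoms yield absent sites (NA coordinates), never a
#' silent zero.
#'
#' @param chain a \linkS4class{ChainModel}.
#' @param massWeighted if TRUE the side-chain center is weighted by
#'   atomic masses; the default is the unweighted centroid, which is
#'   exactly reproducible without a mass table.
#' @return data.frame with one row per residue: residue identity
#'   columns plus \code{sc.x/y/z}, \code{O.x/y/z}, \code{N.x/y/z}.
#' @export
buildSites <- function(chain, massWeighted = FALSE) {
  a <- chain@atoms
  rt <- .residueTable(chain)
  n <- nrow(rt)
  sc <- matrix(NA_real_, n, 3)
  bbO <- matrix(NA_real_, n, 3)
  bbN <- matrix(NA_real_, n, 3)
  split_idx <- split(seq_len(nrow(a)), a$seqIndex)
  for (i in seq_len(n)) {
    rows <- split_idx[[as.character(rt$seqIndex[i])]]
    ra <- a[rows, , drop = FALSE]
    scAtoms <- ra[!(ra$elety %in% .BACKBONE_ATOMS), , drop = FALSE]
    if (nrow(scAtoms) > 0L) {
      w <- if (massWeighted) {
        m <- .ATOMIC_MASS[scAtoms$elesy]
        m[is.na(m)] <- 12.011
        m
      } else rep(1, nrow(scAtoms))
      sc[i, ] <- c(sum(w * scAtoms$x), sum(w * scAtoms$y),
                   sum(w * scAtoms$z)) / sum(w)
    } else if (rt$resid[i] == "GLY") {
      ca <- ra[ra$elety == "CA", , drop = FALSE]
      if (nrow(ca) == 1L) sc[i, ] <- c(ca$x, ca$y, ca$z)
    }
    o <- ra[ra$elety == "O", , drop = FALSE]
    if (nrow(o) == 1L) bbO[i, ] <- c(o$x, o$y, o$z)
    nn <- ra[ra$elety == "N", , drop = FALSE]
    if (nrow(nn) == 1L) bbN[i, ] <- c(nn$x, nn$y, nn$z)
  }
  cbind(rt,
        data.frame(sc.x = sc[, 1], sc.y = sc[, 2], sc.z = sc[, 3],
                   O.x = bbO[, 1], O.y = bbO[, 2], O.z = bbO[, 3],
                   N.x = bbN[, 1], N.y = bbN[, 2], N.z = bbN[, 3]))
}
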