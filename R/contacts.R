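#' Inter-chain residue contacts of a docking pose
#'
#' Two residues on different chains are in contact when any two of
#' their heavy atoms are within \code{cutoff} Angstrom (inclusive) of
#' each other; the default cutoff is 10 Angstrom.
#'
#' @param pose a \linkS4class{DimerPose}.
#' @param cutoff contact distance cutoff in Angstrom (> 0).
#' @return a \linkS4class{ContactSet} with basis "heavy_atom".
#' @export
residueContacts <- function(pose, cutoff = 10) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a single positive number")
  }
  rec <- pose@receptor
  lig <- pose@ligand
  D2 <- .crossDist2(.coords(rec), .coords(lig))
  hit <- which(D2 <= cutoff^2, arr.ind = TRUE)
  recRT <- .residueTable(rec)
  ligRT <- .residueTable(lig)
  if (nrow(hit) == 0L) {
    pairs <- data.frame(recResno = integer(), recIcode = character(),
                        recSeqIndex = integer(), ligResno = integer(),
                        ligIcode = character(), ligSeqIndex = integer(),
                        minDist = numeric(), stringsAsFactors = FALSE)
  } else {
    ri0 <- rec@atoms$seqIndex[hit[, 1]]
    li0 <- lig@atoms$seqIndex[hit[, 2]]
    d <- sqrt(D2[hit])
    key <- paste(ri0, li0)
    agg <- tapply(d, key, min)
    u <- !duplicated(key)
    ri <- ri0[u]; li <- li0[u]
    minD <- as.numeric(agg[paste(ri, li)])
    ord <- order(ri, li)
    ri <- ri[ord]; li <- li[ord]; minD <- minD[ord]
    pairs <- data.frame(
      recResno = recRT$resno[ri + 1L], recIcode = recRT$icode[ri + 1L],
      recSeqIndex = ri,
      ligResno = ligRT$resno[li + 1L], ligIcode = ligRT$icode[li + 1L],
      ligSeqIndex = li, minDist = minD, stringsAsFactors = FALSE)
  }
  new("ContactSet", cutoff = cutoff, basis = "heavy_atom", pairs = pairs)
}

#' Interface residues of a docking pose
#'
#' A residue is interfacial when it has at least one heavy atom within
#' \code{cutoff} Angstrom of any heavy atom of the partner chain, i.e.
#' when it appears in at least one pair of
#' \code{\link{residueContacts}} at the same cutoff.
#'
#' @param pose a \linkS4class{DimerPose}, or a precomputed
#'   \linkS4class{ContactSet} via \code{contacts}.
#' @param cutoff contact cutoff in Angstrom.
#' @param contacts optional precomputed ContactSet (must match cutoff).
#' @return list with elements \code{receptor} and \code{ligand}, each a
#'   data.frame of the interfacial residues (resno, icode, seqIndex).
#' @export
interfaceResidues <- function(pose, cutoff = 10, contacts = NULL) {
  cs <- if (is.null(contacts)) residueContacts(pose, cutoff) else contacts
  p <- cs@pairs
  recU <- !duplicated(p$recSeqIndex)
  ligU <- !duplicated(p$ligSeqIndex)
  rec <- data.frame(resno = p$recResno[recU], icode = p$recIcode[recU],
                    seqIndex = p$recSeqIndex[recU],
                    stringsAsFactors = FALSE)
  lig <- data.frame(resno = p$ligResno[ligU], icode = p$ligIcode[ligU],
                    seqIndex = p$ligSeqIndex[ligU],
                    stringsAsFactors = FALSE)
  list(receptor = rec[order(rec$seqIndex), , drop = FALSE],
       ligand = lig[order(lig$seqIndex), , drop = FALSE])
}

.SITE_THRESHOLDS <- c(sc_sc = 6.8, bb_bb = 4.0, sc_bb = 5.6)

# stack the three site kinds of one chain into a flat table
.siteStack <- function(sites) {
  stack1 <- function(kind, cols) {
    ok <- !is.na(sites[[cols[1]]])
    data.frame(seqIndex = sites$seqIndex[ok], resid = sites$resid[ok],
               resno = sites$resno[ok], icode = sites$icode[ok],
               kind = rep_len(kind, sum(ok)),
               class = rep_len(if (kind == "sc") "sc" else "bb", sum(ok)),
               x = sites[[cols[1]]][ok], y = sites[[cols[2]]][ok],
               z = sites[[cols[3]]][ok], stringsAsFactors = FALSE)
  }
  rbind(stack1("sc", c("sc.x", "sc.y", "sc.z")),
        stack1("bbO", c("O.x", "O.y", "O.z")),
        stack1("bbN", c("N.x", "N.y", "N.z")))
}

#' Site-level inter-chain contacts for the docking potential
#'
#' Interaction sites are the side-chain center, the backbone carbonyl
#' oxygen and the backbone amide nitrogen of each residue (see
#' \code{\link{buildSites}}). A site pair across the interface is a
#' contact when its distance is at or below the class threshold:
#' side chain-side chain 6.8 Angstrom, backbone-backbone 4.0 Angstrom
#' (all four O/N combinations), and mixed side chain/backbone 5.6
#' Angstrom. Absent sites produce no contacts.
#'
#' @param pose a \linkS4class{DimerPose}.
#' @param sitesR,sitesL site tables from \code{\link{buildSites}};
#'   computed from the pose when NULL.
#' @return data.frame with one row per site contact: receptor and
#'   ligand residue identity and name, site kinds (\code{sc}, \code{bbO}
#'   or \code{bbN}), the pair class (\code{sc_sc}, \code{bb_bb} or
#'   \code{sc_bb}) and the distance.
#' @export
siteContacts <- function(pose, sitesR = NULL, sitesL = NULL) {
  if (is.null(sitesR)) sitesR <- buildSites(pose@receptor)
  if (is.null(sitesL)) sitesL <- buildSites(pose@ligand)
  R <- .siteStack(sitesR)
  L <- .siteStack(sitesL)
  empty <- data.frame(recResno = integer(), recIcode = character(),
                      recResid = character(), recKind = character(),
                      ligResno = integer(), ligIcode = character(),
                      ligResid = character(), ligKind = character(),
                      class = character(), dist = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(R) == 0L || nrow(L) == 0L) return(empty)
  D2 <- .crossDist2(cbind(R$x, R$y, R$z), cbind(L$x, L$y, L$z))
  maxThr2 <- max(.SITE_THRESHOLDS)^2
  hit <- which(D2 <= maxThr2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  i <- hit[, 1]; j <- hit[, 2]
  cls <- ifelse(R$class[i] == "sc" & L$class[j] == "sc", "sc_sc",
                ifelse(R$class[i] == "bb" & L$class[j] == "bb",
                       "bb_bb", "sc_bb"))
  d <- sqrt(D2[hit])
  keep <- d <= .SITE_THRESHOLDS[cls]
  i <- i[keep]; j <- j[keep]; cls <- cls[keep]; d <- d[keep]
  ord <- order(R$seqIndex[i], L$seqIndex[j], R$kind[i], L$kind[j])
  i <- i[ord]; j <- j[ord]; cls <- cls[ord]; d <- d[ord]
  data.frame(recResno = R$resno[i], recIcode = R$icode[i],
             recResid = R$resid[i], recKind = R$kind[i],
             ligResno = L$resno[j], ligIcode = L$icode[j],
             ligResid = L$resid[j], ligKind = L$kind[j],
             class = unname(cls), dist = d, stringsAsFactors = FALSE)
}

#' Write a contact set as TSV
#'
#' @param contacts a \linkS4class{ContactSet}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeContactsTSV <- function(contacts, path) {
  utils::write.table(contacts@pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
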