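# Contact-based symmetry (CBS) of homo-dimer interfaces.
#
# An ideal C2 homo-dimer satisfies: if residue x of chain A touches
# residue y of chain B, then residue y of chain A touches residue x of
# chain B. CBS quantifies how closely a pose obeys this, as the Jaccard
# index between the two halves of the inter-chain contact set under
# index transposition.

#' CBS from raw index pairs
#'
#' Takes inter-chain contacts as integer residue indices on a frame
#' shared by the two identical chains (x = receptor-side index, y =
#' ligand-side index). Self pairs (x == y) are trivially symmetric and
#' are excluded from both sets but counted. The remaining pairs are
#' split into S1 = \{x < y\} and S2 = \{x > y\}; S2 is transposed to
#' \{(y, x)\} and the score is |S1 n S2'| / |S1 u S2'|. An empty union
#' scores 0 by convention (flagged via \code{emptyUnion}).
#'
#' @param x,y equal-length integer vectors of contacting residue
#'   indices (receptor side, ligand side).
#' @param mode label recorded in the result ("seqnum" by default).
#' @return a \linkS4class{CbsResult}.
#' @export
cbsFromPairs <- function(x, y, mode = "seqnum") {
  stopifnot(length(x) == length(y))
  x <- as.integer(x); y <- as.integer(y)
  dup <- duplicated(paste(x, y))
  x <- x[!dup]; y <- y[!dup]
  self <- x == y
  nSelf <- sum(self)
  x <- x[!self]; y <- y[!self]
  s1 <- cbind(x = x[x < y], y = y[x < y])
  s2 <- cbind(x = x[x > y], y = y[x > y])
  k1 <- paste(s1[, 1], s1[, 2])
  k2m <- paste(s2[, 2], s2[, 1])  # transposed S2
  uni <- union(k1, k2m)
  score <- if (length(uni) == 0L) 0 else
    length(intersect(k1, k2m)) / length(uni)
  new("CbsResult", cbs = score, s1 = s1, s2 = s2,
      nSelf = as.integer(nSelf), mode = mode,
      emptyUnion = length(uni) == 0L)
}

# Establish a common residue index frame across the two chains of a
# homo-dimer. Default: author residue numbers, when the two chains
# carry the same numbering and no insertion codes. Otherwise fall back
# to a global pairwise sequence alignment and index residues by
# alignment column. Chains whose sequences are clearly not two copies
# of one protein raise an error.
.residueCorrespondence <- function(rec, lig) {
  rtR <- .residueTable(rec)
  rtL <- .residueTable(lig)
  noIcode <- all(!nzchar(rtR$icode)) && all(!nzchar(rtL$icode))
  if (noIcode && setequal(rtR$resno, rtL$resno)) {
    seqR <- .aa321(rtR$resid)[match(sort(rtR$resno), rtR$resno)]
    # sanity: same residue types at shared numbers
    common <- intersect(rtR$resno, rtL$resno)
    same <- rtR$resid[match(common, rtR$resno)] ==
      rtL$resid[match(common, rtL$resno)]
    if (mean(same) >= 0.9) {
      return(list(mode = "seqnum",
                  rec = stats::setNames(rtR$resno,
                                        .resKey(rtR$resno, rtR$icode)),
                  lig = stats::setNames(rtL$resno,
                                        .resKey(rtL$resno, rtL$icode))))
    }
  }
  seqR <- Biostrings::AAString(paste(.aa321(rtR$resid), collapse = ""))
  seqL <- Biostrings::AAString(paste(.aa321(rtL$resid), collapse = ""))
  aln <- Biostrings::pairwiseAlignment(seqR, seqL, type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  pid <- Biostrings::pid(aln)
  if (pid < 50) {
    stop("chains do not share residue numbering and their sequences ",
         sprintf("align at only %.1f%% identity; ", pid),
         "CBS is defined for homo-dimers only")
  }
  alnR <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  alnL <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  colR <- which(alnR != "-")   # alignment column of each receptor residue
  colL <- which(alnL != "-")
  list(mode = "alignment",
       rec = stats::setNames(colR, .resKey(rtR$resno, rtR$icode)),
       lig = stats::setNames(colL, .resKey(rtL$resno, rtL$icode)))
}

#' @describeIn cbsScore CBS of a precomputed ContactSet. Residue
#'   numbers must be directly comparable across the chains (no
#'   insertion codes); contacts are keyed by author residue number.
#' @export
setMethod("cbsScore", "ContactSet", function(x, ...) {
  p <- x@pairs
  if (any(nzchar(p$recIcode)) || any(nzchar(p$ligIcode))) {
    stop("contact set carries insertion codes; compute CBS from the ",
         "DimerPose so residues can be mapped onto a common frame")
  }
  cbsFromPairs(p$recResno, p$ligResno, mode = "seqnum")
})

#' @describeIn cbsScore CBS of a homo-dimer pose. Contacts are computed
#'   at \code{cutoff} (10 Angstrom heavy-atom default) and residues of
#'   the two chains are put on a common index frame: author residue
#'   numbers when the chains share numbering, otherwise a pairwise
#'   sequence alignment (mode recorded in the result). Hetero-dimers
#'   (sequence identity < 50 percent) raise an error.
#' @param cutoff contact cutoff in Angstrom.
#' @param contacts optional precomputed \linkS4class{ContactSet}.
#' @export
setMethod("cbsScore", "DimerPose", function(x, cutoff = 10,
                                            contacts = NULL, ...) {
  corr <- .residueCorrespondence(x@receptor, x@ligand)
  cs <- if (is.null(contacts)) residueContacts(x, cutoff) else contacts
  p <- cs@pairs
  xi <- unname(corr$rec[.resKey(p$recResno, p$recIcode)])
  yi <- unname(corr$lig[.resKey(p$ligResno, p$ligIcode)])
  ok <- !is.na(xi) & !is.na(yi)  # residues unaligned in the common frame
  cbsFromPairs(xi[ok], yi[ok], mode = corr$mode)
})
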