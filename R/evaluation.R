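# Pose quality against the experimental complex (iRMSD, fnat,
# fnon-nat, PCS) and ranking quality (percentage of successful cases,
# hit count, success rate).

#' Default evaluation cutoffs
#'
#' Hit cutoffs used throughout the evaluation suite: iRMSD 2.5 / 8.5 /
#' 9.5 Angstrom and pairwise contact score (PCS) 0.65 / 0.30 / 0.25
#' for experimental structures, high-quality and moderate-quality
#' monomer models respectively; top-10 window for success counting.
#'
#' @param irmsdCrystal,irmsdHigh,irmsdModerate iRMSD hit cutoffs (A).
#' @param pcsCrystal,pcsHigh,pcsModerate PCS hit cutoffs.
#' @param topK ranking window for hits.
#' @return validated named list.
#' @export
evaluationConfig <- function(irmsdCrystal = 2.5, irmsdHigh = 8.5,
                             irmsdModerate = 9.5, pcsCrystal = 0.65,
                             pcsHigh = 0.30, pcsModerate = 0.25,
                             topK = 10L) {
  cfg <- list(irmsdCrystal = irmsdCrystal, irmsdHigh = irmsdHigh,
              irmsdModerate = irmsdModerate, pcsCrystal = pcsCrystal,
              pcsHigh = pcsHigh, pcsModerate = pcsModerate,
              topK = as.integer(topK))
  stopifnot(all(unlist(cfg[1:6]) > 0), cfg$topK >= 1L)
  cfg
}

# matched CA coordinate matrices for residues common to two chains
.commonCA <- function(chainA, chainB, restrictKeys = NULL) {
  caA <- .caTable(chainA)
  caB <- .caTable(chainB)
  keys <- intersect(caA$key, caB$key)
  if (!is.null(restrictKeys)) keys <- intersect(keys, restrictKeys)
  list(keys = keys,
       A = as.matrix(caA[match(keys, caA$key), c("x", "y", "z")]),
       B = as.matrix(caB[match(keys, caB$key), c("x", "y", "z")]))
}

#' Interface RMSD of a docking pose
#'
#' The receptor of the pose is least-squares superposed onto the
#' receptor of the experimental complex over all common CA atoms
#' (Kabsch, via bio3d); the RMSD is then taken over the CA atoms of the
#' ligand interface residues, with the interface defined on the
#' experimental (native) complex by the 10 Angstrom heavy-atom
#' criterion. Residue correspondence is by (residue number, insertion
#' code).
#'
#' @param pose a \linkS4class{DimerPose}.
#' @param native the experimental complex as a \linkS4class{DimerPose}.
#' @param cutoff interface cutoff on the native complex (Angstrom).
#' @return the iRMSD in Angstrom.
#' @export
irmsd <- function(pose, native, cutoff = 10) {
  rec <- .commonCA(pose@receptor, native@receptor)
  if (length(rec$keys) < 3L) {
    stop("cannot superpose receptors: fewer than 3 common CA atoms")
  }
  ifaceL <- interfaceResidues(native, cutoff)$ligand
  if (nrow(ifaceL) == 0L) {
    stop("native complex has no ligand interface residues at ",
         cutoff, " A")
  }
  lig <- .commonCA(pose@ligand, native@ligand,
                   restrictKeys = .resKey(ifaceL$resno, ifaceL$icode))
  if (length(lig$keys) == 0L) {
    stop("no common ligand interface CA atoms between pose and native")
  }
  nR <- nrow(rec$A)
  mobile <- rbind(rec$A, lig$A)  # pose receptor CA then ligand iface CA
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(rec$B)),
                           mobile = as.vector(t(mobile)),
                           fixed.inds = seq_len(3L * nR),
                           mobile.inds = seq_len(3L * nR))
  lt <- matrix(fitted, ncol = 3, byrow = TRUE)[-(seq_len(nR)), ,
                                               drop = FALSE]
  sqrt(mean(rowSums((lt - lig$B)^2)))
}

#' Contact-map quality of a pose against the native complex
#'
#' Residue pairs across the interface are classified over the universe
#' of all receptor x ligand residue pairs: TP contacts present in both
#' pose and native, FP in the pose only, FN in the native only, TN in
#' neither (10 Angstrom heavy-atom contacts). Reported are fnat =
#' TP/(TP+FN) (fraction of native contacts recovered), fnon-nat =
#' FP/(TP+FP) (fraction of the model's contacts that are non-native),
#' and the pairwise contact score PCS, the Matthews correlation
#' coefficient of this classification. Degenerate denominators yield 0
#' with the \code{degenerate} flag set.
#'
#' The \code{mccVariant} argument exists for audit: \code{"standard"}
#' (default) uses the canonical MCC denominator
#' sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); \code{"printed"} reproduces a
#' variant with denominator sqrt((TP+FP)(TP+TN)(FP+FN)(TN+FN)) that
#' circulates in the docking literature, which is not the MCC.
#'
#' @param pose a \linkS4class{DimerPose}.
#' @param native the experimental complex.
#' @param cutoff contact cutoff in Angstrom.
#' @param mccVariant "standard" or "printed".
#' @return list with fnat, fnonnat, pcs, tp, fp, fn, tn and logical
#'   \code{degenerate}.
#' @export
contactQuality <- function(pose, native, cutoff = 10,
                           mccVariant = c("standard", "printed")) {
  mccVariant <- match.arg(mccVariant)
  nPairs <- as.numeric(nResidues(native@receptor)) *
    nResidues(native@ligand)
  keyOf <- function(p) paste(.resKey(p$recResno, p$recIcode),
                             .resKey(p$ligResno, p$ligIcode))
  kPose <- keyOf(residueContacts(pose, cutoff)@pairs)
  kNat <- keyOf(residueContacts(native, cutoff)@pairs)
  tp <- length(intersect(kPose, kNat))
  fp <- length(setdiff(kPose, kNat))
  fn <- length(setdiff(kNat, kPose))
  tn <- nPairs - tp - fp - fn
  safe <- function(num, den) if (den == 0) 0 else num / den
  pcs <- .mcc(tp, fp, fn, tn, mccVariant)
  degenerate <- (tp + fn) == 0 || (tp + fp) == 0 || is.na(pcs)
  list(fnat = safe(tp, tp + fn), fnonnat = safe(fp, tp + fp),
       pcs = if (is.na(pcs)) 0 else pcs,
       tp = tp, fp = fp, fn = fn, tn = tn, degenerate = degenerate)
}

# MCC with a degenerate-denominator guard (returns NA when undefined)
.mcc <- function(tp, fp, fn, tn, variant = "standard") {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  den2 <- if (variant == "standard") {
    (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  } else {
    (tp + fp) * (tp + tn) * (fp + fn) * (tn + fn)
  }
  if (den2 <= 0) return(NA_real_)
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Full quality record of a pose
#'
#' Convenience wrapper combining \code{\link{irmsd}} and
#' \code{\link{contactQuality}}.
#'
#' @inheritParams contactQuality
#' @return one-row data.frame (pose_id, irmsd, fnat, fnonnat, pcs).
#' @export
poseQuality <- function(pose, native, cutoff = 10) {
  cq <- contactQuality(pose, native, cutoff)
  data.frame(pose_id = poseId(pose), irmsd = irmsd(pose, native, cutoff),
             fnat = cq$fnat, fnonnat = cq$fnonnat, pcs = cq$pcs,
             stringsAsFactors = FALSE)
}

# poses in the top-k of a ranking, joined with their qualities
.topQualities <- function(ranking, quality, topK) {
  ids <- ranking$pose_id[ranking$rank <= topK]
  quality[match(ids, quality$pose_id), , drop = FALSE]
}

.checkRQ <- function(rankings, qualities) {
  if (length(rankings) == 0L) stop("empty target set")
  if (!setequal(names(rankings), names(qualities))) {
    stop("rankings and qualities must cover the same targets")
  }
  for (tn in names(rankings)) {
    if (!setequal(rankings[[tn]]$pose_id, qualities[[tn]]$pose_id)) {
      stop("pose ids differ between ranking and qualities for ", tn)
    }
  }
}

.isHit <- function(q, criterion, cutoff) {
  if (criterion == "irmsd") q$irmsd <= cutoff else q$pcs >= cutoff
}

#' Percentage of successful docking cases
#'
#' For each cutoff, the percentage of targets with at least one hit -
#' a pose with iRMSD at or below (or PCS at or above) the cutoff -
#' among the top \code{topK} ranked poses.
#'
#' @param rankings named list of ranking data.frames
#'   (\code{\link{predictRank}} output), one per target.
#' @param qualities named list of quality data.frames (columns
#'   pose_id, irmsd, pcs), one per target.
#' @param criterion "irmsd" (hit: irmsd <= cutoff) or "pcs"
#'   (hit: pcs >= cutoff).
#' @param cutoffs numeric vector of cutoff values to sweep.
#' @param topK ranking window (default 10).
#' @return data.frame (cutoff, pct) with pct in [0, 100].
#' @export
percentageSuccessful <- function(rankings, qualities,
                                 criterion = c("irmsd", "pcs"),
                                 cutoffs, topK = 10L) {
  criterion <- match.arg(criterion)
  .checkRQ(rankings, qualities)
  pct <- vapply(cutoffs, function(ct) {
    succ <- vapply(names(rankings), function(tn) {
      q <- .topQualities(rankings[[tn]], qualities[[tn]], topK)
      any(.isHit(q, criterion, ct))
    }, logical(1))
    100 * mean(succ)
  }, numeric(1))
  data.frame(cutoff = cutoffs, pct = pct)
}

#' Average number of hits in the top-ranked poses
#'
#' Counts, per target, the poses among the top \code{topK} ranked
#' whose iRMSD is at or below \code{cutoff}, and averages the count
#' over targets - a measure of how enriched the top of the ranking is
#' with near-native conformations.
#'
#' @inheritParams percentageSuccessful
#' @param cutoff single iRMSD cutoff in Angstrom.
#' @return mean hit count per target (numeric scalar).
#' @export
hitCount <- function(rankings, qualities, cutoff, topK = 10L) {
  .checkRQ(rankings, qualities)
  hits <- vapply(names(rankings), function(tn) {
    q <- .topQualities(rankings[[tn]], qualities[[tn]], topK)
    sum(q$irmsd <= cutoff)
  }, numeric(1))
  mean(hits)
}

#' Success rate as a function of ranking depth
#'
#' Percentage of targets with at least one correct pose within the top
#' n ranked conformations, for n = 1..nMax. Non-decreasing in n by
#' construction.
#'
#' @inheritParams percentageSuccessful
#' @param cutoff hit cutoff (iRMSD <= or PCS >= depending on
#'   criterion).
#' @param nMax maximum ranking depth (default 1000, truncated to the
#'   ensemble size).
#' @return data.frame (n, pct).
#' @export
successRate <- function(rankings, qualities,
                        criterion = c("irmsd", "pcs"), cutoff,
                        nMax = 1000L) {
  criterion <- match.arg(criterion)
  .checkRQ(rankings, qualities)
  nMax <- min(nMax, max(vapply(rankings, nrow, integer(1))))
  # per target, the best (lowest) rank achieving a hit
  bestRank <- vapply(names(rankings), function(tn) {
    r <- rankings[[tn]]
    q <- qualities[[tn]][match(r$pose_id, qualities[[tn]]$pose_id), ,
                         drop = FALSE]
    hit <- .isHit(q, criterion, cutoff)
    if (any(hit)) min(r$rank[hit]) else Inf
  }, numeric(1))
  n <- seq_len(nMax)
  pct <- vapply(n, function(k) 100 * mean(bestRank <= k), numeric(1))
  data.frame(n = n, pct = pct)
}

#' Cumulative distribution of symmetry scores
#'
#' For each threshold, the fraction of inputs with CBS greater than or
#' equal to the threshold - the cumulative-fraction view used to
#' characterize how prevalent symmetric interfaces are in a set of
#' homo-dimers, and to contrast near-native models with decoys.
#'
#' @param cbsValues numeric vector of CBS scores in [0, 1].
#' @param thresholds grid of threshold values (default 0 to 1 by 0.01).
#' @return data.frame (threshold, fraction), non-increasing in
#'   threshold.
#' @export
cbsDistribution <- function(cbsValues, thresholds = seq(0, 1, by = 0.01)) {
  stopifnot(length(cbsValues) >= 1L)
  frac <- vapply(thresholds, function(th) mean(cbsValues >= th),
                 numeric(1))
  data.frame(threshold = thresholds, fraction = frac)
}
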