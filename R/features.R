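# Per-pose attributes: interface-probability scores, docking-potential
# score, external energy, CBS; per-target Z-score standardization.

#' Read a residue-level interface probability table
#'
#' TSV with header and columns \code{chain}, \code{resno},
#' \code{icode}, \code{p_svc}, \code{p_nbc}: two interface
#' probabilities (from an SVC- and an NBC-based interface predictor)
#' per receptor residue.
#'
#' @param path TSV path.
#' @return data.frame with those columns; probabilities validated to
#'   lie in [0, 1].
#' @export
readProbabilityTable <- function(path) {
  pt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chain = "character",
                                         icode = "character"))
  need <- c("chain", "resno", "icode", "p_svc", "p_nbc")
  if (!all(need %in% names(pt))) {
    stop("probability table must have columns: ",
         paste(need, collapse = ", "))
  }
  pt$icode[is.na(pt$icode)] <- ""
  if (any(pt$p_svc < 0 | pt$p_svc > 1 | pt$p_nbc < 0 | pt$p_nbc > 1)) {
    stop("probabilities outside [0, 1] in ", path)
  }
  pt
}

#' Sum of interface probabilities over the model interface
#'
#' The interface score of a pose is the sum of the per-residue
#' interface probabilities over the receptor residues that are at the
#' pose's interface (10 Angstrom heavy-atom criterion). High scores
#' favor poses that bury surface regions predicted to be interfacial.
#' Residues without a table entry contribute 0; their count is attached
#' as attribute \code{nMissing}.
#'
#' @param pose a \linkS4class{DimerPose}.
#' @param probs probability table (see
#'   \code{\link{readProbabilityTable}}).
#' @param column which probability column to sum: "svc" or "nbc".
#' @param cutoff interface cutoff in Angstrom.
#' @param contacts optional precomputed \linkS4class{ContactSet}.
#' @return the score (numeric scalar).
#' @export
interfaceScore <- function(pose, probs, column = c("svc", "nbc"),
                           cutoff = 10, contacts = NULL) {
  column <- match.arg(column)
  iface <- interfaceResidues(pose, cutoff, contacts)$receptor
  if (nrow(iface) == 0L) {
    out <- 0
    attr(out, "nMissing") <- 0L
    return(out)
  }
  pr <- probs[probs$chain == pose@receptor@chainId, , drop = FALSE]
  idx <- match(.resKey(iface$resno, iface$icode),
               .resKey(pr$resno, pr$icode))
  p <- pr[[paste0("p_", column)]][idx]
  nMissing <- sum(is.na(idx))
  if (nMissing > 0L) {
    warning(nMissing, " interface residue(s) missing from the ",
            "probability table; scored as 0")
  }
  out <- sum(p, na.rm = TRUE)
  attr(out, "nMissing") <- nMissing
  out
}

.SITE_CLASS <- c(sc = "sc", bbO = "bb", bbN = "bb")

.potKey <- function(res1, site1, res2, site2) {
  a <- paste(res1, site1, sep = ":")
  b <- paste(res2, site2, sep = ":")
  ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Read a pairwise docking-potential parameter table
#'
#' TSV with header and columns \code{res_i}, \code{site_i},
#' \code{res_j}, \code{site_j}, \code{value}: one optimized contact
#' parameter per (residue type, interaction site) pair. Site labels are
#' \code{sc}, \code{bbO}, \code{bbN}; the collective label \code{bb}
#' expands to both backbone sites. The table is symmetrized at load, so
#' lookup does not depend on argument order; conflicting duplicate
#' entries raise an error.
#'
#' @param path TSV path.
#' @return a named numeric vector keyed canonically; class
#'   \code{"potentialTable"}.
#' @export
readPotentialTable <- function(path) {
  pt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("res_i", "site_i", "res_j", "site_j", "value")
  if (!all(need %in% names(pt))) {
    stop("potential table must have columns: ",
         paste(need, collapse = ", "))
  }
  expand <- function(df, col) {
    bb <- df[[col]] == "bb"
    if (!any(bb)) return(df)
    rbind(df[!bb, , drop = FALSE],
          do.call(rbind, lapply(c("bbO", "bbN"), function(s) {
            d <- df[bb, , drop = FALSE]; d[[col]] <- s; d
          })))
  }
  pt <- expand(expand(pt, "site_i"), "site_j")
  key <- .potKey(pt$res_i, pt$site_i, pt$res_j, pt$site_j)
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- tapply(pt$value, key, function(v) length(unique(v)) > 1)
    if (any(conflict)) {
      stop("conflicting duplicate parameters in ", path)
    }
    pt <- pt[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  out <- stats::setNames(pt$value, key)
  class(out) <- "potentialTable"
  out
}

#' Residue-pair docking-potential score of a pose
#'
#' Sums the potential parameter over all site-level inter-chain
#' contacts of the pose (see \code{\link{siteContacts}}). Parameters
#' are keyed by the two residue types and their interaction-site kinds;
#' pairs absent from the table contribute 0 and are counted in the
#' \code{nUnknown} attribute.
#'
#' @param pose a \linkS4class{DimerPose}.
#' @param table potential table from \code{\link{readPotentialTable}}
#'   (or a compatibly keyed named numeric vector).
#' @param sitesR,sitesL optional precomputed site tables.
#' @return the score (numeric scalar) with attribute \code{nUnknown}.
#' @export
potentialScore <- function(pose, table, sitesR = NULL, sitesL = NULL) {
  scs <- siteContacts(pose, sitesR, sitesL)
  if (nrow(scs) == 0L) {
    out <- 0
    attr(out, "nUnknown") <- 0L
    return(out)
  }
  key <- .potKey(scs$recResid, scs$recKind, scs$ligResid, scs$ligKind)
  v <- unname(unclass(table)[key])
  nUnknown <- sum(is.na(v))
  out <- sum(v, na.rm = TRUE)
  attr(out, "nUnknown") <- as.integer(nUnknown)
  out
}

#' Per-target Z-score standardization of pose attributes
#'
#' Each attribute is standardized across the pose ensemble of one
#' target: Z = (x - mean) / sd, with the population (divide-by-N)
#' standard deviation. A constant attribute (sd = 0) maps to all-zero
#' Z-scores.
#'
#' @param features data.frame with a \code{pose_id} column and numeric
#'   attribute columns.
#' @param cols attribute columns to standardize (default: all numeric
#'   columns except pose_id).
#' @return the data.frame with each attribute column replaced by its
#'   Z-scores, prefixed \code{z_}, appended after the raw columns.
#' @export
standardizeFeatures <- function(features, cols = NULL) {
  if (nrow(features) < 2L) {
    stop("standardization needs an ensemble of at least 2 poses")
  }
  if (is.null(cols)) {
    cols <- setdiff(names(features)[vapply(features, is.numeric,
                                           logical(1))], "pose_id")
  }
  for (cl in cols) {
    x <- features[[cl]]
    mu <- mean(x)
    sdev <- sqrt(mean((x - mu)^2))  # population sd
    features[[paste0("z_", cl)]] <-
      if (sdev == 0) rep(0, length(x)) else (x - mu) / sdev
  }
  features
}

#' Assemble the per-pose attribute table of a docking ensemble
#'
#' Computes the raw attributes of every pose - the SVC and NBC
#' interface-probability scores, the docking-potential score, the
#' external energy, and (for homo-dimers) the contact-based symmetry
#' score - then standardizes each attribute across the ensemble
#' (\code{\link{standardizeFeatures}}). Homo-dimers carry five
#' attributes, hetero-dimers four.
#'
#' @param poses list of \linkS4class{DimerPose} (one target's
#'   ensemble).
#' @param probs interface probability table.
#' @param potential potential table.
#' @param energies named numeric vector of external energies keyed by
#'   pose id; when NULL the poses' own \code{externalEnergy} slots are
#'   used. A missing energy is an error.
#' @param homo logical; include the CBS attribute.
#' @param cutoff interface/contact cutoff in Angstrom.
#' @param standardize append per-target Z-score columns (default TRUE).
#' @return data.frame ordered by pose_id with raw attribute columns
#'   (\code{svc}, \code{nbc}, \code{potential}, \code{energy}, and
#'   \code{cbs} when \code{homo}) and their \code{z_} counterparts.
#' @export
featurize <- function(poses, probs, potential, energies = NULL,
                      homo = TRUE, cutoff = 10, standardize = TRUE) {
  ids <- vapply(poses, poseId, character(1))
  if (anyDuplicated(ids)) stop("duplicate pose ids in ensemble")
  poses <- poses[order(ids)]
  ids <- sort(ids)
  if (is.null(energies)) {
    energies <- stats::setNames(vapply(poses, externalEnergy,
                                       numeric(1)), ids)
  }
  missingE <- ids[!ids %in% names(energies) | is.na(energies[ids])]
  if (length(missingE)) {
    stop("missing external energy for pose(s): ",
         paste(utils::head(missingE, 5), collapse = ", "))
  }
  rows <- lapply(poses, function(p) {
    cs <- residueContacts(p, cutoff)
    r <- data.frame(
      pose_id = poseId(p),
      svc = as.numeric(interfaceScore(p, probs, "svc", cutoff, cs)),
      nbc = as.numeric(interfaceScore(p, probs, "nbc", cutoff, cs)),
      potential = as.numeric(potentialScore(p, potential)),
      energy = unname(energies[poseId(p)]),
      stringsAsFactors = FALSE)
    if (homo) r$cbs <- cbs(cbsScore(p, cutoff, contacts = cs))
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (standardize) out <- standardizeFeatures(out)
  out
}

#' Write a feature table as TSV
#' @param features data.frame from \code{\link{featurize}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeaturesTSV <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-pose energy table
#'
#' TSV with header and columns \code{pose_id}, \code{energy}.
#' @param path TSV path.
#' @return named numeric vector keyed by pose id.
#' @export
readEnergyTable <- function(path) {
  et <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(pose_id = "character"))
  if (!all(c("pose_id", "energy") %in% names(et))) {
    stop("energy table must have columns pose_id, energy")
  }
  stats::setNames(et$energy, et$pose_id)
}
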