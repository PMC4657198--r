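#' @import methods
NULL

.ATOM_COLS <- c("elety", "elesy", "resid", "resno", "icode",
                "x", "y", "z", "seqIndex")

#' ChainModel: one protein chain as an atom table
#'
#' Holds the heavy atoms of a single chain in file order. The
#' \code{atoms} slot is a data.frame with one row per atom and columns
#' \code{elety} (atom name, e.g. "CA"), \code{elesy} (element symbol),
#' \code{resid} (3-letter residue name), \code{resno} (author residue
#' number), \code{icode} (insertion code, "" if none), \code{x},
#' \code{y}, \code{z} (coordinates, Angstrom) and \code{seqIndex}
#' (0-based dense residue index within the chain).
#'
#' @slot chainId single chain identifier character.
#' @slot atoms data.frame as described above.
#' @exportClass ChainModel
setClass("ChainModel", representation(chainId = "character",
                                      atoms = "data.frame"))

setValidity("ChainModel", function(object) {
  a <- object@atoms
  if (length(object@chainId) != 1L) return("chainId must be length 1")
  if (!all(.ATOM_COLS %in% names(a))) {
    return(paste("atoms must have columns:", paste(.ATOM_COLS, collapse = ", ")))
  }
  if (nrow(a) == 0L) return("chain has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z))) {
    return("non-finite coordinates")
  }
  if (any(!nzchar(a$elesy))) return("empty element symbol")
  # residue index must be dense 0..(n-1) in order of appearance
  idx <- unique(a$seqIndex)
  if (!identical(idx, seq_along(idx) - 1L)) {
    return("seqIndex not consecutive from 0")
  }
  key <- paste(a$seqIndex, a$elety)
  if (anyDuplicated(key)) return("duplicate atom name within a residue")
  TRUE
})

#' DimerPose: a two-chain docking model
#'
#' @slot poseId identifier, unique within an ensemble.
#' @slot receptor,ligand \linkS4class{ChainModel} objects.
#' @slot externalEnergy externally supplied per-pose energy score
#'   (e.g. the total energy reported by the rigid-body docking engine);
#'   \code{NA_real_} when absent.
#' @exportClass DimerPose
setClass("DimerPose", representation(poseId = "character",
                                     receptor = "ChainModel",
                                     ligand = "ChainModel",
                                     externalEnergy = "numeric"))

setValidity("DimerPose", function(object) {
  if (length(object@poseId) != 1L || !nzchar(object@poseId)) {
    return("poseId must be a non-empty string")
  }
  if (length(object@externalEnergy) != 1L) {
    return("externalEnergy must be length 1 (NA when absent)")
  }
  if (identical(object@receptor@chainId, object@ligand@chainId)) {
    return("receptor and ligand must carry distinct chain ids")
  }
  TRUE
})

#' ContactSet: directed inter-chain residue contacts at a cutoff
#'
#' \code{pairs} has one row per contacting (receptor residue, ligand
#' residue) pair: columns \code{recResno}, \code{recIcode},
#' \code{recSeqIndex}, \code{ligResno}, \code{ligIcode},
#' \code{ligSeqIndex}, \code{minDist}.
#'
#' @slot cutoff distance cutoff in Angstrom (inclusive).
#' @slot basis "heavy_atom" or "site".
#' @slot pairs data.frame as described.
#' @exportClass ContactSet
setClass("ContactSet", representation(cutoff = "numeric",
                                      basis = "character",
                                      pairs = "data.frame"))

setValidity("ContactSet", function(object) {
  if (object@cutoff <= 0) return("cutoff must be positive")
  if (!object@basis %in% c("heavy_atom", "site")) {
    return("basis must be 'heavy_atom' or 'site'")
  }
  need <- c("recResno", "recIcode", "recSeqIndex",
            "ligResno", "ligIcode", "ligSeqIndex", "minDist")
  if (!all(need %in% names(object@pairs))) {
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  }
  key <- paste(object@pairs$recResno, object@pairs$recIcode,
               object@pairs$ligResno, object@pairs$ligIcode)
  if (anyDuplicated(key)) return("duplicate contact pairs")
  TRUE
})

#' CbsResult: contact-based symmetry score of a homo-dimer pose
#'
#' The inter-chain contact set, indexed on a residue frame shared by the
#' two identical chains, is split into S1 (receptor index < ligand
#' index) and S2 (receptor index > ligand index); the score is the
#' Jaccard index of S1 and the transposed S2.
#'
#' @slot cbs the symmetry score in [0, 1].
#' @slot s1,s2 two-column integer matrices of (x, y) index pairs.
#' @slot nSelf number of excluded x == y pairs.
#' @slot mode how residue correspondence was established: "seqnum" or
#'   "alignment".
#' @slot emptyUnion TRUE when the contact set (minus self pairs) was
#'   empty, in which case the score is 0 by convention.
#' @exportClass CbsResult
setClass("CbsResult", representation(cbs = "numeric",
                                     s1 = "matrix",
                                     s2 = "matrix",
                                     nSelf = "integer",
                                     mode = "character",
                                     emptyUnion = "logical"))

setValidity("CbsResult", function(object) {
  if (object@cbs < 0 || object@cbs > 1) return("cbs outside [0, 1]")
  if (ncol(object@s1) != 2L || ncol(object@s2) != 2L) {
    return("s1/s2 must be two-column matrices")
  }
  TRUE
})

#' RankingModel: a trained pose-ranking regressor
#'
#' @slot kind "linear" or "svr_rbf".
#' @slot featureOrder attribute names in model order.
#' @slot fit parameter list. For "linear": \code{weights} (named),
#'   \code{intercept}. For "svr_rbf": either a fitted e1071 svm object
#'   (\code{svm}) or the raw expansion (\code{SV} matrix, \code{coefs},
#'   \code{rho}, \code{gamma}) reconstructed from serialization.
#' @slot trainingMeta list recording seed, hyperparameters, fold
#'   assignment and anything needed to reproduce training.
#' @exportClass RankingModel
setClass("RankingModel", representation(kind = "character",
                                        featureOrder = "character",
                                        fit = "list",
                                        trainingMeta = "list"))

setValidity("RankingModel", function(object) {
  if (!object@kind %in% c("linear", "svr_rbf")) {
    return("kind must be 'linear' or 'svr_rbf'")
  }
  if (length(object@featureOrder) == 0L) return("empty featureOrder")
  if (object@kind == "linear") {
    w <- object@fit$weights
    if (is.null(w) || length(w) != length(object@featureOrder)) {
      return("linear weights must match featureOrder length")
    }
  }
  TRUE
})

#' SyntheticBenchmark: a generated multi-target docking benchmark
#'
#' @slot targets named list; each element is a list with components
#'   \code{native} (DimerPose), \code{ensemble} (list of DimerPose),
#'   \code{irmsd} (named numeric, truth per pose), \code{probs}
#'   (probability table data.frame), \code{potential} (potential table),
#'   \code{energies} (named numeric).
#' @slot seed integer seed the benchmark was generated from.
#' @slot params generation parameter list.
#' @exportClass SyntheticBenchmark
setClass("SyntheticBenchmark", representation(targets = "list",
                                              seed = "integer",
                                              params = "list"))

setValidity("SyntheticBenchmark", function(object) {
  if (length(object@targets) == 0L) return("no targets")
  need <- c("native", "ensemble", "irmsd", "probs", "potential", "energies")
  ok <- vapply(object@targets, function(t) all(need %in% names(t)), logical(1))
  if (!all(ok)) return("each target needs native/ensemble/irmsd/probs/potential/energies")
  TRUE
})

setMethod("show", "ChainModel", function(object) {
  a <- object@atoms
  cat(sprintf("ChainModel '%s': %d residues, %d heavy atoms\n",
              object@chainId, max(a$seqIndex) + 1L, nrow(a)))
})

setMethod("show", "DimerPose", function(object) {
  cat(sprintf("DimerPose '%s': receptor %s (%d res), ligand %s (%d res)%s\n",
              object@poseId,
              object@receptor@chainId, nResidues(object@receptor),
              object@ligand@chainId, nResidues(object@ligand),
              if (is.na(object@externalEnergy)) ""
              else sprintf(", energy %.3f", object@externalEnergy)))
})

setMethod("show", "ContactSet", function(object) {
  cat(sprintf("ContactSet (%s basis, cutoff %.1f A): %d residue pairs\n",
              object@basis, object@cutoff, nrow(object@pairs)))
})

setMethod("show", "CbsResult", function(object) {
  cat(sprintf("CBS = %.4f  (|S1| = %d, |S2| = %d, self pairs excluded = %d, mode = %s%s)\n",
              object@cbs, nrow(object@s1), nrow(object@s2), object@nSelf,
              object@mode,
              if (object@emptyUnion) ", empty union -> 0 by convention" else ""))
})

setMethod("show", "RankingModel", function(object) {
  cat(sprintf("RankingModel kind = %s, features = [%s]\n", object@kind,
              paste(object@featureOrder, collapse = ", ")))
  if (object@kind == "linear") {
    cat("  weights:", paste(sprintf("%s = %.4g", object@featureOrder,
                                    object@fit$weights), collapse = ", "),
        sprintf(" intercept = %.4g\n", object@fit$intercept))
  }
})

setMethod("show", "SyntheticBenchmark", function(object) {
  np <- vapply(object@targets, function(t) length(t$ensemble), integer(1))
  cat(sprintf("SyntheticBenchmark: %d targets, %d-%d poses/target, seed %d\n",
              length(object@targets), min(np), max(np), object@seed))
})
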