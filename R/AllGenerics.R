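#' @include AllClasses.R
NULL

#' Accessors for poseRank classes
#'
#' Small accessor generics so that slots are never reached into
#' directly: \code{chainId}, \code{atoms}, \code{nResidues},
#' \code{poseId}, \code{receptor}, \code{ligand},
#' \code{externalEnergy}, \code{contactPairs}, \code{contactCutoff},
#' \code{cbs}, \code{modelKind}, \code{featureOrder},
#' \code{benchmarkTargets}.
#'
#' @param x an object of the matching class.
#' @return the slot value.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("poseId", function(x) standardGeneric("poseId"))
#' @rdname accessors
#' @export
setGeneric("receptor", function(x) standardGeneric("receptor"))
#' @rdname accessors
#' @export
setGeneric("ligand", function(x) standardGeneric("ligand"))
#' @rdname accessors
#' @export
setGeneric("externalEnergy", function(x) standardGeneric("externalEnergy"))
#' @rdname accessors
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))
#' @rdname accessors
#' @export
setGeneric("contactCutoff", function(x) standardGeneric("contactCutoff"))
#' @rdname accessors
#' @export
setGeneric("cbs", function(x) standardGeneric("cbs"))
#' @rdname accessors
#' @export
setGeneric("modelKind", function(x) standardGeneric("modelKind"))
#' @rdname accessors
#' @export
setGeneric("featureOrder", function(x) standardGeneric("featureOrder"))
#' @rdname accessors
#' @export
setGeneric("benchmarkTargets", function(x) standardGeneric("benchmarkTargets"))

#' @rdname accessors
#' @export
setMethod("chainId", "ChainModel", function(x) x@chainId)
#' @rdname accessors
#' @export
setMethod("atoms", "ChainModel", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("nResidues", "ChainModel", function(x) max(x@atoms$seqIndex) + 1L)
#' @rdname accessors
#' @export
setMethod("poseId", "DimerPose", function(x) x@poseId)
#' @rdname accessors
#' @export
setMethod("receptor", "DimerPose", function(x) x@receptor)
#' @rdname accessors
#' @export
setMethod("ligand", "DimerPose", function(x) x@ligand)
#' @rdname accessors
#' @export
setMethod("externalEnergy", "DimerPose", function(x) x@externalEnergy)
#' @rdname accessors
#' @export
setMethod("contactPairs", "ContactSet", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("contactCutoff", "ContactSet", function(x) x@cutoff)
#' @rdname accessors
#' @export
setMethod("cbs", "CbsResult", function(x) x@cbs)
#' @rdname accessors
#' @export
setMethod("modelKind", "RankingModel", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("featureOrder", "RankingModel", function(x) x@featureOrder)
#' @rdname accessors
#' @export
setMethod("benchmarkTargets", "SyntheticBenchmark", function(x) x@targets)

#' Contact-based symmetry score (generic)
#'
#' Dispatches on \linkS4class{DimerPose} (contacts computed at
#' \code{cutoff}, residue correspondence resolved automatically) or on a
#' precomputed \linkS4class{ContactSet} (residue numbers must already be
#' comparable across chains).
#'
#' @param x a DimerPose or ContactSet.
#' @param ... passed to methods (e.g. \code{cutoff}).
#' @return a \linkS4class{CbsResult}.
#' @export
setGeneric("cbsScore", function(x, ...) standardGeneric("cbsScore"))
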