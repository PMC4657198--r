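# Interface-RMSD-supervised pose ranking: epsilon-SVR with an RBF
# kernel for homo-dimers, linear regression for hetero-dimers. Models
# predict iRMSD from standardized attributes; poses are ranked
# ascending by prediction so near-native structures get low ranks.

.CANON_FEATURES <- c("z_svc", "z_nbc", "z_potential", "z_energy", "z_cbs")

.featureMatrix <- function(features, featureOrder) {
  missing <- setdiff(featureOrder, names(features))
  if (length(missing)) {
    stop("feature table lacks attribute(s): ",
         paste(missing, collapse = ", "))
  }
  as.matrix(features[, featureOrder, drop = FALSE])
}

#' Train a pose-ranking regressor
#'
#' Fits a regressor of iRMSD on the standardized pose attributes:
#' either epsilon-SVR with an RBF kernel (e1071/LIBSVM;
#' \code{kind = "svr_rbf"}, used for homo-dimers) or ordinary linear
#' regression (\code{kind = "linear"}, used for hetero-dimers).
#' Features must already be standardized per target. Default SVR
#' hyperparameters are cost = 1, epsilon = 0.1, gamma = 1/d; pass
#' \code{hyperparams = list(grid = TRUE)} for a small seeded grid
#' search over cost and gamma inside the training data.
#'
#' @param features data.frame with \code{pose_id} and \code{z_}
#'   attribute columns (from \code{\link{featurize}}), possibly pooled
#'   over several targets.
#' @param labels named numeric vector of iRMSD values keyed by pose id;
#'   every pose needs a finite label.
#' @param kind "svr_rbf" or "linear".
#' @param hyperparams optional list: \code{cost}, \code{epsilon},
#'   \code{gamma}, \code{grid}.
#' @param seed integer recorded in the training metadata and used for
#'   any internal resampling (grid search).
#' @param featureOrder attribute columns to use; defaults to the
#'   canonical order (svc, nbc, potential, energy, cbs) intersected
#'   with the columns present.
#' @return a \linkS4class{RankingModel}.
#' @export
trainRanker <- function(features, labels, kind = c("svr_rbf", "linear"),
                        hyperparams = list(), seed = 1L,
                        featureOrder = NULL) {
  kind <- match.arg(kind)
  if (is.null(featureOrder)) {
    featureOrder <- intersect(.CANON_FEATURES, names(features))
  }
  if (!all(features$pose_id %in% names(labels))) {
    stop("label/feature key mismatch: poses without a label")
  }
  y <- unname(labels[features$pose_id])
  if (any(!is.finite(y))) stop("non-finite labels")
  X <- .featureMatrix(features, featureOrder)
  d <- ncol(X)
  if (kind == "linear") {
    fitlm <- stats::lm.fit(cbind(1, X), y)
    cf <- fitlm$coefficients
    fit <- list(weights = stats::setNames(cf[-1], featureOrder),
                intercept = unname(cf[1]))
    meta <- list(kind = kind, seed = as.integer(seed), n = nrow(X),
                 orientation = "irmsd")
  } else {
    hp <- utils::modifyList(list(cost = 1, epsilon = 0.1, gamma = 1 / d,
                                 grid = FALSE), hyperparams)
    if (isTRUE(hp$grid)) {
      hp <- .withSeed(seed, .svrGridSearch(X, y, hp))
    }
    sv <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                     cost = hp$cost, epsilon = hp$epsilon,
                     gamma = hp$gamma, scale = FALSE)
    fit <- list(svm = sv, SV = unname(sv$SV),
                coefs = as.numeric(sv$coefs), rho = sv$rho,
                gamma = hp$gamma)
    meta <- list(kind = kind, seed = as.integer(seed), n = nrow(X),
                 orientation = "irmsd",
                 hyperparams = hp[c("cost", "epsilon", "gamma")])
  }
  new("RankingModel", kind = kind, featureOrder = featureOrder,
      fit = fit, trainingMeta = meta)
}

# small grid search on an internal 80/20 split; returns updated hp
.svrGridSearch <- function(X, y, hp) {
  n <- nrow(X)
  val <- sample(n, max(1L, round(0.2 * n)))
  best <- hp
  bestErr <- Inf
  for (cost in c(0.5, 1, 2)) {
    for (gmul in c(0.5, 1, 2)) {
      g <- gmul / ncol(X)
      sv <- e1071::svm(X[-val, , drop = FALSE], y[-val],
                       type = "eps-regression", kernel = "radial",
                       cost = cost, epsilon = hp$epsilon, gamma = g,
                       scale = FALSE)
      err <- sqrt(mean((stats::predict(sv, X[val, , drop = FALSE]) -
                          y[val])^2))
      if (err < bestErr) {
        bestErr <- err
        best <- utils::modifyList(hp, list(cost = cost, gamma = g))
      }
    }
  }
  best
}

# raw model prediction on a feature matrix
.predictRaw <- function(model, X) {
  if (model@kind == "linear") {
    drop(X %*% model@fit$weights) + model@fit$intercept
  } else {
    SV <- model@fit$SV
    K <- exp(-model@fit$gamma * .crossDist2(X, SV))
    drop(K %*% model@fit$coefs) - model@fit$rho
  }
}

#' Predict and rank a pose ensemble
#'
#' Applies a trained \linkS4class{RankingModel} to an ensemble's
#' feature table and assigns ranks 1..N ascending by predicted iRMSD
#' (lower predicted iRMSD = better pose), with ties broken by
#' ascending pose id. Models whose training metadata declare
#' \code{orientation = "quality"} (higher score = better, e.g. the
#' shipped hetero-dimer weights) are sorted descending by score; the
#' reported \code{pred} column is then the negated score so that the
#' "sort ascending by pred" contract still holds.
#'
#' @param model a \linkS4class{RankingModel}.
#' @param features ensemble feature data.frame.
#' @return data.frame (pose_id, pred, rank), sorted by rank.
#' @export
predictRank <- function(model, features) {
  X <- .featureMatrix(features, model@featureOrder)
  pred <- .predictRaw(model, X)
  if (identical(model@trainingMeta$orientation, "quality")) pred <- -pred
  ord <- order(pred, features$pose_id)
  out <- data.frame(pose_id = features$pose_id[ord], pred = pred[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Two-fold cross-validated ranking over a set of targets
#'
#' Splits targets (never individual poses) into \code{nFolds} folds by
#' a seeded random permutation; each target's ensemble is ranked by the
#' model trained on the poses of the other fold's targets, so no
#' target's poses ever inform its own ranking.
#'
#' @param targets named list; each element a list with \code{features}
#'   (data.frame from \code{\link{featurize}}) and \code{labels}
#'   (named iRMSD vector).
#' @param kind passed to \code{\link{trainRanker}}.
#' @param seed integer; fold assignment is reproducible from it.
#' @param nFolds number of folds (default 2).
#' @param hyperparams passed to \code{\link{trainRanker}}.
#' @param featureOrder passed to \code{\link{trainRanker}}.
#' @return list with \code{rankings} (named list of ranking
#'   data.frames), \code{folds} (named integer fold assignment) and
#'   \code{models} (one \linkS4class{RankingModel} per fold).
#' @export
crossValidate <- function(targets, kind = c("svr_rbf", "linear"),
                          seed = 1L, nFolds = 2L, hyperparams = list(),
                          featureOrder = NULL) {
  kind <- match.arg(kind)
  nT <- length(targets)
  if (nT < nFolds) stop("fewer targets (", nT, ") than folds (", nFolds, ")")
  if (is.null(names(targets)) || anyDuplicated(names(targets))) {
    stop("targets must be uniquely named")
  }
  perm <- .withSeed(seed, sample(names(targets)))
  folds <- stats::setNames(rep(seq_len(nFolds), length.out = nT), perm)
  folds <- folds[names(targets)]
  models <- vector("list", nFolds)
  rankings <- vector("list", nT)
  names(rankings) <- names(targets)
  for (f in seq_len(nFolds)) {
    trainNames <- names(folds)[folds != f]
    feats <- do.call(rbind, lapply(targets[trainNames],
                                   function(t) t$features))
    labels <- do.call(c, lapply(targets[trainNames],
                                function(t) t$labels))
    names(labels) <- unlist(lapply(targets[trainNames],
                                   function(t) names(t$labels)),
                            use.names = FALSE)
    models[[f]] <- trainRanker(feats, labels, kind, hyperparams,
                               seed = seed, featureOrder = featureOrder)
    models[[f]]@trainingMeta$fold <- f
    models[[f]]@trainingMeta$trainTargets <- trainNames
    for (tn in names(folds)[folds == f]) {
      rankings[[tn]] <- predictRank(models[[f]], targets[[tn]]$features)
    }
  }
  list(rankings = rankings, folds = folds, models = models)
}

#' The shipped hetero-dimer linear ranking weights
#'
#' Linear model over the four hetero-dimer attributes with the
#' published optimized weights: SVC interface score 171.9, NBC
#' interface score 891.8, docking potential 122.7, external energy
#' 2.2; intercept 0. The weights' published magnitudes do not fix the
#' scoring direction, so the orientation is explicit: the default
#' \code{"quality"} treats the weighted sum as a quality score (higher
#' = better; large positive weights on interface-probability scores
#' most plausibly reward good poses), while \code{"irmsd"} treats it as
#' a predicted iRMSD (lower = better). \code{\link{predictRank}} honors
#' the orientation; the stored weight vector is identical either way.
#'
#' @param orientation "quality" (default) or "irmsd".
#' @return a \linkS4class{RankingModel} of kind "linear" with
#'   featureOrder (z_svc, z_nbc, z_potential, z_energy).
#' @export
defaultHeteroModel <- function(orientation = c("quality", "irmsd")) {
  orientation <- match.arg(orientation)
  fo <- c("z_svc", "z_nbc", "z_potential", "z_energy")
  new("RankingModel", kind = "linear", featureOrder = fo,
      fit = list(weights = stats::setNames(c(171.9, 891.8, 122.7, 2.2),
                                           fo),
                 intercept = 0),
      trainingMeta = list(kind = "linear", orientation = orientation,
                          source = "shipped default"))
}

#' Serialize a ranking model to JSON
#'
#' Linear models store weights and intercept; SVR models store the
#' support-vector expansion (support vectors, dual coefficients,
#' offset, kernel width), which is exactly what prediction uses, so
#' the round trip is lossless for prediction.
#'
#' @param model a \linkS4class{RankingModel}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeRankingModel <- function(model, path) {
  fit <- model@fit
  fit$svm <- NULL  # external object; the expansion fields suffice
  doc <- list(kind = model@kind, featureOrder = model@featureOrder,
              fit = fit, trainingMeta = model@trainingMeta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ranking model from JSON
#' @param path JSON path written by \code{\link{writeRankingModel}}.
#' @return a \linkS4class{RankingModel}.
#' @export
readRankingModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- doc$fit
  if (doc$kind == "linear") {
    fit$weights <- stats::setNames(as.numeric(fit$weights),
                                   doc$featureOrder)
  } else {
    fit$SV <- matrix(as.numeric(fit$SV), ncol = length(doc$featureOrder))
    fit$coefs <- as.numeric(fit$coefs)
  }
  meta <- doc$trainingMeta
  if (is.null(meta)) meta <- list()
  new("RankingModel", kind = doc$kind,
      featureOrder = doc$featureOrder, fit = fit, trainingMeta = meta)
}
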