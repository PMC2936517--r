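# extract primal weights from a linear-kernel libsvm fit
.primalWeights <- function(fit) {
  w <- drop(crossprod(fit$coefs, fit$SV))
  list(weights = as.numeric(w), bias = -fit$rho)
}

.rocAuc <- function(labels, scores) {
  as.numeric(pROC::auc(response = factor(labels, levels = c(-1, 1)),
                       predictor = scores, direction = "<", quiet = TRUE))
}

#' Train an epsilon-insensitive SVR on PBM probes
#'
#' Fits epsilon-insensitive support-vector regression with a linear kernel in
#' the explicit (selected) di-mismatch feature space and returns the primal
#' solution: one weight per k-mer feature plus a bias. Unless a feature
#' \code{space} is supplied, the candidate dictionary is built from the
#' sampled probe sequences and reduced with \code{\link{selectFeatures}}.
#'
#' @param sample a \linkS4class{TrainingSample}; labels are the normalized
#'   intensities.
#' @param config a \linkS4class{TrainingConfig} with
#'   \code{mode = "regression"}.
#' @param space optional pre-built \linkS4class{FeatureSpace}; when given,
#'   feature selection is skipped and the space is used as-is.
#' @param costGrid optional grid of regularization constants C. When
#'   supplied, C is chosen by \code{tuneFolds}-fold cross-validation within
#'   the training sample (held-out Spearman correlation), a standard nested
#'   model-selection step that never sees test data; \code{config@cost} is
#'   used as-is when \code{costGrid} is NULL.
#' @param tuneFolds,tuneSeed folds and seed for the internal cost selection.
#' @return A \linkS4class{LinearSequenceModel}.
#' @export
trainRegressor <- function(sample, config = trainingConfig(), space = NULL,
                           costGrid = NULL, tuneFolds = 5, tuneSeed = 1) {
  if (config@mode != "regression") stop("config mode must be 'regression'")
  seqs <- c(sample@positives@sequence, sample@negatives@sequence)
  y <- sample@labels
  if (is.null(space)) {
    space <- buildFeatureSpace(seqs, config@params)
    space <- selectFeatures(sample, space, config@maxFeatures)
  }
  prov <- sprintf("SVR on %d probes from '%s', %d features",
                  length(seqs), sample@positives@designId, length(space))
  if (stats::sd(y) == 0) {
    warning("degenerate labels (all equal); returning a constant model")
    return(new("LinearSequenceModel", space = space,
               weights = numeric(length(space)), bias = y[1L],
               config = config, provenance = prov))
  }
  X <- featureMap(seqs, space)
  fitOne <- function(rows, cost)
    e1071::svm(x = X[rows, , drop = FALSE], y = y[rows],
               type = "eps-regression", kernel = "linear", cost = cost,
               epsilon = config@epsilon, scale = FALSE, fitted = FALSE)
  if (!is.null(costGrid)) {
    set.seed(tuneSeed)
    fold <- sample(rep_len(seq_len(tuneFolds), nrow(X)))
    cv <- vapply(costGrid, function(cost) {
      mean(vapply(seq_len(tuneFolds), function(f) {
        fit <- fitOne(fold != f, cost)
        stats::cor(as.numeric(stats::predict(fit, X[fold == f, , drop = FALSE])),
                   y[fold == f], method = "spearman")
      }, numeric(1)))
    }, numeric(1))
    config@cost <- costGrid[which.max(cv)]
    prov <- sprintf("%s, CV-selected C = %g", prov, config@cost)
  }
  fit <- fitOne(seq_len(nrow(X)), config@cost)
  pw <- .primalWeights(fit)
  new("LinearSequenceModel", space = space, weights = pw$weights,
      bias = pw$bias, config = config, provenance = prov)
}

#' Train a binary SVM on ChIP windows
#'
#' Fits a soft-margin linear SVM in the explicit di-mismatch feature space on
#' peak (+1) versus flank (-1) windows. Feature selection by class-mean
#' difference is applied exactly as for the SVR. The returned weights are
#' oriented so that higher decision values indicate the positive class.
#'
#' @param windows a \linkS4class{LabeledWindowSet}.
#' @param config a \linkS4class{TrainingConfig} with
#'   \code{mode = "classification"}; the standard in vivo model keeps
#'   (k, m) = (13, 5) fixed.
#' @param space optional pre-built \linkS4class{FeatureSpace} (skips
#'   selection).
#' @return A \linkS4class{LinearSequenceModel}.
#' @export
trainClassifier <- function(windows,
                            config = trainingConfig(mode = "classification"),
                            space = NULL) {
  if (config@mode != "classification") stop("config mode must be 'classification'")
  y <- windows@labels
  if (length(unique(y)) < 2L) stop("both classes must be present")
  seqs <- windows@sequences
  if (is.null(space)) {
    space <- buildFeatureSpace(seqs, config@params)
    space <- .selectByClassMeans(seqs[y == 1L], seqs[y == -1L], space,
                                 config@maxFeatures)
  }
  X <- featureMap(seqs, space)
  fit <- e1071::svm(x = X, y = factor(y, levels = c(-1, 1)),
                    type = "C-classification", kernel = "linear",
                    cost = config@cost, scale = FALSE, fitted = FALSE)
  pw <- .primalWeights(fit)
  s <- as.numeric(X %*% pw$weights) + pw$bias
  if (mean(s[y == 1L]) < mean(s[y == -1L])) {
    pw$weights <- -pw$weights
    pw$bias <- -pw$bias
  }
  new("LinearSequenceModel", space = space, weights = pw$weights,
      bias = pw$bias, config = config,
      provenance = sprintf("SVM on %d windows, %d features",
                           length(seqs), length(space)))
}

#' Score sequences with a trained model
#'
#' Computes \code{weights . featureMap(sequence) + bias} for each sequence
#' through the precomputed k-mer contribution table (one hash lookup per
#' window), which is exactly equivalent to materializing the feature vector.
#'
#' @param model a \linkS4class{LinearSequenceModel}.
#' @param sequences character vector or \code{DNAStringSet}, each at least k
#'   long.
#' @return Numeric vector of model scores.
#' @export
predictScores <- function(model, sequences) {
  sequences <- .asSeqChar(sequences)
  params <- model@config@params
  if (any(nchar(sequences) < params@k)) stop("sequence shorter than k")
  cpp_predict_seqs(sequences, model@space@features, model@weights,
                   model@bias, params@k, minMatchingDinucs(params),
                   params@strandMode == "both")
}

#' Detection of the top n items
#'
#' The size of the intersection between the n highest-predicted and the n
#' highest-measured items. Ties are broken by item id so the statistic is
#' invariant to input ordering.
#'
#' @param predScores,trueScores equal-length score vectors over the same
#'   items.
#' @param n size of the top lists (100 in the standard probe evaluation).
#' @param ids item identifiers; defaults to positions.
#' @return Integer in [0, n].
#' @export
detectionTopN <- function(predScores, trueScores, n, ids = NULL) {
  if (length(predScores) != length(trueScores))
    stop("score vectors must have equal length")
  if (n > length(predScores)) stop("'n' exceeds the number of items")
  if (is.null(ids)) ids <- as.character(seq_along(predScores))
  topPred <- ids[order(-predScores, ids)][seq_len(n)]
  topTrue <- ids[order(-trueScores, ids)][seq_len(n)]
  length(intersect(topPred, topTrue))
}

#' Cross-design evaluation of PBM models
#'
#' The full in vitro protocol: normalize the training design, sample the
#' intensity tails, select features, train an SVR, score every probe of the
#' held-out design, and count the detection of its top \code{nTop} probes.
#' Run in both directions and averaged, as in the standard cross-design
#' benchmark.
#'
#' @param designA,designB \linkS4class{ProbeSet}s with disjoint probe
#'   sequences.
#' @param config \linkS4class{TrainingConfig}.
#' @param nTop size of the detection top list.
#' @param zThreshold,minPositives passed to
#'   \code{\link{sampleTrainingProbes}}.
#' @param costGrid grid for the internal cost selection of
#'   \code{\link{trainRegressor}} (set NULL to use \code{config@cost}
#'   directly).
#' @return List with per-direction detections, their average, and the two
#'   trained models.
#' @export
crossDesignEvaluate <- function(designA, designB, config = trainingConfig(),
                                nTop = 100, zThreshold = 4,
                                minPositives = 500,
                                costGrid = 10^seq(-5, 0)) {
  oneWay <- function(train, test) {
    train <- normalizeIntensities(train)
    test <- normalizeIntensities(test)
    sample <- sampleTrainingProbes(train, zThreshold, minPositives)
    model <- trainRegressor(sample, config, costGrid = costGrid)
    pred <- predictScores(model, test@sequence)
    list(model = model,
         detection = detectionTopN(pred, test@normalized, nTop, test@id))
  }
  ab <- oneWay(designA, designB)
  ba <- oneWay(designB, designA)
  list(detection = c(AtoB = ab$detection, BtoA = ba$detection),
       average = mean(c(ab$detection, ba$detection)),
       models = list(AtoB = ab$model, BtoA = ba$model))
}

#' Stratified cross-validated AUC of the ChIP classifier
#'
#' Splits the windows into stratified folds, runs the complete training
#' pipeline (feature-space construction, class-mean feature selection, SVM
#' fit) on each training split, and computes the ROC AUC of the decision
#' values on the held-out fold. Keeping feature selection inside the folds
#' avoids selection bias, so label permutations yield AUC near 0.5.
#'
#' @param windows a \linkS4class{LabeledWindowSet}.
#' @param config \linkS4class{TrainingConfig} (classification).
#' @param folds number of folds (10 in the standard protocol).
#' @param seed seed for the fold assignment.
#' @return List with \code{mean} and per-fold AUCs.
#' @export
crossvalAUC <- function(windows,
                        config = trainingConfig(mode = "classification"),
                        folds = 10, seed = 1) {
  y <- windows@labels
  if (min(table(y)) < folds)
    stop("each class needs at least ", folds, " windows for stratification")
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(-1L, 1L)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  seqs <- windows@sequences
  params <- config@params
  # candidate dictionary from sequences only (label-free, fold-independent);
  # per-fold class means are recovered from one grouped pairwise pass:
  # sum over a training fold = total class sum - held-out fold sum
  space <- buildFeatureSpace(seqs, params)
  group <- (fold - 1L) + folds * (y == 1L)
  S <- cpp_group_sum_scores(seqs, group, 2L * folds, space@features,
                            params@k, minMatchingDinucs(params),
                            params@strandMode == "both")
  nNeg <- tabulate(fold[y == -1L], folds)
  nPos <- tabulate(fold[y == 1L], folds)
  totNeg <- colSums(S[seq_len(folds), , drop = FALSE])
  totPos <- colSums(S[folds + seq_len(folds), , drop = FALSE])
  perFold <- vapply(seq_len(folds), function(f) {
    meanPos <- (totPos - S[folds + f, ]) / (sum(nPos) - nPos[f])
    meanNeg <- (totNeg - S[f, ]) / (sum(nNeg) - nNeg[f])
    d <- abs(meanPos - meanNeg)
    keep <- order(-d, space@features)[seq_len(min(config@maxFeatures, length(d)))]
    sub <- new("FeatureSpace", features = sort(space@features[keep]),
               params = params)
    tr <- fold != f
    model <- trainClassifier(
      new("LabeledWindowSet", sequences = seqs[tr], labels = y[tr],
          origin = windows@origin[tr]), config, space = sub)
    .rocAuc(y[!tr], predictScores(model, seqs[!tr]))
  }, numeric(1))
  list(mean = mean(perFold), perFold = perFold)
}

#' Serialize / restore a linear sequence model
#'
#' Writes a JSON header (configuration and provenance) alongside a
#' feature/weight TSV; \code{readModel} restores the model exactly.
#'
#' @param model a \linkS4class{LinearSequenceModel}.
#' @param prefix path prefix; \code{<prefix>.json} and
#'   \code{<prefix>_weights.tsv} are written.
#' @export
writeModel <- function(model, prefix) {
  cfg <- model@config
  p <- cfg@params
  header <- list(mode = cfg@mode, epsilon = cfg@epsilon, cost = cfg@cost,
                 k = p@k, m = p@m, strandMode = p@strandMode,
                 maxFeatures = cfg@maxFeatures, bias = model@bias,
                 provenance = model@provenance)
  jsonlite::write_json(header, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(
    data.frame(feature = model@space@features, weight = model@weights,
               stringsAsFactors = FALSE),
    paste0(prefix, "_weights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(prefix)
}

#' @rdname writeModel
#' @export
readModel <- function(prefix) {
  header <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- utils::read.delim(paste0(prefix, "_weights.tsv"),
                           stringsAsFactors = FALSE)
  ord <- order(tab$feature)
  params <- diMismatchParams(header$k, header$m, header$strandMode)
  cfg <- trainingConfig(epsilon = header$epsilon, cost = header$cost,
                        params = params, maxFeatures = header$maxFeatures,
                        mode = header$mode)
  new("LinearSequenceModel",
      space = new("FeatureSpace", features = tab$feature[ord], params = params),
      weights = tab$weight[ord], bias = header$bias, config = cfg,
      provenance = as.character(header$provenance))
}
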