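#' Threshold-level classification metrics
#'
#' Sensitivity, specificity and accuracy in percent plus the Matthews
#' correlation coefficient from a confusion matrix. When any factor of
#' the MCC denominator is zero (a degenerate predictor or degenerate
#' truth), MCC is defined as 0.
#'
#' @param tp,fp,tn,fn confusion counts (`tp+fn >= 1`, `tn+fp >= 1`).
#' @return named vector `c(sen, spec, acc, mcc)`.
#' @examples
#' confusion_metrics(10, 0, 10, 0) # perfect classifier
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  if (tp + fn < 1) stop("no positive examples (tp + fn = 0)", call. = FALSE)
  if (tn + fp < 1) stop("no negative examples (tn + fp = 0)", call. = FALSE)
  sen <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / (tp + fp + tn + fn)
  den <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(den == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(prod(den))
  c(sen = sen, spec = spec, acc = acc, mcc = mcc)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Threshold-free area under the ROC curve computed from ranks:
#' the probability that a random positive scores above a random
#' negative, counting ties as 1/2.
#'
#' @param scores numeric decision scores.
#' @param labels logical or `"positive"`/`"negative"` labels (anything
#'   coercible via [as_binary_labels()]).
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  np <- sum(y); nn <- sum(!y)
  if (np == 0L || nn == 0L)
    stop("AUC needs at least one positive and one negative", call. = FALSE)
  r <- rank(scores)
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

#' Coerce labels to logical (TRUE = positive)
#'
#' Accepts logical vectors, the `oligo_set` labels
#' `"positive"`/`"negative"`, `"pos"`/`"neg"`, factors thereof, or 0/1.
#'
#' @param labels label vector.
#' @return logical vector.
#' @export
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(labels == 1)
  }
  l <- tolower(as.character(labels))
  if (!all(l %in% c("positive", "negative", "pos", "neg")))
    stop("labels must be positive/negative", call. = FALSE)
  l %in% c("positive", "pos")
}

#' Threshold sweep evaluation
#'
#' Evaluates scored, labelled examples at every threshold of a grid
#' (default -1..1 by 0.1, the decision-score scale of the SVM models):
#' predictions are positive when `score >= threshold`. Reports per-row
#' Sen/Spec/Acc/MCC, the threshold-free AUC, and the row maximizing MCC.
#'
#' @param scores numeric decision scores.
#' @param labels see [as_binary_labels()].
#' @param thresholds numeric grid.
#' @return an `eval_report`: data frame (threshold, sen, spec, acc, mcc)
#'   with attributes `auc`, `best` (row index of maximal MCC, first on
#'   ties), `scores`, `labels`.
#' @export
threshold_sweep <- function(scores, labels, thresholds = seq(-1, 1, by = 0.1)) {
  stopifnot(length(thresholds) >= 1)
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  rows <- t(vapply(thresholds, function(t) {
    pred <- scores >= t
    confusion_metrics(sum(pred & y), sum(pred & !y),
                      sum(!pred & !y), sum(!pred & y))
  }, c(sen = 0, spec = 0, acc = 0, mcc = 0)))
  out <- data.frame(threshold = thresholds, rows)
  attr(out, "auc") <- rank_auc(scores, y)
  attr(out, "best") <- which.max(out$mcc)
  attr(out, "scores") <- scores
  attr(out, "labels") <- y
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> AUC =", round(attr(x, "auc"), 3), "\n")
  print.data.frame(round(as.data.frame(x), 4))
  b <- attr(x, "best")
  cat(sprintf("best MCC %.3f at threshold %.2f\n", x$mcc[b], x$threshold[b]))
  invisible(x)
}

#' Best row of an evaluation report
#'
#' @param report an `eval_report`.
#' @return one-row data frame (threshold, sen, spec, acc, mcc) plus `auc`.
#' @export
best_row <- function(report) {
  b <- attr(report, "best")
  out <- as.data.frame(report)[b, , drop = FALSE]
  out$auc <- attr(report, "auc")
  rownames(out) <- NULL
  out
}

#' Write an evaluation report as TSV
#'
#' Column order mirrors the conventional performance tables:
#' Thres, Sen, Spec, Acc, MCC, AUC.
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  df <- data.frame(Thres = report$threshold, Sen = report$sen,
                   Spec = report$spec, Acc = report$acc, MCC = report$mcc,
                   AUC = attr(report, "auc"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default SVM hyperparameter grid
#'
#' Cost/width grid searched by [train_svm()]. Widths below 2^-7 matter
#' for the high-dimensional percentage features (up to 1024 columns for
#' pentanucleotide composition), where larger kernel widths collapse the
#' decision function.
#'
#' @param cost cost values.
#' @param gamma RBF width values.
#' @return data frame of grid points.
#' @export
svm_grid <- function(cost = c(1, 16), gamma = 2^c(-11, -9, -7)) {
  expand.grid(cost = cost, gamma = gamma)
}

#' Train an RBF-kernel SVM on composition features
#'
#' Selects the cost/width grid point maximizing MCC at threshold 0 under
#' seeded internal stratified cross-validation, then refits on all data.
#' Decision scores are oriented so positives score high. Deterministic
#' given `seed`.
#'
#' @param X feature matrix (rows = examples).
#' @param y labels, see [as_binary_labels()]; at least 2 per class.
#' @param grid data frame from [svm_grid()].
#' @param seed integer seed for the internal fold assignment.
#' @param inner_folds folds of the internal selection CV.
#' @param class_weights if `TRUE`, per-class error weights proportional
#'   to inverse class frequency (for imbalanced, "realistic" training).
#' @param feature_k word length the features were computed with
#'   (recorded for downstream prediction on raw sequences).
#' @param provenance free-text training-set identifier.
#' @return an `imodn_model`.
#' @export
train_svm <- function(X, y, grid = svm_grid(), seed = 1, inner_folds = 3,
                      class_weights = FALSE, feature_k = NULL,
                      provenance = "") {
  y <- as_binary_labels(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (sum(y) < 2 || sum(!y) < 2)
    stop("need at least 2 examples per class", call. = FALSE)
  yf <- factor(ifelse(y, "positive", "negative"),
               levels = c("negative", "positive"))
  cw <- if (class_weights) {
    w <- length(y) / (2 * table(yf)); stats::setNames(as.numeric(w), names(w))
  } else NULL

  if (nrow(grid) > 1) {
    k <- min(inner_folds, sum(y), sum(!y))
    fold <- make_folds(y, k, seed)
    inner_mcc <- vapply(seq_len(nrow(grid)), function(g) {
      sc <- numeric(length(y))
      for (f in seq_len(k)) {
        tr <- fold != f
        fit <- fit_svm(X[tr, , drop = FALSE], yf[tr], grid$cost[g],
                       grid$gamma[g], cw)
        sc[!tr] <- svm_scores(fit, X[!tr, , drop = FALSE])
      }
      pred <- sc >= 0
      m <- confusion_metrics(sum(pred & y), sum(pred & !y),
                             sum(!pred & !y), sum(!pred & y))
      m[["mcc"]]
    }, numeric(1))
    best <- which.max(inner_mcc)
  } else best <- 1L

  fit <- fit_svm(X, yf, grid$cost[best], grid$gamma[best], cw)
  structure(list(svm = fit, cost = grid$cost[best], gamma = grid$gamma[best],
                 feature_k = feature_k, threshold = 0,
                 pos_motifs = NULL, neg_motifs = NULL, gap_max = 1,
                 class_weights = class_weights, seed = seed,
                 provenance = provenance),
            class = "imodn_model")
}

fit_svm <- function(X, yf, cost, gamma, class_weights = NULL) {
  e1071::svm(X, yf, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE,
             class.weights = class_weights)
}

# Decision scores oriented so that positives score high: libsvm labels
# the decision column "A/B" where positive values favor class A.
svm_scores <- function(fit, X) {
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  flip <- !startsWith(colnames(dv)[1], "positive")
  if (flip) -dv[, 1] else dv[, 1]
}

# Seeded stratified fold assignment: within each class, a shuffled
# 1..k recycling so per-class fold sizes differ by at most 1.
make_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      ix <- which(y == cl)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  fold
}

#' @export
print.imodn_model <- function(x, ...) {
  cat(sprintf("<imodn_model> RBF SVM (cost=%g, gamma=%g), k=%s, threshold=%g\n",
              x$cost, x$gamma, x$feature_k %||% "?", x$threshold))
  if (!is.null(x$pos_motifs))
    cat("hybrid: ", length(x$pos_motifs), " positive / ",
        length(x$neg_motifs), " negative motifs\n", sep = "")
  invisible(x)
}

#' Set the decision threshold recorded with a model
#'
#' @param model an `imodn_model`.
#' @param threshold new decision threshold.
#' @return the updated model.
#' @export
set_threshold <- function(model, threshold) {
  stopifnot(inherits(model, "imodn_model"), is.finite(threshold))
  model$threshold <- threshold
  model
}

#' Attach motif lists for hybrid scoring
#'
#' @param model an `imodn_model`.
#' @param pos_motifs,neg_motifs motif text forms (character vectors or
#'   `motif_table`s) discriminating the positive / negative class.
#' @param gap_max gap bound used when matching.
#' @return the updated model; [predict.imodn_model()] with
#'   `type = "hybrid"` and [hybrid_score()] then apply the +1/-1 rule.
#' @export
attach_motifs <- function(model, pos_motifs, neg_motifs = character(),
                          gap_max = 1) {
  stopifnot(inherits(model, "imodn_model"))
  as_motif_vec <- function(m)
    if (inherits(m, "data.frame")) as.character(m$motif) else as.character(m)
  model$pos_motifs <- as_motif_vec(pos_motifs)
  model$neg_motifs <- as_motif_vec(neg_motifs)
  model$gap_max <- gap_max
  model
}

#' Predict with a trained model
#'
#' @param object an `imodn_model`.
#' @param newdata an `oligo_set`, a character vector of sequences, or a
#'   precomputed feature matrix.
#' @param type `"score"` (SVM decision score), `"hybrid"` (motif-weighted
#'   score, see [hybrid_score()]), or `"call"`
#'   (`"IMODN"`/`"non-IMODN"` at the model threshold, on the hybrid score
#'   when motifs are attached).
#' @param ... unused.
#' @return numeric scores or character calls.
#' @export
predict.imodn_model <- function(object, newdata,
                                type = c("score", "hybrid", "call"), ...) {
  type <- match.arg(type)
  seqs <- NULL
  if (inherits(newdata, "oligo_set")) seqs <- newdata$seq
  else if (is.character(newdata)) seqs <- newdata
  if (!is.null(seqs)) {
    if (is.null(object$feature_k))
      stop("model lacks feature_k; supply a feature matrix", call. = FALSE)
    X <- featurize_set(oligo_set(seqs), object$feature_k)
  } else X <- as.matrix(newdata)
  sc <- svm_scores(object$svm, X)
  has_motifs <- !is.null(object$pos_motifs) || !is.null(object$neg_motifs)
  if (type %in% c("hybrid", "call") && has_motifs) {
    if (is.null(seqs))
      stop("hybrid scoring needs sequences, not a feature matrix",
           call. = FALSE)
    sc <- sc + motif_adjustment(object, seqs)
  }
  if (type == "call")
    ifelse(sc >= object$threshold, "IMODN", "non-IMODN")
  else sc
}

motif_adjustment <- function(model, seqs) {
  hit_any <- function(motifs) {
    if (is.null(motifs) || length(motifs) == 0) return(logical(length(seqs)))
    Reduce(`|`, lapply(motifs, function(m)
      motif_matches(m, seqs, model$gap_max)))
  }
  as.numeric(hit_any(model$pos_motifs)) - as.numeric(hit_any(model$neg_motifs))
}

#' Hybrid motif-weighted score
#'
#' The SVM decision score plus 1 if any attached positive-class motif
#' matches the oligo and minus 1 if any attached negative-class motif
#' matches (both may apply, netting 0). Without attached motifs the
#' score is unmodified. The adjustment is applied to the score before
#' any thresholding.
#'
#' @param model an `imodn_model` (see [attach_motifs()]).
#' @param oligo an `oligo_set`, sequence vector, or single sequence.
#' @return numeric hybrid scores.
#' @export
hybrid_score <- function(model, oligo) {
  predict(model, oligo, type = "hybrid")
}

#' Stratified k-fold cross-validation with pooled scoring
#'
#' Splits the labelled set into seeded stratified folds, scores each
#' fold with an SVM trained (including grid selection) on the remaining
#' folds, pools the held-out decision scores, and evaluates them with a
#' single [threshold_sweep()] and AUC. Pooling keeps the evaluation
#' deterministic and gives a single ROC.
#'
#' @param set a labelled `oligo_set` (each class count >= `folds`).
#' @param feature_k k-mer word length for the features.
#' @param grid hyperparameter grid, see [svm_grid()].
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling fold assignment and training.
#' @param thresholds threshold grid for the sweep.
#' @param ... passed to [train_svm()] (e.g. `class_weights`).
#' @return an `eval_report` on the pooled scores (attributes `scores`,
#'   `labels`, `fold`).
#' @export
cross_validate <- function(set, feature_k = 5, grid = svm_grid(), folds = 5,
                           seed = 1, thresholds = seq(-1, 1, by = 0.1), ...) {
  stopifnot(inherits(set, "oligo_set"))
  y <- as_binary_labels(set$label)
  if (min(sum(y), sum(!y)) < folds)
    stop("each class must have at least `folds` examples", call. = FALSE)
  X <- featurize_set(set, feature_k)
  fold <- make_folds(y, folds, seed)
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    m <- train_svm(X[tr, , drop = FALSE], y[tr], grid = grid,
                   seed = seed + f, feature_k = feature_k, ...)
    scores[!tr] <- svm_scores(m$svm, X[!tr, , drop = FALSE])
  }
  rep <- threshold_sweep(scores, y, thresholds)
  attr(rep, "fold") <- fold
  rep
}

#' Save / load a trained model
#'
#' Models are persisted as a JSON container holding the hyperparameters,
#' feature specification, motif lists, threshold and seed, plus the
#' serialized kernel machine (ASCII-armored), so model files are plain
#' text.
#'
#' @param model an `imodn_model`.
#' @param path file path.
#' @return `path` (save) or the restored `imodn_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "imodn_model"))
  payload <- list(
    cost = model$cost, gamma = model$gamma, feature_k = model$feature_k,
    threshold = model$threshold, pos_motifs = model$pos_motifs,
    neg_motifs = model$neg_motifs, gap_max = model$gap_max,
    class_weights = model$class_weights, seed = model$seed,
    provenance = model$provenance,
    svm = jsonlite::base64_enc(serialize(model$svm, NULL))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- unserialize(jsonlite::base64_dec(p$svm))
  structure(list(svm = fit, cost = p$cost, gamma = p$gamma,
                 feature_k = p$feature_k, threshold = p$threshold,
                 pos_motifs = unlist(p$pos_motifs),
                 neg_motifs = unlist(p$neg_motifs),
                 gap_max = p$gap_max %||% 1,
                 class_weights = isTRUE(p$class_weights),
                 seed = p$seed, provenance = p$provenance),
            class = "imodn_model")
}
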