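# Random-forest engine. Tree growing is delegated to the randomForest
# package (bagged CART with Gini splits); everything derived from the
# fitted ensemble -- out-of-bag vote scores, tie-aware AUC, proximity in
# both modes, external scoring -- is computed here from the stored in-bag
# indicators and per-tree terminal-node assignments so that each quantity
# is reproducible and auditable against its definition.

#' Fit a bootstrap ensemble of classification trees
#'
#' Grows `n_trees` CART trees on bootstrap samples (drawn with replacement,
#' sample size equal to the training-set size) and records, for every tree,
#' the in-bag count, terminal-node assignment and vote of every training
#' subject. Defaults follow classical random forests: `floor(sqrt(p))`
#' candidate features per split, unlimited depth, minimum node size 1.
#'
#' @param x Numeric matrix or data frame of features (subjects x features);
#'   finite values only.
#' @param labels Binary labels: a factor with two levels (first level =
#'   negative class, second = positive) or a vector coercible to one.
#' @param n_trees Number of trees (pipeline default is 4000; smaller values
#'   are fine for experimentation).
#' @param seed Integer seed; forests are bit-reproducible given seed and
#'   inputs.
#' @param mtry Features tried per split; default `floor(sqrt(ncol(x)))`.
#' @param nodesize Minimum terminal node size (default 1).
#' @return An object of class `forest_model`: the fitted `randomForest`
#'   object plus `inbag` (subjects x trees bootstrap counts), `leaves`
#'   (subjects x trees terminal-node ids), `votes` (subjects x trees logical,
#'   `TRUE` = positive vote), `feature_ids`, `class_labels`
#'   (negative, positive), `subject_ids` and `seed`.
#' @examples
#' x <- matrix(rnorm(60 * 4), 60)
#' y <- factor(rep(c("hc", "case"), each = 30), levels = c("hc", "case"))
#' x[y == "case", 1] <- x[y == "case", 1] + 3
#' fit <- fit_forest(x, y, n_trees = 100, seed = 1)
#' fit$n_trees
#' @export
fit_forest <- function(x, labels, n_trees = 4000L, seed = 1L, mtry = NULL,
                       nodesize = 1L) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop_("feature matrix must be numeric")
  if (any(!is.finite(x)))
    stop_("non-finite feature values are not allowed (first at row %d)",
          which(!is.finite(x))[1] %% nrow(x))
  check_count(n_trees, "n_trees", min = 1L)
  if (!is.factor(labels)) labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L)
    stop_("`labels` must contain exactly two classes, got %d",
          nlevels(labels))
  if (any(table(labels) < 2L))
    stop_("each class needs at least 2 subjects")
  if (length(labels) != nrow(x))
    stop_("length of labels (%d) does not match rows of x (%d)",
          length(labels), nrow(x))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- sprintf("s%03d", seq_len(nrow(x)))

  rf <- with_seed(seed, randomForest::randomForest(
    x, labels, ntree = n_trees, mtry = mtry, nodesize = nodesize,
    keep.inbag = TRUE, keep.forest = TRUE, importance = FALSE
  ))
  pred <- stats::predict(rf, x, predict.all = TRUE, nodes = TRUE)
  leaves <- attr(pred, "nodes")
  attr(pred, "nodes") <- NULL
  votes <- pred$individual == levels(labels)[2]
  inbag <- rf$inbag
  dimnames(inbag) <- dimnames(leaves) <- dimnames(votes) <-
    list(rownames(x), NULL)

  if (n_trees >= 50L) {
    never_oob <- rowSums(inbag == 0L) == 0L
    if (any(never_oob))
      stop_("subject(s) %s are in-bag in every tree; increase n_trees",
            paste(rownames(x)[never_oob], collapse = ", "))
  }
  out <- list(rf = rf, n_trees = as.integer(n_trees), inbag = inbag,
              leaves = leaves, votes = votes,
              feature_ids = colnames(x),
              class_labels = levels(labels), labels = labels,
              subject_ids = rownames(x), seed = as.integer(seed),
              mtry = mtry, nodesize = nodesize)
  class(out) <- "forest_model"
  out
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("Random forest: %d trees, %d features, %d subjects\n",
              x$n_trees, length(x$feature_ids), length(x$subject_ids)))
  cat(sprintf("  classes: %s (negative) vs %s (positive); mtry = %d, seed = %d\n",
              x$class_labels[1], x$class_labels[2], x$mtry, x$seed))
  sc <- oob_scores(x)
  if (!anyNA(sc))
    cat(sprintf("  OOB AUC: %.3f\n", auc_roc(sc, x$labels)$auc))
  invisible(x)
}

#' Out-of-bag vote scores
#'
#' For each training subject, the fraction of trees in which the subject was
#' out of the bootstrap sample and the tree voted for the positive class.
#' Subjects that were in-bag in every tree cannot be scored and are returned
#' as `NA` with their ids in the `"undefined"` attribute (never silently
#' imputed).
#'
#' @param forest A `forest_model`.
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
oob_scores <- function(forest) {
  stopifnot(inherits(forest, "forest_model"))
  oob <- forest$inbag == 0L
  n_oob <- rowSums(oob)
  score <- rowSums(forest$votes & oob) / n_oob
  score[n_oob == 0L] <- NA_real_
  names(score) <- forest$subject_ids
  if (any(n_oob == 0L))
    attr(score, "undefined") <- forest$subject_ids[n_oob == 0L]
  score
}

#' Out-of-bag AUC of a fitted forest
#'
#' @param forest A `forest_model`.
#' @return The out-of-bag area under the ROC curve.
#' @export
oob_auc <- function(forest) {
  sc <- oob_scores(forest)
  if (!is.null(attr(sc, "undefined")))
    stop_("subjects never out-of-bag: %s",
          paste(attr(sc, "undefined"), collapse = ", "))
  auc_roc(sc, forest$labels)$auc
}

#' ROC curve and tie-aware AUC
#'
#' The AUC is computed by the Mann-Whitney pair-count identity,
#' (concordant + 0.5 * tied) / (n_pos * n_neg), which is exact under ties
#' and independent of any threshold grid. The stored curve uses the
#' empirical score set as thresholds.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (factor, second level = positive, or logical).
#' @return An object of class `roc_result` with `thresholds` (descending),
#'   `tpr`, `fpr` and `auc`.
#' @examples
#' auc_roc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc
#' @export
auc_roc <- function(scores, labels) {
  if (is.logical(labels)) pos <- labels
  else {
    if (!is.factor(labels)) labels <- factor(labels)
    labels <- droplevels(labels)
    if (nlevels(labels) != 2L) stop_("both classes must be present")
    pos <- labels == levels(labels)[2]
  }
  if (length(scores) != length(pos)) stop_("scores and labels differ in length")
  if (any(!is.finite(scores))) stop_("scores must be finite")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop_("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  out <- list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc)
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d thresholds\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Gini importance
#'
#' Mean over trees of the total decrease in Gini node impurity attributable
#' to splits on each feature. Features never used for a split score 0.
#'
#' @param forest A `forest_model`.
#' @return Named non-negative numeric vector, one entry per feature.
#' @export
gini_importance <- function(forest) {
  stopifnot(inherits(forest, "forest_model"))
  imp <- forest$rf$importance[, "MeanDecreaseGini"]
  names(imp) <- forest$feature_ids
  imp
}

#' Forest proximity matrix
#'
#' Co-occupancy frequency of terminal nodes: in `all_trees` mode,
#' `value(i, j)` is the fraction of all trees in which subjects i and j land
#' in the same terminal node (diagonal exactly 1). In `oob_pairs` mode both
#' numerator and denominator are restricted to trees in which both subjects
#' are out of bag; pairs with no qualifying tree are `NA`-flagged, and an
#' error is raised if any are flagged at `n_trees >= 1000`. The clustering
#' distance is `1 - proximity`.
#'
#' @param forest A `forest_model`.
#' @param subset Optional subject ids (or indices) to restrict the matrix to;
#'   the subtype pipeline passes cases only.
#' @param mode `"all_trees"` (classical definition, default) or
#'   `"oob_pairs"`.
#' @return An object of class `proximity_matrix` with `values`,
#'   `subject_ids`, `mode` and `n_trees`.
#' @export
rf_proximity <- function(forest, subset = NULL,
                         mode = c("all_trees", "oob_pairs")) {
  stopifnot(inherits(forest, "forest_model"))
  mode <- match.arg(mode)
  ids <- forest$subject_ids
  if (is.null(subset)) idx <- seq_along(ids)
  else if (is.character(subset)) {
    idx <- match(subset, ids)
    if (anyNA(idx))
      stop_("unknown subjects in subset: %s",
            paste(subset[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(subset)
  n <- length(idx)
  leaves <- forest$leaves[idx, , drop = FALSE]
  if (mode == "all_trees") {
    acc <- matrix(0, n, n)
    for (t in seq_len(forest$n_trees)) {
      v <- leaves[, t]
      acc <- acc + outer(v, v, "==")
    }
    values <- acc / forest$n_trees
  } else {
    oob <- forest$inbag[idx, , drop = FALSE] == 0L
    num <- matrix(0, n, n)
    den <- matrix(0, n, n)
    for (t in seq_len(forest$n_trees)) {
      o <- oob[, t]
      both <- outer(o, o, "&")
      v <- leaves[, t]
      num <- num + outer(v, v, "==") * both
      den <- den + both
    }
    values <- num / den
    values[den == 0] <- NA_real_
    if (anyNA(values) && forest$n_trees >= 1000L)
      stop_("pairs with no tree where both subjects are out-of-bag remain at n_trees = %d",
            forest$n_trees)
  }
  dimnames(values) <- list(ids[idx], ids[idx])
  out <- list(values = values, subject_ids = ids[idx], mode = mode,
              n_trees = forest$n_trees)
  class(out) <- "proximity_matrix"
  out
}

#' @export
print.proximity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("Proximity matrix (%s): %d subjects, %d trees; off-diagonal mean %.3f\n",
              x$mode, length(x$subject_ids), x$n_trees,
              mean(off, na.rm = TRUE)))
  invisible(x)
}

#' Distance view of a proximity matrix
#'
#' @param proximity A `proximity_matrix`.
#' @return A symmetric numeric matrix `1 - proximity` with zero diagonal.
#' @export
proximity_distance <- function(proximity) {
  stopifnot(inherits(proximity, "proximity_matrix"))
  d <- 1 - proximity$values
  diag(d) <- 0
  d
}

#' Score external subjects with a fitted forest
#'
#' Unseen subjects are pushed down every tree; the score is the fraction of
#' all trees voting for the positive class (no out-of-bag restriction, which
#' only applies to training subjects).
#'
#' @param forest A `forest_model`.
#' @param newdata Numeric matrix or data frame containing at least the
#'   training features (by name).
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
score_external <- function(forest, newdata) {
  stopifnot(inherits(forest, "forest_model"))
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) stop_("`newdata` is empty")
  missing <- setdiff(forest$feature_ids, colnames(newdata))
  if (length(missing))
    stop_("missing training features in newdata: %s",
          paste(missing, collapse = ", "))
  newdata <- newdata[, forest$feature_ids, drop = FALSE]
  pred <- stats::predict(forest$rf, newdata, predict.all = TRUE)
  score <- rowMeans(pred$individual == forest$class_labels[2])
  names(score) <- rownames(newdata)
  score
}
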