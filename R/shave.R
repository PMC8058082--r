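# Importance-based feature shaving: iteratively refit the forest, drop the
# least important fraction of features, track the out-of-bag AUC per round,
# and select the smallest feature set whose AUC is within a tolerance of the
# best round.

#' Recursive Gini-importance shaving
#'
#' Starting from the full feature set, each round fits a forest, records its
#' out-of-bag AUC, recomputes Gini importance, and removes the
#' `max(1, floor(drop_fraction * set size))` least important features; the
#' iteration stops once `min_features` remain (the final reduced set is also
#' fitted and recorded). The per-round seed is `seed + round - 1` so traces
#' are reproducible and individual rounds can be refit in isolation.
#'
#' @param x Numeric feature matrix (subjects x features, named columns).
#' @param labels Binary labels as in [fit_forest()].
#' @param n_trees Trees per round.
#' @param seed Base seed.
#' @param drop_fraction Fraction of the current set removed per round
#'   (at least one feature).
#' @param min_features Smallest feature-set size to reach.
#' @param auc_tolerance Tolerance used by [select_optimal()] when picking the
#'   selected round.
#' @return An object of class `shaving_trace`: `rounds` (each with
#'   `feature_ids`, `oob_auc`, `importance`), `selected_round`,
#'   `selected_features` and `selection_rule`.
#' @examples
#' x <- matrix(rnorm(60 * 10), 60, dimnames = list(NULL, paste0("f", 1:10)))
#' y <- factor(rep(c("a", "b"), each = 30))
#' x[y == "b", 1:2] <- x[y == "b", 1:2] + 2
#' tr <- shave(x, y, n_trees = 100, seed = 1, min_features = 2)
#' sapply(tr$rounds, function(r) length(r$feature_ids))
#' @export
shave <- function(x, labels, n_trees = 4000L, seed = 1L, drop_fraction = 0.1,
                  min_features = 5L, auc_tolerance = 0.005) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  check_scalar_number(drop_fraction, "drop_fraction", 0, 1)
  check_count(min_features, "min_features", min = 1L)
  if (min_features >= ncol(x))
    stop_("min_features (%d) must be below the initial feature count (%d)",
          min_features, ncol(x))
  feats <- colnames(x)
  rounds <- list()
  r <- 0L
  repeat {
    r <- r + 1L
    fit <- fit_forest(x[, feats, drop = FALSE], labels, n_trees = n_trees,
                      seed = seed + r - 1L)
    imp <- gini_importance(fit)
    rounds[[r]] <- list(feature_ids = feats, oob_auc = oob_auc(fit),
                        importance = imp)
    if (length(feats) <= min_features) break
    n_drop <- max(1L, floor(drop_fraction * length(feats)))
    keep <- max(min_features, length(feats) - n_drop)
    # drop lowest importance; ties broken by original feature order
    ord <- order(imp, seq_along(imp), decreasing = c(TRUE, FALSE),
                 method = "radix")
    feats <- feats[sort(ord[seq_len(keep)])]
  }
  trace <- structure(
    list(rounds = rounds,
         selection_rule = list(drop_fraction = drop_fraction,
                               min_features = as.integer(min_features),
                               auc_tolerance = auc_tolerance,
                               n_trees = as.integer(n_trees),
                               seed = as.integer(seed))),
    class = "shaving_trace")
  trace$selected_features <- select_optimal(trace, auc_tolerance)
  trace$selected_round <- attr(trace$selected_features, "round")
  attr(trace$selected_features, "round") <- NULL
  trace
}

#' Select the optimal shaving round
#'
#' Among rounds whose AUC is within `auc_tolerance` of the maximum, returns
#' the smallest feature set; ties on size are broken by higher AUC, then by
#' the later round.
#'
#' @param trace A `shaving_trace`.
#' @param auc_tolerance AUC tolerance relative to the best round.
#' @return Character vector of selected feature ids (attribute `"round"`
#'   carries the chosen round index).
#' @export
select_optimal <- function(trace, auc_tolerance = 0.005) {
  stopifnot(inherits(trace, "shaving_trace"))
  if (!length(trace$rounds)) stop_("empty shaving trace")
  aucs <- vapply(trace$rounds, `[[`, numeric(1), "oob_auc")
  sizes <- vapply(trace$rounds, function(r) length(r$feature_ids), integer(1))
  ok <- which(aucs >= max(aucs) - auc_tolerance)
  ord <- ok[order(sizes[ok], -aucs[ok], -ok)]
  sel <- ord[1]
  structure(trace$rounds[[sel]]$feature_ids, round = sel)
}

#' @export
print.shaving_trace <- function(x, ...) {
  sizes <- vapply(x$rounds, function(r) length(r$feature_ids), integer(1))
  aucs <- vapply(x$rounds, `[[`, numeric(1), "oob_auc")
  cat(sprintf("Shaving trace: %d rounds, %d -> %d features\n",
              length(sizes), sizes[1], sizes[length(sizes)]))
  cat(sprintf("  selected round %d: %d features, OOB AUC %.3f (tolerance %.3f)\n",
              x$selected_round, sizes[x$selected_round],
              aucs[x$selected_round], x$selection_rule$auc_tolerance))
  invisible(x)
}

#' @export
summary.shaving_trace <- function(object, ...) {
  data.frame(
    round = seq_along(object$rounds),
    n_features = vapply(object$rounds, function(r) length(r$feature_ids),
                        integer(1)),
    oob_auc = vapply(object$rounds, `[[`, numeric(1), "oob_auc"),
    selected = seq_along(object$rounds) == object$selected_round
  )
}
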