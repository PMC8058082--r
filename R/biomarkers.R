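# Biomarker validation of subtypes: per-feature-class classification of
# intergroup contrasts with shaving, direction-of-dysregulation tests at a
# Bonferroni-corrected threshold, and canonical correlation of marker
# panels.

severity_rank <- function(g) {
  # HC is least severe; subtypes rank by their number (S1 < S2 < ...)
  r <- integer(length(g))
  s <- grepl("^S[0-9]+$", g)
  r[s] <- as.integer(sub("^S", "", g[s]))
  r
}

#' Classify an intergroup contrast with one feature class
#'
#' Fits a random forest on the named feature class restricted to two groups,
#' shaves it by Gini importance, and reports the selected model's
#' out-of-bag AUC and ranked retained features. Class `"pooled"`
#' concatenates biomarkers and all auxiliary classes.
#'
#' @param cohort A `cohort_table`.
#' @param groups Named factor over discovery subjects from
#'   [analysis_groups()], or any named group vector; `"case"` may be used to
#'   pool all subtypes.
#' @param contrast Character pair `c(positive, negative)`, e.g.
#'   `c("S2", "HC")`.
#' @param feature_class Feature class name or `"pooled"`.
#' @param n_trees Trees per shaving round.
#' @param seed Base seed.
#' @param drop_fraction,min_features,auc_tolerance Passed to [shave()].
#' @return An object of class `classification_report` with `contrast`,
#'   `feature_class`, `auc`, `n_markers`, `markers` (retained, by decreasing
#'   importance) and the full `trace`.
#' @export
classify_contrast <- function(cohort, groups, contrast,
                              feature_class = "biomarker",
                              n_trees = 4000L, seed = 1L,
                              drop_fraction = 0.1, min_features = 5L,
                              auc_tolerance = 0.005) {
  stopifnot(inherits(cohort, "cohort_table"), length(contrast) == 2L)
  g <- as.character(groups)
  names(g) <- names(groups)
  if (any(contrast == "case")) g[g != "HC"] <- "case"
  for (side in contrast)
    if (!side %in% g) stop_("group '%s' is empty or unknown", side)
  feats <- features_of_class(cohort, feature_class)
  ids <- names(g)[g %in% contrast]
  x <- cohort$values[ids, feats, drop = FALSE]
  y <- factor(g[ids], levels = c(contrast[2], contrast[1]))
  trace <- shave(x, y, n_trees = n_trees, seed = seed,
                 drop_fraction = drop_fraction, min_features = min_features,
                 auc_tolerance = auc_tolerance)
  sel <- trace$rounds[[trace$selected_round]]
  imp <- sel$importance[sel$feature_ids]
  ranked <- sel$feature_ids[order(-imp, seq_along(imp), method = "radix")]
  out <- list(contrast = paste(contrast[1], "vs", contrast[2]),
              positive = contrast[1], negative = contrast[2],
              feature_class = feature_class,
              auc = sel$oob_auc, n_markers = length(ranked),
              markers = ranked, importance = imp[ranked], trace = trace,
              n_subjects = length(ids))
  class(out) <- "classification_report"
  out
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("%s on %s features: OOB AUC %.3f with %d retained markers\n",
              x$contrast, x$feature_class, x$auc, x$n_markers))
  top <- utils::head(x$markers, 5)
  cat("  top markers:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Direction-of-dysregulation tests for top markers
#'
#' Tests equality of marker means between the two groups of each contrast
#' (Welch t by default) for the top-k retained markers of each
#' classification report. The Bonferroni threshold is `alpha / m` with `m`
#' the number of (marker, contrast) tests actually performed. A marker is
#' flagged `"up"` or `"down"` in the more severe group only when it passes
#' the corrected threshold, otherwise `"ns"`; markers constant in both
#' groups are `"untestable"`.
#'
#' @param cohort A `cohort_table`.
#' @param groups Named group factor (see [analysis_groups()]).
#' @param reports List of `classification_report` objects.
#' @param top_k Markers tested per contrast (default 5).
#' @param alpha Family-wise level before correction (default 0.05).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A data frame with one row per (marker, contrast): `marker`,
#'   `contrast`, `rank`, `mean_severe`, `mean_other`, `p`, `direction`;
#'   attributes `"threshold"` and `"m"`.
#' @export
marker_direction_tests <- function(cohort, groups, reports, top_k = 5L,
                                   alpha = 0.05, variant = "welch") {
  stopifnot(inherits(cohort, "cohort_table"))
  g <- as.character(groups); names(g) <- names(groups)
  rows <- list()
  for (rep in reports) {
    stopifnot(inherits(rep, "classification_report"))
    markers <- utils::head(rep$markers, top_k)
    sev_pair <- c(rep$positive, rep$negative)
    gg <- g
    if (any(sev_pair == "case")) gg[!gg %in% "HC"] <- "case"
    severe <- sev_pair[which.max(severity_rank(ifelse(sev_pair == "case", "S1",
                                                      sev_pair)))]
    other <- setdiff(sev_pair, severe)
    for (i in seq_along(markers)) {
      va <- cohort$values[names(gg)[gg == severe], markers[i]]
      vb <- cohort$values[names(gg)[gg == other], markers[i]]
      if (stats::var(c(va, vb)) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          marker = markers[i], contrast = rep$contrast, rank = i,
          mean_severe = mean(va), mean_other = mean(vb), p = NA_real_,
          direction = "untestable", stringsAsFactors = FALSE)
        next
      }
      tt <- t_test_from_summary(mean(va), max(stats::sd(va), 1e-12),
                                length(va),
                                mean(vb), max(stats::sd(vb), 1e-12),
                                length(vb), variant = variant)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = markers[i], contrast = rep$contrast, rank = i,
        mean_severe = mean(va), mean_other = mean(vb), p = tt$p,
        direction = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  threshold <- alpha / m
  sig <- !is.na(out$p) & out$p < threshold
  out$direction[is.na(out$direction)] <-
    ifelse(sig[is.na(out$direction)],
           ifelse(out$mean_severe[is.na(out$direction)] >
                    out$mean_other[is.na(out$direction)], "up", "down"),
           "ns")
  attr(out, "threshold") <- threshold
  attr(out, "m") <- m
  out
}

#' Canonical correlation analysis
#'
#' Computes canonical correlations between two variable sets by column
#' standardization, whitening of each set through its singular value
#' decomposition (rank-deficient sets are handled by truncating below a
#' relative tolerance), and an SVD of the cross-product of the whitened
#' scores -- a numerically stable route whose singular values are the
#' canonical correlations.
#'
#' @param x,y Numeric matrices with the same number of rows.
#' @param n_components Number of canonical pairs to return; defaults to
#'   `min(rank(x), rank(y))`.
#' @return An object of class `cca_result` with `cor` (non-increasing, in
#'   `[0, 1]`), `xcoef`, `ycoef` (weights for centered, unit-variance
#'   variables), `xscores`, `yscores`, and the effective `rank_x`, `rank_y`.
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' cca(x, x %*% matrix(c(1, 2, 0, 1, 1, 1, 0, 0, 3), 3))$cor
#' @export
cca <- function(x, y, n_components = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop_("x and y must have the same number of rows")
  if (nrow(x) < 3L) stop_("need at least 3 observations")
  for (nm in c("x", "y")) {
    m <- get(nm)
    if (is.null(colnames(m)))
      colnames(m) <- sprintf("%s%02d", nm, seq_len(ncol(m)))
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0))
      stop_("zero-variance column in %s: %s", nm,
            paste(colnames(m)[sds == 0], collapse = ", "))
    assign(nm, scale(m))
  }
  whiten <- function(m) {
    sv <- svd(m)
    keep <- sv$d > max(sv$d) * 1e-8
    list(q = sv$u[, keep, drop = FALSE],
         back = sv$v[, keep, drop = FALSE] %*%
           diag(1 / sv$d[keep], sum(keep)),
         rank = sum(keep))
  }
  wx <- whiten(x); wy <- whiten(y)
  sv <- svd(crossprod(wx$q, wy$q))
  k <- min(wx$rank, wy$rank)
  if (!is.null(n_components)) k <- min(k, n_components)
  cors <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  xcoef <- wx$back %*% sv$u[, seq_len(k), drop = FALSE]
  ycoef <- wy$back %*% sv$v[, seq_len(k), drop = FALSE]
  rownames(xcoef) <- colnames(x); rownames(ycoef) <- colnames(y)
  out <- list(cor = cors, xcoef = xcoef, ycoef = ycoef,
              xscores = x %*% xcoef, yscores = y %*% ycoef,
              rank_x = wx$rank, rank_y = wy$rank)
  class(out) <- "cca_result"
  out
}

#' @export
print.cca_result <- function(x, ...) {
  k <- min(3L, length(x$cor))
  cat(sprintf("CCA: %d canonical pairs (ranks %d, %d); first %d correlations: %s\n",
              length(x$cor), x$rank_x, x$rank_y, k,
              paste(sprintf("%.3f", x$cor[seq_len(k)]), collapse = ", ")))
  invisible(x)
}

#' Canonical correlation of two marker panels
#'
#' Removes the intersection of the two panels and runs [cca()] on the
#' remaining (non-overlapping) members, reporting the leading correlations.
#'
#' @param cohort A `cohort_table`.
#' @param panel_a,panel_b Character vectors of feature ids.
#' @param subjects Optional subject ids (defaults to all subjects).
#' @param n_components Canonical pairs to return (default 3).
#' @return A `cca_result` with attribute `"panels"` recording the
#'   non-overlapping members used.
#' @export
compare_marker_panels <- function(cohort, panel_a, panel_b, subjects = NULL,
                                  n_components = 3L) {
  stopifnot(inherits(cohort, "cohort_table"))
  unknown <- setdiff(c(panel_a, panel_b), colnames(cohort$values))
  if (length(unknown))
    stop_("unknown panel features: %s", paste(unknown, collapse = ", "))
  shared <- intersect(panel_a, panel_b)
  a <- setdiff(panel_a, shared); b <- setdiff(panel_b, shared)
  if (!length(a) || !length(b))
    stop_("no non-overlapping members remain in panel %s",
          if (!length(a)) "A" else "B")
  if (is.null(subjects)) subjects <- cohort$subject_ids
  res <- cca(cohort$values[subjects, a, drop = FALSE],
             cohort$values[subjects, b, drop = FALSE],
             n_components = n_components)
  attr(res, "panels") <- list(a = a, b = b, overlap = shared)
  res
}
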