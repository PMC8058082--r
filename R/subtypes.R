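# Subtype discovery: case-vs-control forest on clinical items, case-only
# proximity distance, PAM, severity naming, silhouette and embedding
# diagnostics.

#' Discover clinical severity subtypes
#'
#' Fits a case-vs-control random forest on the individual clinical items of
#' the discovery sample, extracts the proximity matrix restricted to cases,
#' clusters the cases with PAM on the distance `1 - proximity`, and names
#' the clusters in order of their mean severity-scale total (`S1` = least
#' severe). Silhouette widths are computed over all discovery subjects
#' (controls as their own group) on the full-cohort distance from the same
#' forest, together with a 2-D embedding for visualization.
#'
#' @param cohort A `cohort_table` (see [generate_cohort()] / [read_cohort()]).
#' @param n_trees Trees for the clustering forest (default 4000).
#' @param seed Integer seed.
#' @param k Number of clusters (default 2).
#' @param proximity_mode Passed to [rf_proximity()].
#' @param embed_method Passed to [embed_2d()].
#' @param severity_feature Feature id of the severity-scale total used to
#'   name clusters; defaults to the total of the cohort's first clinical
#'   scale.
#' @return An object of class `subtype_fit` with the per-case `labels`
#'   (`"S1"`, `"S2"`, ...), `medoids`, `total_cost`, `silhouettes` (per
#'   subject and per group including controls), `embedding`, `severity_order`
#'   (cluster id -> name), the case-only `proximity` and the underlying
#'   `forest`.
#' @examples
#' \donttest{
#' tab <- generate_cohort(cohort_config(seed = 1))
#' fit <- discover_subtypes(tab, n_trees = 300, seed = 1)
#' table(fit$labels)
#' }
#' @export
discover_subtypes <- function(cohort, n_trees = 4000L, seed = 1L, k = 2L,
                              proximity_mode = "all_trees",
                              embed_method = "diffusion_map",
                              severity_feature = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  check_count(k, "k", min = 1L)
  disc <- cohort$role == "discovery"
  items <- features_of_class(cohort, "clinical_item")
  x <- cohort$values[disc, items, drop = FALSE]
  grp <- factor(cohort$group[disc], levels = c("hc", "case"))
  case_ids <- cohort$subject_ids[disc][grp == "case"]
  if (length(case_ids) < 2L * k)
    stop_("need at least %d cases for k = %d, have %d", 2L * k, k,
          length(case_ids))
  if (is.null(severity_feature)) {
    summaries <- cohort$feature_meta[cohort$feature_meta$class ==
                                       "clinical_summary", ]
    sev_scale <- cohort$feature_meta$scale_id[
      cohort$feature_meta$class == "clinical_item"][1]
    severity_feature <- summaries$feature_id[summaries$scale_id == sev_scale][1]
  }
  if (!severity_feature %in% colnames(cohort$values))
    stop_("severity feature '%s' not found", severity_feature)

  forest <- fit_forest(x, grp, n_trees = n_trees, seed = seed)
  prox_cases <- rf_proximity(forest, subset = case_ids, mode = proximity_mode)
  d_cases <- proximity_distance(prox_cases)
  pam <- pam_cluster(d_cases, k)

  # severity naming: cluster with the lowest mean severity total becomes S1
  sev <- cohort$values[disc, severity_feature][grp == "case"]
  cluster_sev <- vapply(seq_len(k), function(cl)
    mean(sev[pam$labels == cl]), numeric(1))
  severity_order <- sprintf("S%d", rank(cluster_sev, ties.method = "first"))
  names(severity_order) <- as.character(seq_len(k))
  labels <- severity_order[as.character(pam$labels)]
  names(labels) <- case_ids

  # diagnostics over all discovery subjects, controls as their own group
  prox_full <- rf_proximity(forest, mode = proximity_mode)
  d_full <- proximity_distance(prox_full)
  groups3 <- ifelse(grp == "hc", "HC", labels[cohort$subject_ids[disc]])
  sil <- silhouette_scores(d_full, groups3)
  embedding <- embed_2d(d_full, method = embed_method)

  out <- list(labels = labels, medoids = pam$medoids,
              total_cost = pam$total_cost, k = as.integer(k),
              pam = pam, severity_order = severity_order,
              cluster_severity_means = stats::setNames(cluster_sev,
                                                       severity_order),
              silhouettes = sil$scores,
              cluster_mean_silhouettes = sil$cluster_means,
              embedding = embedding, groups = groups3,
              proximity = prox_cases, forest = forest,
              severity_feature = severity_feature, seed = as.integer(seed))
  class(out) <- "subtype_fit"
  out
}

#' @export
print.subtype_fit <- function(x, ...) {
  cat(sprintf("Subtype fit: k = %d on %d cases (PAM on 1 - forest proximity)\n",
              x$k, length(x$labels)))
  tab <- table(x$labels)
  for (nm in names(tab))
    cat(sprintf("  %s: %d cases, mean %s = %.1f, mean silhouette %.2f\n",
                nm, tab[[nm]], x$severity_feature,
                x$cluster_severity_means[[nm]],
                x$cluster_mean_silhouettes[[nm]]))
  cat(sprintf("  HC mean silhouette: %.2f\n",
              x$cluster_mean_silhouettes[["HC"]]))
  invisible(x)
}

#' @export
summary.subtype_fit <- function(object, ...) {
  tab <- table(object$labels)
  data.frame(subtype = names(tab), n = as.integer(tab),
             mean_severity = object$cluster_severity_means[names(tab)],
             mean_silhouette = object$cluster_mean_silhouettes[names(tab)],
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.subtype_fit <- function(x, ...) {
  grp <- factor(x$groups, levels = c("HC", sort(unique(x$labels))))
  cols <- c("grey50", grDevices::hcl.colors(nlevels(grp) - 1L, "Dark 2"))
  graphics::plot(x$embedding, col = cols[as.integer(grp)],
                 pch = ifelse(grp == "HC", 1, 19),
                 xlab = "dimension 1", ylab = "dimension 2",
                 main = "Forest-distance embedding", ...)
  graphics::legend("topright", legend = levels(grp),
                   col = cols, pch = c(1, rep(19, nlevels(grp) - 1L)),
                   bty = "n")
  invisible(x)
}

#' Group labels for downstream contrasts
#'
#' Combines a cohort's case/control status with fitted subtype labels into
#' one factor over the discovery subjects (`HC`, `S1`, `S2`, ...).
#'
#' @param cohort A `cohort_table`.
#' @param subtypes A `subtype_fit` from [discover_subtypes()].
#' @return Named factor over discovery subjects.
#' @export
analysis_groups <- function(cohort, subtypes) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(subtypes, "subtype_fit"))
  disc <- cohort$subject_ids[cohort$role == "discovery"]
  g <- ifelse(cohort$group[match(disc, cohort$subject_ids)] == "hc", "HC",
              subtypes$labels[disc])
  if (anyNA(g)) stop_("subtype labels missing for some discovery cases")
  factor(stats::setNames(g, disc),
         levels = c("HC", sort(unique(subtypes$labels))))
}
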