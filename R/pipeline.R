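# End-to-end orchestration: simulate (or read) a cohort, discover subtypes,
# score the clustering forest on the validation sample, profile the
# subtypes, classify every contrast x feature class, test marker
# directions, compare marker panels, and write a deterministic run
# directory with a manifest of checksums.

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] with the pipeline defaults:
#' 4000 trees, two clusters, shaving drop fraction 0.1 with AUC tolerance
#' 0.005, family-wise threshold 1e-4 for the clinical tables, marker alpha
#' 0.05 Bonferroni-corrected over the top-5 markers of the four contrasts,
#' and all-trees proximity. Per-stage seeds are derived from the global
#' seed by fixed offsets so stages can be rerun in isolation.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory for run artifacts.
#' @param cohort_config A [cohort_config()] for simulation, or `NULL` to
#'   read an existing cohort from `cohort_prefix`.
#' @param cohort_prefix Path prefix of a written cohort (used when
#'   `cohort_config` is `NULL`).
#' @param n_trees,k,proximity_mode Passed to [discover_subtypes()].
#' @param drop_fraction,auc_tolerance,min_features Passed to [shave()].
#' @param alpha_family Family-wise threshold for [profile_subtypes()].
#' @param alpha_marker Pre-correction level for [marker_direction_tests()].
#' @param top_k Markers tested per contrast.
#' @param contrasts List of group pairs to classify.
#' @param classes Feature classes to classify per contrast.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("pamforest_run_"),
                            cohort_config = NULL, cohort_prefix = NULL,
                            n_trees = 4000L, k = 2L,
                            proximity_mode = "all_trees",
                            drop_fraction = 0.1, auc_tolerance = 0.005,
                            min_features = 5L,
                            alpha_family = 1e-4, alpha_marker = 0.05,
                            top_k = 5L,
                            contrasts = list(c("S2", "S1"), c("S1", "HC"),
                                             c("S2", "HC"), c("case", "HC")),
                            classes = c("biomarker", "comorbidity",
                                        "neurocognitive", "demographic",
                                        "psychiatric_history",
                                        "premilitary_trauma", "pooled")) {
  if (is.null(cohort_config) && is.null(cohort_prefix))
    cohort_config <- pamforest::cohort_config(seed = seed)
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              cohort_config = cohort_config, cohort_prefix = cohort_prefix,
              n_trees = as.integer(n_trees), k = as.integer(k),
              proximity_mode = proximity_mode,
              drop_fraction = drop_fraction, auc_tolerance = auc_tolerance,
              min_features = as.integer(min_features),
              alpha_family = alpha_family, alpha_marker = alpha_marker,
              top_k = as.integer(top_k), contrasts = contrasts,
              classes = classes)
  class(cfg) <- "pipeline_config"
  cfg
}

write_num_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_full)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full subtype-discovery pipeline
#'
#' Executes simulate (or read) -> subtype discovery -> external validation
#' scoring -> clinical profiling -> contrast x feature-class classification
#' -> marker direction tests -> marker-panel canonical correlation, and
#' writes all artifacts plus a manifest (configuration, seeds, checksums)
#' and a human-readable summary to the output directory. Outputs contain no
#' timestamps, so a rerun with the same configuration is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted objects and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # stage seeds derived from the global seed by fixed offsets
  seeds <- list(simulate = config$seed, subtype = config$seed + 1L,
                classify = config$seed + 100L)

  cohort <- stage("simulate", {
    if (!is.null(config$cohort_config)) {
      cc <- config$cohort_config
      cc$seed <- seeds$simulate
      tab <- generate_cohort(cc)
      write_cohort(tab, od("cohort"))
      tab
    } else read_cohort(config$cohort_prefix)
  })

  subtypes <- stage("subtype", discover_subtypes(
    cohort, n_trees = config$n_trees, seed = seeds$subtype, k = config$k,
    proximity_mode = config$proximity_mode))
  groups <- analysis_groups(cohort, subtypes)

  external <- stage("external_scoring", {
    val <- cohort$role == "validation"
    items <- features_of_class(cohort, "clinical_item")
    sc <- score_external(subtypes$forest,
                         cohort$values[val, items, drop = FALSE])
    roc <- auc_roc(sc, factor(cohort$group[val], levels = c("hc", "case")))
    list(scores = sc, auc = roc$auc)
  })

  profile <- stage("profile", profile_subtypes(cohort, subtypes,
                                               alpha = config$alpha_family))

  reports <- stage("classify", {
    out <- list()
    for (ci in seq_along(config$contrasts)) {
      for (li in seq_along(config$classes)) {
        rep <- classify_contrast(
          cohort, groups, config$contrasts[[ci]], config$classes[[li]],
          n_trees = config$n_trees,
          seed = seeds$classify + 10L * ci + li,
          drop_fraction = config$drop_fraction,
          min_features = config$min_features,
          auc_tolerance = config$auc_tolerance)
        out[[paste(rep$contrast, rep$feature_class, sep = " | ")]] <- rep
      }
    }
    out
  })

  biomarker_reports <- Filter(function(r) r$feature_class == "biomarker",
                              reports)
  directions <- stage("marker_directions", marker_direction_tests(
    cohort, groups, biomarker_reports, top_k = config$top_k,
    alpha = config$alpha_marker))

  panel_cca <- stage("panel_cca", {
    sel <- function(contrast) {
      r <- biomarker_reports[[paste(contrast, "biomarker", sep = " | ")]]
      if (is.null(r)) NULL else r$markers
    }
    pa <- sel("case vs HC"); pb <- sel("S2 vs HC")
    if (is.null(pa) || is.null(pb) ||
        !length(setdiff(pa, pb)) || !length(setdiff(pb, pa))) NULL
    else compare_marker_panels(cohort, pa, pb,
                               subjects = names(groups))
  })

  # ---- artifacts ----
  stage("write", {
    write_num_csv(data.frame(
      subject_id = names(subtypes$labels), cluster = subtypes$pam$labels,
      subtype = unname(subtypes$labels),
      silhouette = unname(subtypes$silhouettes[names(subtypes$labels)])),
      od("subtypes.csv"))
    write_num_csv(data.frame(
      subject_id = rownames(subtypes$embedding), group = subtypes$groups,
      dim1 = subtypes$embedding[, 1], dim2 = subtypes$embedding[, 2]),
      od("embedding.csv"))
    write_num_csv(data.frame(
      group = names(subtypes$cluster_mean_silhouettes),
      mean_silhouette = unname(subtypes$cluster_mean_silhouettes)),
      od("silhouettes.csv"))
    write_num_csv(profile$summary_table, od("profile_summary.csv"))
    if (!is.null(profile$characteristics_table))
      write_num_csv(profile$characteristics_table, od("characteristics.csv"))
    write_num_csv(data.frame(
      variable = rownames(profile$pca$loadings),
      pc1_loading = profile$pca$loadings[, 1],
      row.names = NULL), od("pca_loadings.csv"))
    auc_tab <- do.call(rbind, lapply(reports, function(r) data.frame(
      contrast = r$contrast, feature_class = r$feature_class, auc = r$auc,
      n_markers = r$n_markers, stringsAsFactors = FALSE)))
    rownames(auc_tab) <- NULL
    write_num_csv(auc_tab, od("auc_matrix.csv"))
    write_num_csv(directions, od("marker_directions.csv"))
    shav <- do.call(rbind, lapply(names(reports), function(nm) {
      s <- summary(reports[[nm]]$trace)
      cbind(model = nm, s)
    }))
    write_num_csv(shav, od("shaving_traces.csv"))
    ext <- data.frame(subject_id = names(external$scores),
                      score = unname(external$scores))
    write_num_csv(ext, od("external_scores.csv"))
    json <- list(
      external_validation_auc = external$auc,
      pc1_variance_fraction = profile$pca$var_fractions[1],
      pc1_ratio = profile$pc1_ratio,
      subtype_sizes = as.list(table(subtypes$labels)),
      cluster_mean_silhouettes = as.list(subtypes$cluster_mean_silhouettes),
      marker_threshold = attr(directions, "threshold"),
      panel_cca = if (is.null(panel_cca)) NULL else panel_cca$cor)
    jsonlite::write_json(json, od("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    TRUE
  })

  # manifest with configuration and artifact checksums
  stage("manifest", {
    files <- sort(setdiff(list.files(config$out_dir),
                          c("manifest.json", "report.md")))
    sums <- as.list(tools::md5sum(file.path(config$out_dir, files)))
    names(sums) <- files
    cfg_ser <- config
    cfg_ser$cohort_config <- unclass(cfg_ser$cohort_config)
    manifest <- list(package = "pamforest",
                     version = as.character(utils::packageVersion("pamforest")),
                     config = unclass(cfg_ser), stage_seeds = seeds,
                     checksums = sums)
    jsonlite::write_json(manifest, od("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    TRUE
  })

  invisible(list(out_dir = config$out_dir, cohort = cohort,
                 subtypes = subtypes, profile = profile, reports = reports,
                 directions = directions, external = external,
                 panel_cca = panel_cca))
}

#' Render a human-readable report from a completed run directory
#'
#' Assembles `report.md` from the stored artifacts without recomputation,
#' after verifying every artifact against the manifest checksums.
#' Re-rendering an unchanged run changes no bytes.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Invisibly, the report path.
#' @export
render_report <- function(run_dir) {
  manifest_file <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_file)) stop_("missing artifact 'manifest.json'")
  manifest <- jsonlite::read_json(manifest_file)
  missing <- names(manifest$checksums)[
    !file.exists(file.path(run_dir, names(manifest$checksums)))]
  if (length(missing))
    stop_("missing artifact '%s'", missing[1])
  sums <- tools::md5sum(file.path(run_dir, names(manifest$checksums)))
  bad <- names(manifest$checksums)[sums != unlist(manifest$checksums)]
  if (length(bad))
    stop_("artifact '%s' does not match its manifest checksum", bad[1])

  summ <- jsonlite::read_json(file.path(run_dir, "summary.json"))
  sil <- utils::read.csv(file.path(run_dir, "silhouettes.csv"))
  auc <- utils::read.csv(file.path(run_dir, "auc_matrix.csv"))
  dirs <- utils::read.csv(file.path(run_dir, "marker_directions.csv"))
  lines <- c(
    "# Subtype discovery run report", "",
    sprintf("Seed: %s; trees: %s; clusters: %s.",
            manifest$config$seed, manifest$config$n_trees,
            manifest$config$k), "",
    "## Subtypes",
    sprintf("- sizes: %s",
            paste(sprintf("%s = %s", names(summ$subtype_sizes),
                          unlist(summ$subtype_sizes)), collapse = ", ")),
    sprintf("- group mean silhouettes: %s",
            paste(sprintf("%s = %.2f", sil$group, sil$mean_silhouette),
                  collapse = ", ")),
    sprintf("- external validation AUC of the clustering forest: %.3f",
            as.numeric(summ$external_validation_auc)),
    sprintf("- PC1 variance fraction: %.2f; PC1 severe/mild mean ratio: %.2f",
            as.numeric(summ$pc1_variance_fraction),
            as.numeric(summ$pc1_ratio)), "",
    "## Classification AUC by contrast and feature class", "",
    "| contrast | feature class | OOB AUC | markers |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %.3f | %d |", auc$contrast, auc$feature_class,
            auc$auc, auc$n_markers), "",
    "## Marker direction calls",
    sprintf("(Bonferroni threshold %.5g)",
            as.numeric(summ$marker_threshold)), "",
    "| marker | contrast | rank | p | direction |", "|---|---|---|---|---|",
    sprintf("| %s | %s | %d | %.3g | %s |", dirs$marker, dirs$contrast,
            dirs$rank, dirs$p, dirs$direction), "")
  if (!is.null(summ$panel_cca))
    lines <- c(lines, "## Marker panel canonical correlations",
               paste(sprintf("%.3f", unlist(summ$panel_cca)),
                     collapse = ", "), "")
  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
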