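# Synthetic cohort generator.
#
# Subjects carry three latent traits:
#   z  - symptom severity, graded HC < S1 < ... < S_K (drives every scale);
#   v  - general distress, elevated in all cases (case-generic items);
#   u  - severe-symptom profile, elevated only in the most severe subtype
#        (severe-specific items such as dissociation or phobic avoidance
#        that healthy controls and milder cases rarely endorse).
# Ordinal items follow a graded-response style model:
#   item = round(range * pnorm(l*(z - c) + g*(u - cu) + h*(v - cv) + e)),
# with item loadings, difficulties, and noise fixed per instrument (the item
# bank is drawn once from an internal constant so every cohort answers the
# same questionnaires). Biomarkers and auxiliary feature classes are Gaussian
# with equicorrelated residuals per block and planted standardized mean
# shifts on a minority of features.

.BANK_SEED <- 22L

# severity weights used for marker / auxiliary shifts per group:
# HC = 0, planted subtypes graded up to 1 for the most severe.
.marker_weights <- function(k) {
  if (k == 1L) return(1)
  c(seq(0.6, 1, length.out = k))
}

.aux_classes <- c(
  comorbidity = 10L, neurocognitive = 15L, demographic = 5L,
  psychiatric_history = 8L, premilitary_trauma = 6L
)

#' Configuration for the synthetic cohort generator
#'
#' Returns a validated configuration object for [generate_cohort()]. The
#' defaults emulate the scale of a two-site case-control study: a discovery
#' sample of 74 cases and 71 healthy controls, a validation sample of 26
#' cases and 36 controls, 16 clinical instruments (one 17-item severity scale
#' scored 0-8 per item, fifteen 10-item scales scored 0-4), 342 multi-omic
#' biomarkers in seven subclasses, and five weaker auxiliary feature classes.
#' Two case subtypes are planted in proportions 0.35/0.65; their latent
#' severity means are calibrated so that the simulated severity-scale totals
#' average near 3.4 (HC), 54 (S1) and 76 (S2).
#'
#' @param n_hc_discovery,n_case_discovery,n_hc_validation,n_case_validation
#'   Subject counts per group and sample role.
#' @param subtype_proportions Fractions of cases per planted subtype, in
#'   increasing order of severity; must sum to 1.
#' @param severity_means Latent severity means, one for healthy controls
#'   followed by one per subtype, strictly increasing.
#' @param severity_sd Within-group latent severity standard deviation.
#' @param n_clinical_scales Number of clinical instruments; the first is the
#'   severity scale.
#' @param items_per_scale Integer vector of items per scale, length
#'   `n_clinical_scales`.
#' @param item_loading_range Range of item loadings on severity; severity
#'   scale items draw from the upper half, other items from the lower half.
#' @param item_noise_sd Latent-scale noise standard deviation of ordinary
#'   items. Severe-specific profile items use a third of it and distress
#'   items half of it (severe symptoms are reported more reliably).
#' @param profile_shift,profile_sd Mean shift (most severe subtype only) and
#'   sd of the severe-symptom profile trait.
#' @param distress_shift,distress_sd Mean shift (all cases) and sd of the
#'   general distress trait.
#' @param n_biomarkers_per_class Named integer vector of biomarkers per
#'   subclass (defaults total 342).
#' @param n_informative_markers Number of biomarkers carrying planted
#'   group-dependent mean shifts.
#' @param marker_effect_size Standardized mean difference (Cohen's d) of an
#'   informative marker between the most severe subtype and controls.
#' @param marker_up_fraction Fraction of informative markers up-regulated in
#'   the severe direction (at least one, a lactate-like metabolite); the
#'   rest are down-regulated.
#' @param block_correlation Equicorrelation of residuals within a biomarker
#'   subclass or auxiliary class, in `[0, 1)`.
#' @param aux_class_effect_sizes Named effect sizes for the five auxiliary
#'   classes (comorbidity, neurocognitive, demographic, psychiatric_history,
#'   premilitary_trauma).
#' @param seed Integer seed for subject-level randomness.
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(seed = 7)
#' cfg$n_case_discovery
#' @export
cohort_config <- function(n_hc_discovery = 71L,
                          n_case_discovery = 74L,
                          n_hc_validation = 36L,
                          n_case_validation = 26L,
                          subtype_proportions = c(0.35, 0.65),
                          severity_means = c(0, 5.83, 7.30),
                          severity_sd = 0.3,
                          n_clinical_scales = 16L,
                          items_per_scale = c(17L, rep(10L, 15L)),
                          item_loading_range = c(0.25, 0.9),
                          item_noise_sd = 2.1,
                          profile_shift = 3.2,
                          profile_sd = 0.1,
                          distress_shift = 1.5,
                          distress_sd = 0.25,
                          n_biomarkers_per_class = c(
                            methylation = 120L, mirna = 60L, metabolite = 60L,
                            protein = 50L, endocrine = 25L, clinlab = 15L,
                            physio = 12L
                          ),
                          n_informative_markers = 20L,
                          marker_effect_size = 0.8,
                          marker_up_fraction = 0.1,
                          block_correlation = 0.2,
                          aux_class_effect_sizes = c(
                            comorbidity = 0.5, neurocognitive = 0.6,
                            demographic = 0, psychiatric_history = 0.7,
                            premilitary_trauma = 0.3
                          ),
                          seed = 1L) {
  for (nm in c("n_hc_discovery", "n_case_discovery", "n_hc_validation",
               "n_case_validation"))
    check_count(get(nm), nm)
  if (!is.numeric(subtype_proportions) || length(subtype_proportions) < 1L ||
      any(subtype_proportions < 0))
    stop_("`subtype_proportions` must be non-negative fractions")
  if (abs(sum(subtype_proportions) - 1) > 1e-9)
    stop_("`subtype_proportions` must sum to 1 (got %.12f)",
          sum(subtype_proportions))
  k <- length(subtype_proportions)
  if (length(severity_means) != k + 1L)
    stop_("`severity_means` must have length %d (HC plus one per subtype)",
          k + 1L)
  if (any(diff(severity_means) <= 0))
    stop_("`severity_means` must be strictly increasing (HC < S1 < ...)")
  check_scalar_number(severity_sd, "severity_sd", lower = 1e-12)
  check_count(n_clinical_scales, "n_clinical_scales", min = 1L)
  if (length(items_per_scale) != n_clinical_scales)
    stop_("`items_per_scale` must have length `n_clinical_scales`")
  if (any(items_per_scale < 1L)) stop_("`items_per_scale` entries must be >= 1")
  if (length(item_loading_range) != 2L || item_loading_range[1] <= 0 ||
      diff(item_loading_range) <= 0)
    stop_("`item_loading_range` must be an increasing positive interval")
  check_scalar_number(item_noise_sd, "item_noise_sd", lower = 1e-12)
  check_scalar_number(marker_effect_size, "marker_effect_size", lower = 0)
  check_scalar_number(marker_up_fraction, "marker_up_fraction", 0, 1)
  check_scalar_number(block_correlation, "block_correlation", 0, 1 - 1e-12)
  check_count(n_informative_markers, "n_informative_markers")
  if (n_informative_markers > sum(n_biomarkers_per_class))
    stop_("more informative markers requested than markers available")
  if (is.null(names(n_biomarkers_per_class)) ||
      any(!nzchar(names(n_biomarkers_per_class))))
    stop_("`n_biomarkers_per_class` must be a named vector")
  missing_aux <- setdiff(names(.aux_classes), names(aux_class_effect_sizes))
  if (length(missing_aux))
    stop_("`aux_class_effect_sizes` missing classes: %s",
          paste(missing_aux, collapse = ", "))
  cfg <- list(
    n_hc_discovery = as.integer(n_hc_discovery),
    n_case_discovery = as.integer(n_case_discovery),
    n_hc_validation = as.integer(n_hc_validation),
    n_case_validation = as.integer(n_case_validation),
    subtype_proportions = subtype_proportions,
    severity_means = unname(severity_means),
    severity_sd = severity_sd,
    n_clinical_scales = as.integer(n_clinical_scales),
    items_per_scale = as.integer(items_per_scale),
    item_loading_range = item_loading_range,
    item_noise_sd = item_noise_sd,
    profile_shift = profile_shift,
    profile_sd = profile_sd,
    distress_shift = distress_shift,
    distress_sd = distress_sd,
    n_biomarkers_per_class = n_biomarkers_per_class,
    n_informative_markers = as.integer(n_informative_markers),
    marker_effect_size = marker_effect_size,
    marker_up_fraction = marker_up_fraction,
    block_correlation = block_correlation,
    aux_class_effect_sizes = aux_class_effect_sizes,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

# planted subtype sizes by largest-remainder apportionment
subtype_sizes <- function(n_cases, proportions) {
  raw <- proportions * n_cases
  sizes <- floor(raw)
  rem <- n_cases - sum(sizes)
  if (rem > 0) {
    frac_order <- order(raw - sizes, decreasing = TRUE)
    sizes[frac_order[seq_len(rem)]] <- sizes[frac_order[seq_len(rem)]] + 1L
  }
  if (any(sizes == 0L & proportions > 0))
    stop_(paste("subtype proportions incompatible with %d cases:",
                "rounding leaves an empty planted subtype"), n_cases)
  as.integer(sizes)
}

# Fixed item bank: instrument parameters shared by every generated cohort
# with the same configuration. Item types for the non-severity scales are
# u (severe-specific profile), v (case-generic distress), z (weak severity),
# in proportions 40/30/30 shuffled across items.
item_bank <- function(config) {
  with_seed(.BANK_SEED, {
    n_sev <- config$items_per_scale[1]
    n_other <- sum(config$items_per_scale[-1])
    p <- n_sev + n_other
    lr <- config$item_loading_range
    mid <- mean(lr)
    type <- c(rep("sev", n_sev),
              sample(rep(c("u", "v", "z"),
                         c(round(0.4 * n_other), round(0.3 * n_other),
                           n_other - round(0.4 * n_other) - round(0.3 * n_other)))))
    l <- ifelse(type == "sev", stats::runif(p, mid, lr[2]),
         ifelse(type == "z", stats::runif(p, lr[1], mid), 0))
    cz <- ifelse(type == "sev", stats::runif(p, 4.5, 9.5), stats::runif(p, 2, 9))
    g <- ifelse(type == "u", stats::runif(p, 1.5, 2.2), 0)
    cu <- stats::runif(p, 1.2, 2.4)
    h <- ifelse(type == "v", stats::runif(p, 0.8, 1.2), 0)
    cv <- stats::runif(p, 0.5, 2.0)
    noise <- ifelse(type == "u", config$item_noise_sd / 3,
             ifelse(type == "v", config$item_noise_sd / 2.1,
                    config$item_noise_sd))
    scale_id <- rep(sprintf("SC%02d", seq_len(config$n_clinical_scales)),
                    config$items_per_scale)
    scale_id[seq_len(n_sev)] <- "CAPS"
    ranges <- rep(c(8L, 4L), c(n_sev, n_other))
    item_id <- unlist(lapply(seq_len(config$n_clinical_scales), function(s) {
      id <- if (s == 1L) "CAPS" else sprintf("SC%02d", s)
      sprintf("%s_i%02d", id, seq_len(config$items_per_scale[s]))
    }))

    # biomarker bank: identities of informative markers and their directions
    n_mark <- sum(config$n_biomarkers_per_class)
    subclass <- rep(names(config$n_biomarkers_per_class),
                    config$n_biomarkers_per_class)
    marker_id <- unlist(lapply(names(config$n_biomarkers_per_class), function(k)
      sprintf("%s_%03d", k, seq_len(config$n_biomarkers_per_class[[k]]))))
    n_inf <- config$n_informative_markers
    inf_idx <- integer(0)
    dirs <- integer(0)
    if (n_inf > 0) {
      inf_idx <- sort(sample.int(n_mark, n_inf))
      # ensure a metabolite is present to act as the up-regulated
      # lactate-like marker
      metab <- which(subclass == "metabolite")
      if (length(metab) && !any(inf_idx %in% metab))
        inf_idx[1] <- sample(metab, 1L)
      inf_idx <- sort(inf_idx)
      dirs <- rep(-1L, n_inf)
      n_up <- max(1L, round(config$marker_up_fraction * n_inf))
      up_pool <- which(inf_idx %in% metab)
      if (!length(up_pool)) up_pool <- 1L
      first_up <- up_pool[1]
      extra <- setdiff(sample.int(n_inf), first_up)[seq_len(max(0L, n_up - 1L))]
      dirs[c(first_up, extra)] <- 1L
      if (length(metab)) marker_id[inf_idx[first_up]] <- "lactate"
    }

    # auxiliary classes: first half of each class informative
    aux_id <- unlist(lapply(names(.aux_classes), function(k)
      sprintf("%s_%02d", k, seq_len(.aux_classes[[k]]))))
    aux_class <- rep(names(.aux_classes), .aux_classes)
    aux_dir <- ifelse(aux_class == "neurocognitive", -1L, 1L)
    aux_inf <- unlist(lapply(unname(.aux_classes), function(nk)
      seq_len(nk) <= ceiling(nk / 2)))

    list(item_id = item_id, scale_id = scale_id, ranges = ranges, type = type,
         l = l, cz = cz, g = g, cu = cu, h = h, cv = cv, noise = noise,
         marker_id = marker_id, marker_subclass = subclass,
         informative_idx = inf_idx, informative_dir = dirs,
         aux_id = aux_id, aux_class = aux_class, aux_dir = aux_dir,
         aux_informative = aux_inf)
  })
}

# equicorrelated Gaussian block: sqrt(rho) * shared + sqrt(1-rho) * noise
equicorrelated_block <- function(n, p, rho) {
  shared <- stats::rnorm(n)
  sqrt(rho) * matrix(shared, n, p) + sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
}

generate_sample <- function(config, bank, n_hc, n_case, role, id_prefix) {
  k <- length(config$subtype_proportions)
  sizes <- subtype_sizes(n_case, config$subtype_proportions)
  subtype_names <- sprintf("S%d", seq_len(k))
  sub <- sample(rep(subtype_names, sizes))
  n <- n_hc + n_case
  group <- rep(c("hc", "case"), c(n_hc, n_case))
  mu_z <- c(rep(config$severity_means[1], n_hc),
            config$severity_means[-1][match(sub, subtype_names)])
  z <- stats::rnorm(n, mu_z, config$severity_sd)
  # profile trait graded across subtypes: none for the mildest, full shift
  # for the most severe (a single-subtype cohort has no severe-specific
  # profile, so discovered structure there is noise)
  u_mean <- numeric(n)
  u_weight <- if (k == 1L) 0 else (match(sub, subtype_names) - 1) / (k - 1)
  u_mean[group == "case"] <- config$profile_shift * u_weight
  u <- stats::rnorm(n, u_mean, config$profile_sd)
  v <- stats::rnorm(n, ifelse(group == "case", config$distress_shift, 0),
                    config$distress_sd)

  p_items <- length(bank$item_id)
  lat <- outer(z, bank$l) - rep(bank$l * bank$cz, each = n) +
    outer(u, bank$g) - rep(bank$g * bank$cu, each = n) +
    outer(v, bank$h) - rep(bank$h * bank$cv, each = n) +
    matrix(stats::rnorm(n * p_items), n) *
      rep(bank$noise, each = n)
  items <- round(stats::pnorm(lat) * rep(bank$ranges, each = n))

  scales <- unique(bank$scale_id)
  summaries <- vapply(scales, function(s)
    rowSums(items[, bank$scale_id == s, drop = FALSE]), numeric(n))
  colnames(summaries) <- paste0(scales, "_total")

  sub_full <- c(rep(NA_character_, n_hc), sub)
  w <- c(0, .marker_weights(k))[match(ifelse(group == "hc", "hc", sub_full),
                                      c("hc", subtype_names))]
  markers <- matrix(0, n, length(bank$marker_id))
  for (cls in unique(bank$marker_subclass)) {
    idx <- which(bank$marker_subclass == cls)
    markers[, idx] <- equicorrelated_block(n, length(idx),
                                           config$block_correlation)
  }
  if (length(bank$informative_idx))
    markers[, bank$informative_idx] <- markers[, bank$informative_idx] +
      outer(w * config$marker_effect_size, bank$informative_dir)

  aux <- matrix(0, n, length(bank$aux_id))
  for (cls in unique(bank$aux_class)) {
    idx <- which(bank$aux_class == cls)
    aux[, idx] <- equicorrelated_block(n, length(idx), config$block_correlation)
    inf <- idx[bank$aux_informative[idx]]
    eff <- config$aux_class_effect_sizes[[cls]]
    if (length(inf) && eff != 0)
      aux[, inf] <- aux[, inf] + outer(w * eff, bank$aux_dir[inf])
  }

  values <- cbind(items, summaries, markers, aux)
  colnames(values) <- c(bank$item_id, colnames(summaries), bank$marker_id,
                        bank$aux_id)
  subject_ids <- c(sprintf("%s_HC_%03d", id_prefix, seq_len(n_hc)),
                   sprintf("%s_C_%03d", id_prefix, seq_len(n_case)))
  rownames(values) <- subject_ids
  list(subject_ids = subject_ids, group = group, role = rep(role, n),
       true_subtype = c(rep(NA_character_, n_hc), sub), values = values)
}

#' Generate a synthetic discovery + validation cohort
#'
#' Draws a complete subject-by-feature table under the configured generative
#' model: ordinal clinical items and their scale totals, multi-omic
#' biomarkers with planted informative markers, and five auxiliary feature
#' classes. Calling with the same configuration (including seed) is
#' bit-reproducible.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `cohort_table` with elements `subject_ids`,
#'   `group` (`"case"`/`"hc"`), `role` (`"discovery"`/`"validation"`),
#'   `true_subtype` (generator ground truth, `NA` for controls), `values`
#'   (numeric matrix, subjects x features) and `feature_meta` (data frame
#'   with `feature_id`, `class`, `subclass`, `scale_id`,
#'   `expected_direction`).
#' @examples
#' tab <- generate_cohort(cohort_config(seed = 7))
#' dim(tab$values)
#' table(tab$group, tab$role)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_("`config` must be created by cohort_config()")
  bank <- item_bank(config)
  parts <- with_seed(config$seed, {
    disc <- generate_sample(config, bank, config$n_hc_discovery,
                            config$n_case_discovery, "discovery", "D")
    val <- generate_sample(config, bank, config$n_hc_validation,
                           config$n_case_validation, "validation", "V")
    list(disc, val)
  })
  values <- rbind(parts[[1]]$values, parts[[2]]$values)
  n_items <- length(bank$item_id)
  scales <- unique(bank$scale_id)
  exp_dir <- rep("", ncol(values))
  names(exp_dir) <- colnames(values)
  if (length(bank$informative_idx))
    exp_dir[bank$marker_id[bank$informative_idx]] <-
      ifelse(bank$informative_dir > 0, "up", "down")
  feature_meta <- data.frame(
    feature_id = colnames(values),
    class = c(rep("clinical_item", n_items),
              rep("clinical_summary", length(scales)),
              rep("biomarker", length(bank$marker_id)),
              bank$aux_class),
    subclass = c(rep("", n_items + length(scales)), bank$marker_subclass,
                 rep("", length(bank$aux_id))),
    scale_id = c(bank$scale_id, scales,
                 rep("", length(bank$marker_id) + length(bank$aux_id))),
    expected_direction = unname(exp_dir),
    stringsAsFactors = FALSE
  )
  out <- list(
    subject_ids = c(parts[[1]]$subject_ids, parts[[2]]$subject_ids),
    group = c(parts[[1]]$group, parts[[2]]$group),
    role = c(parts[[1]]$role, parts[[2]]$role),
    true_subtype = c(parts[[1]]$true_subtype, parts[[2]]$true_subtype),
    values = values,
    feature_meta = feature_meta,
    config = config
  )
  class(out) <- "cohort_table"
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Synthetic cohort table\n")
  cat(sprintf("  subjects: %d\n", length(x$subject_ids)))
  tab <- table(x$role, x$group)
  for (r in rownames(tab))
    cat(sprintf("    %s: %d cases, %d controls\n", r, tab[r, "case"],
                tab[r, "hc"]))
  cat(sprintf("  features: %d (%s)\n", nrow(x$feature_meta),
              paste(sprintf("%s %d", names(table(x$feature_meta$class)),
                            table(x$feature_meta$class)), collapse = ", ")))
  invisible(x)
}

#' Subset helper: feature columns of a given class
#'
#' @param cohort A `cohort_table`.
#' @param class Feature class name, or `"pooled"` for biomarkers plus all
#'   auxiliary classes.
#' @return Character vector of feature ids.
#' @export
features_of_class <- function(cohort, class) {
  fm <- cohort$feature_meta
  if (identical(class, "pooled"))
    return(fm$feature_id[fm$class %in% c("biomarker", names(.aux_classes))])
  if (!class %in% fm$class) stop_("unknown feature class '%s'", class)
  fm$feature_id[fm$class == class]
}

fmt_full <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  sub("^(-?\\d+)\\.0*$", "\\1", out)
}

#' Write a cohort to plain-text files
#'
#' Writes `<prefix>_matrix.csv` (subjects x features, first column
#' `subject_id`), `<prefix>_subjects.csv` (`subject_id`, `group`, `role`,
#' `true_subtype`) and `<prefix>_features.tsv` (`feature_id`, `class`,
#' `subclass`, `scale_id`, `expected_direction`). Numerics are written with
#' 17 significant digits so the round trip through [read_cohort()] is exact.
#'
#' @param cohort A `cohort_table`.
#' @param prefix Path prefix for the three files.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, prefix) {
  if (!inherits(cohort, "cohort_table")) stop_("`cohort` must be a cohort_table")
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  mat_file <- paste0(prefix, "_matrix.csv")
  subj_file <- paste0(prefix, "_subjects.csv")
  feat_file <- paste0(prefix, "_features.tsv")
  vals <- apply(cohort$values, 2, fmt_full)
  mat <- data.frame(subject_id = cohort$subject_ids, vals,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(mat, mat_file, row.names = FALSE, quote = FALSE)
  subj <- data.frame(
    subject_id = cohort$subject_ids, group = cohort$group, role = cohort$role,
    true_subtype = ifelse(is.na(cohort$true_subtype), "",
                          cohort$true_subtype),
    stringsAsFactors = FALSE
  )
  utils::write.csv(subj, subj_file, row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$feature_meta, feat_file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(mat_file, subj_file, feat_file))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `cohort_table` equal to the written one on all data fields.
#' @export
read_cohort <- function(prefix) {
  mat_file <- paste0(prefix, "_matrix.csv")
  subj_file <- paste0(prefix, "_subjects.csv")
  feat_file <- paste0(prefix, "_features.tsv")
  for (f in c(mat_file, subj_file, feat_file))
    if (!file.exists(f)) stop_("missing cohort file '%s'", f)
  mat <- utils::read.csv(mat_file, check.names = FALSE,
                         colClasses = "character")
  subj <- utils::read.csv(subj_file, colClasses = "character")
  fm <- utils::read.delim(feat_file, colClasses = "character")
  if (nrow(mat) != nrow(subj) ||
      !identical(sort(mat$subject_id), sort(subj$subject_id)))
    stop_("mismatched subject sets between matrix (%d) and subject labels (%d)",
          nrow(mat), nrow(subj))
  feat_cols <- setdiff(colnames(mat), "subject_id")
  missing_in_matrix <- setdiff(fm$feature_id, feat_cols)
  if (length(missing_in_matrix))
    stop_("feature '%s' listed in the sidecar is absent from the matrix",
          missing_in_matrix[1])
  extra <- setdiff(feat_cols, fm$feature_id)
  if (length(extra))
    stop_("matrix column '%s' has no sidecar metadata", extra[1])
  known <- c("clinical_item", "clinical_summary", "biomarker",
             names(.aux_classes))
  bad <- fm$feature_id[!fm$class %in% known]
  if (length(bad))
    stop_("unknown feature class '%s' for feature '%s'",
          fm$class[match(bad[1], fm$feature_id)], bad[1])
  values <- matrix(NA_real_, nrow(mat), length(feat_cols),
                   dimnames = list(mat$subject_id, feat_cols))
  for (j in seq_along(feat_cols)) {
    col <- mat[[feat_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      i <- which(is.na(num))[1]
      stop_("non-numeric value '%s' at row %d (subject %s), column '%s'",
            col[i], i, mat$subject_id[i], feat_cols[j])
    }
    values[, j] <- num
  }
  values <- values[, fm$feature_id, drop = FALSE]
  ord <- match(mat$subject_id, subj$subject_id)
  out <- list(
    subject_ids = mat$subject_id,
    group = subj$group[ord],
    role = subj$role[ord],
    true_subtype = ifelse(nzchar(subj$true_subtype[ord]),
                          subj$true_subtype[ord], NA_character_),
    values = values,
    feature_meta = fm,
    config = NULL
  )
  class(out) <- "cohort_table"
  out
}
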