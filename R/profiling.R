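# Clinical profiling of subtypes: PCA of summary scales, omnibus ANOVA +
# pairwise Wilcoxon comparisons with a family-wise threshold, two-sample t
# from printed summary statistics, and 2x2 Pearson chi-square.

#' Principal component analysis of summary scales
#'
#' Variables are z-scored and the correlation matrix eigen-decomposed.
#' The first component's sign is chosen so that it correlates positively
#' with `severity` (higher PC1 = more severe); remaining components have the
#' largest-magnitude loading made positive.
#'
#' @param x Numeric matrix (subjects x variables), no missing values.
#' @param severity Optional numeric vector used to orient PC1; if `NULL`,
#'   PC1 is oriented so the sum of its loadings is positive.
#' @return An object of class `pca_result` with `loadings`,
#'   `var_fractions` (non-increasing, summing to 1) and `scores`.
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' pca_summary(x)$var_fractions
#' @export
pca_summary <- function(x, severity = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop_("at least two variables are required")
  if (anyNA(x)) stop_("missing values are not allowed")
  if (is.null(colnames(x))) colnames(x) <- sprintf("v%02d", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop_("zero-variance variable: %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  eig <- eigen(stats::cor(x), symmetric = TRUE)
  loadings <- eig$vectors
  fractions <- eig$values / sum(eig$values)
  scores <- z %*% loadings
  # orientation
  if (!is.null(severity)) {
    if (stats::cor(scores[, 1], severity) < 0) {
      loadings[, 1] <- -loadings[, 1]; scores[, 1] <- -scores[, 1]
    }
  } else if (sum(loadings[, 1]) < 0) {
    loadings[, 1] <- -loadings[, 1]; scores[, 1] <- -scores[, 1]
  }
  for (j in seq.int(2L, ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) { loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j] }
  }
  dimnames(loadings) <- list(colnames(x), sprintf("PC%d", seq_len(ncol(x))))
  colnames(scores) <- colnames(loadings)
  rownames(scores) <- rownames(x)
  out <- list(loadings = loadings, var_fractions = fractions, scores = scores)
  class(out) <- "pca_result"
  out
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA of %d variables: PC1 %.1f%% of variance (PC2 %.1f%%)\n",
              nrow(x$loadings), 100 * x$var_fractions[1],
              100 * x$var_fractions[2]))
  invisible(x)
}

# Wilcoxon rank-sum: exact enumeration for small tie-free samples,
# tie-corrected continuity-corrected normal approximation otherwise.
wilcoxon_pair <- function(a, b) {
  exact <- max(length(a), length(b)) <= 25 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  c(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Omnibus and pairwise comparison of one variable across groups
#'
#' One-way ANOVA across all groups plus Wilcoxon rank-sum tests for every
#' pairwise contrast, flagged at a family-wise threshold.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) with at least two levels, each with
#'   at least 2 subjects.
#' @param alpha Family-wise significance threshold (default `1e-4`).
#' @return A list with `means`, `sds`, `anova_F`, `anova_p`, `pairwise`
#'   (data frame with contrast, statistic, p, significant) and
#'   `significant` (omnibus flag). Constant values in all groups give
#'   `NA` statistics marked `untestable`.
#' @export
omnibus_and_pairwise <- function(values, groups, alpha = 1e-4) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop_("at least two groups are required")
  if (any(table(groups) < 2L)) stop_("each group needs at least 2 subjects")
  if (length(values) != length(groups))
    stop_("values and groups differ in length")
  means <- tapply(values, groups, mean)
  sds <- tapply(values, groups, stats::sd)
  untestable <- stats::var(values) == 0
  if (untestable) {
    aF <- NA_real_; ap <- NA_real_
  } else {
    fit <- stats::anova(stats::lm(values ~ groups))
    aF <- fit[["F value"]][1]; ap <- fit[["Pr(>F)"]][1]
  }
  combos <- utils::combn(levels(groups), 2)
  pw <- data.frame(
    contrast = apply(combos, 2, function(cc) paste(cc[2], "vs", cc[1])),
    statistic = NA_real_, p = NA_real_, stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(combos))) {
    a <- values[groups == combos[2, j]]
    b <- values[groups == combos[1, j]]
    if (stats::var(c(a, b)) == 0) next
    res <- wilcoxon_pair(a, b)
    pw$statistic[j] <- res["statistic"]; pw$p[j] <- res["p"]
  }
  pw$significant <- !is.na(pw$p) & pw$p < alpha
  list(means = means, sds = sds, anova_F = aF, anova_p = ap,
       pairwise = pw, significant = !is.na(ap) && ap < alpha,
       untestable = untestable, alpha = alpha)
}

#' Two-sample t test from summary statistics
#'
#' Reconstructs the two-sided two-sample t test from printed means, standard
#' deviations and sample sizes, as used to compare published table rows.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries; `n >= 2`, `sd > 0`.
#' @param variant `"pooled"` (classical, df = n1 + n2 - 2) or `"welch"`
#'   (Satterthwaite df).
#' @return A list with `t`, `df` and two-sided `p`.
#' @examples
#' t_test_from_summary(32.50, 7.33, 74, 36.83, 10.24, 26)$p
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  check_count(n1, "n1", min = 2L); check_count(n2, "n2", min = 2L)
  check_scalar_number(sd1, "sd1", lower = 1e-12)
  check_scalar_number(sd2, "sd2", lower = 1e-12)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square for a 2x2 table
#'
#' Without continuity correction, as used for comparing subtype proportions.
#' Cells are `a` (group 1 positive), `b` (group 1 negative), `c` (group 2
#' positive), `d` (group 2 negative).
#'
#' @param a,b,c,d Non-negative integer counts with positive margins.
#' @return A list with `chi2`, `df` (1) and `p`.
#' @examples
#' chi_square_2x2(8, 18, 33, 15)$p
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  for (nm in c("a", "b", "c", "d")) check_count(get(nm), nm)
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop_("all table margins must be positive")
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Profile subtypes on clinical summary scales
#'
#' Emits, for every clinical summary scale and for the first principal
#' component of all scales, the group means/sds for controls and each
#' subtype, the omnibus ANOVA p, and pairwise Wilcoxon p values flagged at
#' the family-wise threshold; plus a comparison of the subtypes on the
#' demographic, comorbidity and psychiatric-history feature classes
#' (two-group pooled t, equivalent to a two-group ANOVA).
#'
#' @param cohort A `cohort_table`.
#' @param subtypes A `subtype_fit`.
#' @param alpha Family-wise threshold (default `1e-4`).
#' @return An object of class `profile_report` with `summary_table`,
#'   `pca` (a `pca_result`), `pc1_ratio` (the most severe subtype's mean
#'   PC1 elevation above controls divided by the least severe subtype's),
#'   `characteristics_table` and `alpha`.
#' @export
profile_subtypes <- function(cohort, subtypes, alpha = 1e-4) {
  stopifnot(inherits(cohort, "cohort_table"))
  groups <- analysis_groups(cohort, subtypes)
  disc_ids <- names(groups)
  summaries <- features_of_class(cohort, "clinical_summary")
  if (!length(summaries)) stop_("no clinical summary scales in cohort")
  missing <- setdiff(summaries, colnames(cohort$values))
  if (length(missing))
    stop_("missing summary scales: %s", paste(missing, collapse = ", "))
  vals <- cohort$values[disc_ids, summaries, drop = FALSE]
  sev <- cohort$values[disc_ids, subtypes$severity_feature]
  pca <- pca_summary(vals, severity = sev)

  analyse <- function(v) omnibus_and_pairwise(v, groups, alpha)
  rows <- c(list(PC1 = analyse(pca$scores[, 1])),
            stats::setNames(lapply(summaries, function(f)
              analyse(vals[, f])), summaries))
  lv <- levels(groups)
  summary_table <- do.call(rbind, lapply(names(rows), function(nm) {
    r <- rows[[nm]]
    row <- data.frame(variable = nm, stringsAsFactors = FALSE)
    for (g in lv) {
      row[[paste0("mean_", g)]] <- unname(r$means[g])
      row[[paste0("sd_", g)]] <- unname(r$sds[g])
    }
    row$anova_p <- r$anova_p
    for (j in seq_len(nrow(r$pairwise))) {
      cn <- gsub(" ", "_", r$pairwise$contrast[j])
      row[[paste0("p_", cn)]] <- r$pairwise$p[j]
    }
    row$significant <- r$significant
    row
  }))

  sub_lv <- setdiff(lv, "HC")
  pc1_means <- tapply(pca$scores[, 1], groups, mean)
  # PC1 scores are centered, so compare subtype elevations above controls
  pc1_ratio <- unname((pc1_means[sub_lv[length(sub_lv)]] - pc1_means["HC"]) /
                        (pc1_means[sub_lv[1]] - pc1_means["HC"]))

  # subtype-vs-subtype characteristics (most vs least severe subtype)
  char_classes <- intersect(c("demographic", "comorbidity",
                              "psychiatric_history"),
                            unique(cohort$feature_meta$class))
  a_ids <- disc_ids[groups == sub_lv[1]]
  b_ids <- disc_ids[groups == sub_lv[length(sub_lv)]]
  char_rows <- lapply(char_classes, function(cl) {
    feats <- features_of_class(cohort, cl)
    do.call(rbind, lapply(feats, function(f) {
      va <- cohort$values[a_ids, f]; vb <- cohort$values[b_ids, f]
      tt <- t_test_from_summary(mean(va), max(stats::sd(va), 1e-12),
                                length(va), mean(vb),
                                max(stats::sd(vb), 1e-12), length(vb))
      data.frame(variable = f, class = cl,
                 mean_a = mean(va), sd_a = stats::sd(va),
                 mean_b = mean(vb), sd_b = stats::sd(vb),
                 p = tt$p, stringsAsFactors = FALSE)
    }))
  })
  characteristics <- do.call(rbind, char_rows)
  if (!is.null(characteristics))
    names(characteristics)[3:6] <- c(paste0("mean_", sub_lv[1]),
                                     paste0("sd_", sub_lv[1]),
                                     paste0("mean_", sub_lv[length(sub_lv)]),
                                     paste0("sd_", sub_lv[length(sub_lv)]))

  out <- list(summary_table = summary_table, pca = pca,
              pc1_ratio = pc1_ratio,
              characteristics_table = characteristics, alpha = alpha,
              groups = groups)
  class(out) <- "profile_report"
  out
}

#' @export
print.profile_report <- function(x, ...) {
  n_sig <- sum(x$summary_table$significant, na.rm = TRUE)
  cat(sprintf("Subtype profile: %d/%d summary variables significant at p < %g\n",
              n_sig, nrow(x$summary_table), x$alpha))
  cat(sprintf("  PC1 variance fraction %.2f; PC1 mean ratio (severe/mild) %.2f\n",
              x$pca$var_fractions[1], x$pc1_ratio))
  invisible(x)
}
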