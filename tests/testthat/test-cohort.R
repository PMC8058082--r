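# Synthetic cohort generator: determinism, planted structure, calibration,
# and file round trips.

test_that("same configuration yields bit-identical cohorts", {
  a <- generate_cohort(cohort_config(seed = 7))
  b <- generate_cohort(cohort_config(seed = 7))
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(seed = 8))
  expect_false(identical(a$values, c$values))
})

test_that("default proportions plant subtypes of 26 and 48 cases", {
  tab <- generate_cohort(cohort_config(seed = 1))
  disc_cases <- tab$role == "discovery" & tab$group == "case"
  expect_equal(as.integer(table(tab$true_subtype[disc_cases])[c("S1", "S2")]),
               c(26L, 48L))
  # subtype labels exist only for cases
  expect_true(all(is.na(tab$true_subtype[tab$group == "hc"])))
  expect_true(all(!is.na(tab$true_subtype[tab$group == "case"])))
})

test_that("rounding that empties a planted subtype is an explicit error", {
  expect_error(
    generate_cohort(cohort_config(
      n_case_discovery = 10L, subtype_proportions = c(0.001, 0.999),
      severity_means = c(0, 5.8, 7.3), seed = 1)),
    "empty planted subtype")
})

test_that("simulated severity-scale totals match the calibration targets", {
  # Monte-Carlo check of the generator's group means at n = 1000 per group
  cfg <- cohort_config(n_hc_discovery = 1000L, n_case_discovery = 2000L,
                       n_hc_validation = 0L, n_case_validation = 2L,
                       subtype_proportions = c(0.5, 0.5), seed = 42)
  tab <- generate_cohort(cfg)
  d <- tab$role == "discovery"
  g <- ifelse(tab$group[d] == "hc", "HC", tab$true_subtype[d])
  m <- tapply(tab$values[d, "CAPS_total"], g, mean)
  expect_lt(abs(m[["HC"]] - 3.37), 5)
  expect_lt(abs(m[["S1"]] - 54.31), 5)
  expect_lt(abs(m[["S2"]] - 75.60), 5)
  # severity ordering propagates to every scale total
  totals <- grep("_total$", colnames(tab$values), value = TRUE)
  for (f in totals) {
    mm <- tapply(tab$values[d, f], g, mean)
    expect_true(mm[["HC"]] < mm[["S1"]] & mm[["S1"]] < mm[["S2"]],
                label = sprintf("severity ordering for %s", f))
  }
})

test_that("expected severity-total is monotone in the severe subtype mean", {
  caps_s2 <- vapply(c(6.5, 7.3, 8.1), function(z2) {
    cfg <- cohort_config(n_hc_discovery = 4L, n_case_discovery = 2000L,
                         n_hc_validation = 0L, n_case_validation = 2L,
                         subtype_proportions = c(0.5, 0.5),
                         severity_means = c(0, 5.83, z2), seed = 5)
    tab <- generate_cohort(cfg)
    d <- tab$role == "discovery"
    mean(tab$values[d, "CAPS_total"][tab$true_subtype[d] %in% "S2"])
  }, numeric(1))
  expect_true(all(diff(caps_s2) > 0))
})

test_that("planted markers reach their nominal effect size within 0.1", {
  cfg <- cohort_config(n_hc_discovery = 2000L, n_case_discovery = 4000L,
                       n_hc_validation = 0L, n_case_validation = 2L,
                       subtype_proportions = c(0.5, 0.5), seed = 11)
  tab <- generate_cohort(cfg)
  d <- tab$role == "discovery"
  hc <- d & tab$group == "hc"
  s2 <- d & tab$true_subtype %in% "S2"
  fm <- tab$feature_meta
  inf <- fm$feature_id[fm$class == "biomarker" & fm$expected_direction != ""]
  expect_length(inf, 20L)
  for (f in inf) {
    pooled_sd <- sqrt((stats::var(tab$values[hc, f]) +
                         stats::var(tab$values[s2, f])) / 2)
    d_obs <- (mean(tab$values[s2, f]) - mean(tab$values[hc, f])) / pooled_sd
    d_exp <- ifelse(fm$expected_direction[fm$feature_id == f] == "up", 0.8,
                    -0.8)
    expect_lt(abs(d_obs - d_exp), 0.1)
  }
  # at least one up-regulated lactate-like metabolite is planted
  expect_true("lactate" %in% inf)
  expect_identical(fm$expected_direction[fm$feature_id == "lactate"], "up")
})

test_that("a null configuration leaves group means at sampling noise", {
  # severity means almost equal and all planted effects at zero: every
  # feature's case-control t statistic should look null
  n_seeds <- 10
  frac_ok <- vapply(seq_len(n_seeds), function(s) {
    cfg <- cohort_config(
      n_hc_discovery = 1000L, n_case_discovery = 1000L,
      n_hc_validation = 0L, n_case_validation = 2L,
      subtype_proportions = c(0.5, 0.5),
      severity_means = c(0, 1e-7, 2e-7),
      profile_shift = 0, distress_shift = 0, marker_effect_size = 0,
      aux_class_effect_sizes = c(comorbidity = 0, neurocognitive = 0,
                                 demographic = 0, psychiatric_history = 0,
                                 premilitary_trauma = 0),
      seed = s)
    tab <- generate_cohort(cfg)
    d <- tab$role == "discovery"
    grp <- tab$group[d]
    vals <- tab$values[d, ]
    keep <- apply(vals, 2, stats::var) > 0
    tstat <- apply(vals[, keep], 2, function(v) {
      va <- v[grp == "case"]; vb <- v[grp == "hc"]
      (mean(va) - mean(vb)) /
        sqrt(stats::var(va) / length(va) + stats::var(vb) / length(vb))
    })
    mean(abs(tstat) < 4)
  }, numeric(1))
  expect_true(all(frac_ok >= 0.99))
})

test_that("cohorts round-trip through their plain-text files", {
  tab <- generate_cohort(cohort_config(seed = 3))
  prefix <- file.path(tempfile("cohort"), "run")
  write_cohort(tab, prefix)
  back <- read_cohort(prefix)
  expect_identical(back$subject_ids, tab$subject_ids)
  expect_identical(back$group, tab$group)
  expect_identical(back$role, tab$role)
  expect_identical(back$true_subtype, tab$true_subtype)
  expect_equal(back$values, tab$values)
  expect_identical(back$feature_meta, tab$feature_meta)
})

test_that("malformed cohort files produce named errors", {
  tab <- generate_cohort(cohort_config(seed = 3))
  prefix <- file.path(tempfile("cohort"), "run")
  write_cohort(tab, prefix)

  # sidecar feature missing from the matrix
  fm <- utils::read.delim(paste0(prefix, "_features.tsv"),
                          colClasses = "character")
  fm2 <- rbind(fm, data.frame(feature_id = "ghost_marker",
                              class = "biomarker", subclass = "mirna",
                              scale_id = "", expected_direction = ""))
  utils::write.table(fm2, paste0(prefix, "_features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(prefix), "ghost_marker")
  utils::write.table(fm, paste0(prefix, "_features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # unknown feature class names the offending feature
  fm3 <- fm
  fm3$class[5] <- "astrology"
  utils::write.table(fm3, paste0(prefix, "_features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(prefix), fm$feature_id[5])
  utils::write.table(fm, paste0(prefix, "_features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # non-numeric cell is reported with row and column
  mat <- readLines(paste0(prefix, "_matrix.csv"))
  mat[3] <- sub("^([^,]*,[^,]*),[^,]*", "\\1,oops", mat[3])
  writeLines(mat, paste0(prefix, "_matrix.csv"))
  err <- tryCatch(read_cohort(prefix), error = conditionMessage)
  expect_match(err, "non-numeric")
  expect_match(err, "row 2")
})
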