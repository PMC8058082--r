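# Biomarker validation: contrast classification, direction tests, CCA.

test_that("an exact linear relation gives canonical correlations of one", {
  set.seed(1)
  x <- matrix(rnorm(50 * 3), 50)
  m <- matrix(c(1, 0.5, 0, -1, 2, 1, 0, 0, 1), 3)
  res <- cca(x, x %*% m)
  expect_true(all(abs(res$cor - 1) < 1e-8))
})

test_that("independent sets have small canonical correlations", {
  set.seed(2)
  res <- cca(matrix(rnorm(500 * 3), 500), matrix(rnorm(500 * 2), 500))
  expect_true(all(res$cor < 0.2))
})

test_that("cca matches a grid-plus-refinement search oracle for u = v = 2", {
  set.seed(3)
  x <- matrix(rnorm(50 * 2), 50)
  y <- 0.6 * x %*% matrix(c(1, 0.3, -0.2, 1), 2) + matrix(rnorm(100, sd = 0.8), 50)
  res <- cca(x, y)
  # oracle: for each x-weight angle, the best y combination is the fitted
  # value of a least-squares regression; refine the angle numerically
  best_cor <- function(theta) {
    xa <- x %*% c(cos(theta), sin(theta))
    fit <- stats::lm.fit(cbind(1, y), xa)
    stats::cor(xa, xa - fit$residuals)
  }
  grid <- seq(0, pi, length.out = 2000)
  vals <- vapply(grid, best_cor, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(best_cor, c(lo, hi), maximum = TRUE, tol = 1e-12)
  expect_lt(abs(res$cor[1] - opt$objective), 1e-8)
})

test_that("canonical correlations are affine invariant", {
  set.seed(4)
  for (s in 1:50) {
    n <- 40; u <- sample(2:4, 1); v <- sample(2:4, 1)
    x <- matrix(rnorm(n * u), n)
    y <- matrix(rnorm(n * v), n)
    y[, 1] <- y[, 1] + 0.5 * x[, 1]
    a <- cca(x, y)$cor
    mx <- matrix(rnorm(u * u), u); while (abs(det(mx)) < 0.1)
      mx <- matrix(rnorm(u * u), u)
    my <- matrix(rnorm(v * v), v); while (abs(det(my)) < 0.1)
      my <- matrix(rnorm(v * v), v)
    b <- cca(sweep(x %*% mx, 2, rnorm(u), "+"),
             sweep(y %*% my, 2, rnorm(v), "+"))$cor
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("successive canonical variates are uncorrelated within each set", {
  set.seed(5)
  x <- matrix(rnorm(100 * 4), 100)
  y <- matrix(rnorm(100 * 3), 100)
  res <- cca(x, y)
  cx <- cor(res$xscores); cy <- cor(res$yscores)
  expect_lt(max(abs(cx[upper.tri(cx)])), 1e-8)
  expect_lt(max(abs(cy[upper.tri(cy)])), 1e-8)
  expect_true(all(diff(res$cor) <= 1e-12))
})

test_that("zero-variance columns are rejected by name", {
  x <- cbind(a = rnorm(30), flat = rep(2, 30))
  expect_error(cca(x, matrix(rnorm(60), 30)), "flat")
})

test_that("panel comparison drops overlap and rejects empty remainders", {
  set.seed(6)
  n <- 500
  latent <- matrix(rnorm(n * 2), n)
  panel <- function(p) latent %*% matrix(rnorm(2 * p), 2) +
    matrix(rnorm(n * p, sd = 0.4), n)
  vals <- cbind(panel(4), panel(3))
  colnames(vals) <- paste0("m", 1:7)
  coh <- manual_cohort(vals, group = rep("case", n))
  res <- compare_marker_panels(coh, paste0("m", 1:4), paste0("m", 5:7))
  expect_gte(res$cor[1], 0.9)
  expect_error(compare_marker_panels(coh, paste0("m", 1:4), paste0("m", 1:4)),
               "non-overlapping")
  expect_error(compare_marker_panels(coh, "m1", "nope"), "unknown")
})

test_that("disjoint noise panels stay below the permutation null", {
  set.seed(7)
  n <- 150
  vals <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("m", 1:6)))
  coh <- manual_cohort(vals, group = rep("case", n))
  obs <- compare_marker_panels(coh, paste0("m", 1:3), paste0("m", 4:6))$cor[1]
  null <- replicate(200, {
    cca(vals[, 1:3], vals[sample(n), 4:6])$cor[1]
  })
  expect_lt(obs, quantile(null, 0.95) + 0.05)
})

test_that("the Bonferroni layout of five markers by four contrasts gives 0.0025", {
  set.seed(8)
  n_per <- c(HC = 30, S1 = 20, S2 = 25)
  g <- factor(rep(names(n_per), n_per), levels = names(n_per))
  vals <- matrix(rnorm(75 * 25), 75, dimnames = list(NULL, paste0("b", 1:25)))
  rownames(vals) <- sprintf("s%03d", 1:75)
  coh <- manual_cohort(vals, group = ifelse(g == "HC", "hc", "case"))
  groups <- stats::setNames(as.character(g), rownames(vals))
  reports <- list(
    fake_report(paste0("b", 1:5), "S2", "S1"),
    fake_report(paste0("b", 6:10), "S1", "HC"),
    fake_report(paste0("b", 11:15), "S2", "HC"),
    fake_report(paste0("b", 16:20), "case", "HC"))
  res <- marker_direction_tests(coh, groups, reports, top_k = 5)
  expect_identical(attr(res, "m"), 20L)
  expect_equal(attr(res, "threshold"), 0.05 / 20)
})

test_that("direction calls have power for planted shifts and stay silent under the null", {
  flags <- t(vapply(1:20, function(s) {
    set.seed(s)
    vals <- cbind(down_marker = c(rnorm(71), rnorm(48, -1.5)),
                  null_marker = rnorm(119))
    rownames(vals) <- sprintf("s%03d", 1:119)
    coh <- manual_cohort(vals, group = rep(c("hc", "case"), c(71, 48)))
    groups <- stats::setNames(rep(c("HC", "S2"), c(71, 48)), rownames(vals))
    res <- marker_direction_tests(
      coh, groups, list(fake_report(colnames(vals), "S2", "HC")), top_k = 2)
    c(res$direction[res$marker == "down_marker"] == "down",
      res$direction[res$marker == "null_marker"] == "ns")
  }, logical(2)))
  expect_gte(mean(flags[, 1]), 0.95)
  expect_gte(mean(flags[, 2]), 0.95)
})

test_that("swapping group labels flips directions but not p values", {
  set.seed(9)
  vals <- cbind(m1 = c(rnorm(40), rnorm(40, 2)))
  rownames(vals) <- sprintf("s%03d", 1:80)
  coh <- manual_cohort(vals, group = rep(c("hc", "case"), each = 40))
  g1 <- stats::setNames(rep(c("S1", "S2"), each = 40), rownames(vals))
  g2 <- stats::setNames(rep(c("S2", "S1"), each = 40), rownames(vals))
  r1 <- marker_direction_tests(coh, g1, list(fake_report("m1", "S2", "S1")),
                               top_k = 1)
  r2 <- marker_direction_tests(coh, g2, list(fake_report("m1", "S2", "S1")),
                               top_k = 1)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_identical(sort(c(r1$direction, r2$direction)), c("down", "up"))
})

test_that("classify_contrast separates planted biomarker signal from noise", {
  tab <- generate_cohort(cohort_config(seed = 10))
  fit <- discover_subtypes(tab, n_trees = 400, seed = 101)
  groups <- analysis_groups(tab, fit)
  rep_bio <- classify_contrast(tab, groups, c("S2", "HC"), "biomarker",
                               n_trees = 600, seed = 11)
  expect_gte(rep_bio$auc, 0.9)
  fm <- tab$feature_meta
  planted <- fm$feature_id[fm$expected_direction != ""]
  recovery <- mean(planted %in% rep_bio$markers)
  expect_gte(recovery, 0.6)
  # a no-effect feature class stays at chance
  rep_dem <- classify_contrast(tab, groups, c("S2", "HC"), "demographic",
                               n_trees = 600, seed = 12, min_features = 2)
  expect_gt(rep_dem$auc, 0.25)
  expect_lt(rep_dem$auc, 0.7)
  # pooling classes does not destroy the biomarker signal
  rep_pool <- classify_contrast(tab, groups, c("S2", "HC"), "pooled",
                                n_trees = 600, seed = 13)
  expect_gte(rep_pool$auc, rep_bio$auc - 0.05)
})

test_that("shaving recovers most planted markers at pipeline tree counts", {
  hits <- vapply(1:3, function(s) {
    tab <- generate_cohort(cohort_config(seed = s + 20))
    groups <- stats::setNames(
      ifelse(tab$group == "hc", "HC", tab$true_subtype),
      tab$subject_ids)[tab$role == "discovery"]
    rep_bio <- classify_contrast(tab, groups, c("S2", "HC"), "biomarker",
                                 n_trees = 1500, seed = s)
    fm <- tab$feature_meta
    planted <- fm$feature_id[fm$expected_direction != ""]
    mean(planted %in% rep_bio$markers)
  }, numeric(1))
  expect_gte(sum(hits >= 0.8), 2)
})
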