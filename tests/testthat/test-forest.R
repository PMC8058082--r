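# Forest engine: OOB scores, AUC, importance, proximity, external scoring.

test_that("forests are bit-reproducible and separate strong classes", {
  dat <- sep_classes(n_per = 30, p = 5, d = 5, seed = 1)
  f1 <- fit_forest(dat$x, dat$y, n_trees = 500, seed = 1)
  f2 <- fit_forest(dat$x, dat$y, n_trees = 500, seed = 1)
  expect_identical(f1$inbag, f2$inbag)
  expect_identical(f1$leaves, f2$leaves)
  expect_identical(f1$votes, f2$votes)
  expect_gte(oob_auc(f1), 0.99)
  # per-tree bootstrap size equals the training-set size
  expect_true(all(colSums(f1$inbag) == nrow(dat$x)))
})

test_that("shuffled labels give chance-level OOB AUC", {
  # at n = 100 the OOB AUC has a sampling sd near 0.065, so the chance
  # band is asserted for the bulk of seeds plus a centered mean
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(100 * 30), 100)
    y <- factor(sample(rep(c("a", "b"), 50)))
    oob_auc(fit_forest(x, y, n_trees = 150, seed = s))
  }, numeric(1))
  expect_gte(sum(aucs > 0.35 & aucs < 0.65), 18)
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("degenerate forest inputs are rejected", {
  dat <- sep_classes(seed = 2)
  expect_error(fit_forest(dat$x, factor(rep("a", nrow(dat$x)))), "two classes")
  xx <- dat$x; xx[1, 1] <- NA
  expect_error(fit_forest(xx, dat$y), "non-finite")
  expect_error(fit_forest(dat$x, dat$y, n_trees = 0), "n_trees")
})

test_that("OOB scores agree with a brute-force recount", {
  dat <- sep_classes(n_per = 15, p = 4, d = 2, seed = 3)
  fit <- fit_forest(dat$x, dat$y, n_trees = 60, seed = 3)
  sc <- oob_scores(fit)
  for (i in seq_along(sc)) {
    num <- 0; den <- 0
    for (t in seq_len(fit$n_trees)) {
      if (fit$inbag[i, t] == 0) {
        den <- den + 1
        if (fit$votes[i, t]) num <- num + 1
      }
    }
    expect_equal(unname(sc[i]), num / den)
  }
})

test_that("a single-tree forest forces its OOB score", {
  dat <- sep_classes(n_per = 10, p = 2, d = 6, seed = 4)
  fit <- fit_forest(dat$x, dat$y, n_trees = 1, seed = 4)
  sc <- oob_scores(fit)
  oob_idx <- which(fit$inbag[, 1] == 0)
  inbag_idx <- which(fit$inbag[, 1] > 0)
  # in-bag-everywhere subjects are flagged, not silently scored
  expect_true(all(is.na(sc[inbag_idx])))
  expect_setequal(attr(sc, "undefined"), fit$subject_ids[inbag_idx])
  # an OOB subject's score is exactly its single tree's vote
  expect_true(all(sc[oob_idx] == as.numeric(fit$votes[oob_idx, 1])))
})

test_that("auc_roc reproduces forced examples and rejects one-class input", {
  expect_equal(auc_roc(c(0.9, 0.4, 0.5, 0.1),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_equal(auc_roc(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(auc_roc(rep(0.3, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(auc_roc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("auc_roc equals the Mann-Whitney pair count on random vectors", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(pos) || all(!pos)) pos[1:2] <- c(TRUE, FALSE)
    r <- auc_roc(scores, pos)
    expect_identical(r$auc, auc_paircount(scores, pos))
    # stored curve is consistent: tpr/fpr non-decreasing, trapezoid = auc
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
    trap <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
  }
})

test_that("gini importance concentrates on informative features", {
  # single informative feature takes all the importance
  set.seed(5)
  x <- cbind(f1 = rep(c(0, 1), each = 20))
  y <- factor(rep(c("a", "b"), each = 20))
  fit <- fit_forest(x, y, n_trees = 50, seed = 5)
  imp <- gini_importance(fit)
  expect_gt(imp[["f1"]], 0)

  # two strong features out-rank pure noise in nearly every replicate
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(80 * 12), 80,
                dimnames = list(NULL, paste0("f", 1:12)))
    y <- factor(rep(c("a", "b"), each = 40))
    x[y == "b", 1:2] <- x[y == "b", 1:2] + 3
    imp <- gini_importance(fit_forest(x, y, n_trees = 150, seed = s))
    all(c("f1", "f2") %in% names(sort(imp, decreasing = TRUE))[1:2])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("single-tree Gini decrease matches the hand formula", {
  # perfect split on one binary feature: decrease = n * gini(root)
  # = 2ab/(a+b) with a, b the in-bag class counts
  x <- cbind(f1 = c(0, 0, 0, 1, 1, 1))
  y <- factor(c("a", "a", "a", "b", "b", "b"))
  for (s in 1:5) {
    fit <- fit_forest(x, y, n_trees = 1, seed = s)
    a <- sum(fit$inbag[y == "a", 1]); b <- sum(fit$inbag[y == "b", 1])
    if (a == 0 || b == 0) next  # degenerate bootstrap grows no split
    expect_equal(unname(gini_importance(fit)[["f1"]]), 2 * a * b / (a + b))
  }
})

test_that("proximity matches a brute-force leaf tally in both modes", {
  dat <- sep_classes(n_per = 10, p = 4, d = 2, seed = 6)
  fit <- fit_forest(dat$x, dat$y, n_trees = 50, seed = 6)
  pm <- rf_proximity(fit, mode = "all_trees")
  n <- nrow(dat$x)
  manual <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    manual[i, j] <- mean(fit$leaves[i, ] == fit$leaves[j, ])
  expect_identical(unname(pm$values), manual)
  expect_identical(diag(pm$values), rep(1, n) |> stats::setNames(fit$subject_ids))

  po <- rf_proximity(fit, mode = "oob_pairs")
  for (i in 1:n) for (j in 1:n) {
    both <- fit$inbag[i, ] == 0 & fit$inbag[j, ] == 0
    expected <- if (any(both))
      mean(fit$leaves[i, both] == fit$leaves[j, both]) else NA_real_
    expect_identical(unname(po$values[i, j]), expected)
  }
})

test_that("duplicated subjects have proximity exactly one", {
  set.seed(7)
  x <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, paste0("f", 1:3)))
  x[2, ] <- x[1, ]
  y <- factor(rep(c("a", "b"), each = 10))
  fit <- fit_forest(x, y, n_trees = 100, seed = 7)
  pm <- rf_proximity(fit)
  expect_identical(unname(pm$values[1, 2]), 1)
})

test_that("proximity invariants hold across random forests", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(10:24, 1)
    x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
    y <- factor(rep(c("a", "b"), length.out = n))
    x[y == "b", 1] <- x[y == "b", 1] + 2
    pm <- rf_proximity(fit_forest(x, y, n_trees = 40, seed = s))
    expect_lt(max(abs(pm$values - t(pm$values))), 1e-12)
    expect_true(all(pm$values >= 0 & pm$values <= 1))
    expect_true(all(diag(pm$values) == 1))
    d <- proximity_distance(pm)
    expect_true(all(diag(d) == 0))
  }
})

test_that("external scoring matches training votes for duplicated subjects", {
  dat <- sep_classes(n_per = 20, p = 4, d = 4, seed = 8)
  fit <- fit_forest(dat$x, dat$y, n_trees = 100, seed = 8)
  sc <- score_external(fit, dat$x[3, , drop = FALSE])
  expect_equal(unname(sc), mean(fit$votes[3, ]))
  expect_error(score_external(fit, dat$x[0, , drop = FALSE]), "empty")
  expect_error(score_external(fit, dat$x[, 1:2]), "missing training features")
})

test_that("permuted-label OOB AUC is centered at one half", {
  dat <- sep_classes(n_per = 50, p = 5, d = 4, seed = 9)
  aucs <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    oob_auc(fit_forest(dat$x, sample(dat$y), n_trees = 100, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
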