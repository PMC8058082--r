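# Shared fixtures: small, fast datasets built in code.

# two well-separated Gaussian classes
sep_classes <- function(n_per = 30, p = 5, d = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- factor(rep(c("neg", "pos"), each = n_per), levels = c("neg", "pos"))
  x[y == "pos", ] <- x[y == "pos", ] + d / sqrt(p)
  list(x = x, y = y)
}

# random dissimilarity matrix with zero diagonal
random_distance <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  d
}

# exhaustive PAM optimum for k = 2
pam_bruteforce_k2 <- function(d) {
  n <- nrow(d)
  best <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cost <- sum(pmin(d[, i], d[, j]))
    if (cost < best) best <- cost
  }
  best
}

# tie-aware AUC by explicit pair counting
auc_paircount <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  total <- 0
  for (a in sp) for (b in sn)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# a minimal classification_report for direction-test unit tests
fake_report <- function(markers, positive, negative) {
  structure(list(contrast = paste(positive, "vs", negative),
                 positive = positive, negative = negative,
                 feature_class = "biomarker", auc = NA_real_,
                 n_markers = length(markers), markers = markers),
            class = "classification_report")
}

# a minimal cohort_table built directly from a matrix
manual_cohort <- function(values, group, role = NULL, classes = NULL) {
  n <- nrow(values)
  if (is.null(role)) role <- rep("discovery", n)
  if (is.null(classes)) classes <- rep("biomarker", ncol(values))
  if (is.null(rownames(values))) rownames(values) <- sprintf("s%03d", 1:n)
  structure(list(
    subject_ids = rownames(values), group = group, role = role,
    true_subtype = rep(NA_character_, n), values = values,
    feature_meta = data.frame(
      feature_id = colnames(values), class = classes,
      subclass = "", scale_id = "", expected_direction = "",
      stringsAsFactors = FALSE)),
    class = "cohort_table")
}
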