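test_that("agreement percentage is the diagonal share", {
  d <- confusion_matrix(diag(c(10, 20, 30, 25, 15)))
  expect_equal(agreement_percentage(d), 100)
  off <- matrix(2, 5, 5); diag(off) <- 0
  expect_equal(agreement_percentage(confusion_matrix(off)), 0)
  expect_error(agreement_percentage(confusion_matrix(matrix(0, 5, 5))), "empty")
})

test_that("Cohen's kappa: perfect agreement, chance-level agreement, degenerate input", {
  d <- confusion_matrix(diag(c(10, 20, 30, 25, 15)))
  expect_equal(cohen_kappa(d)$kappa, 1)

  # counts equal to the outer product of their marginals -> kappa = 0
  # (two categories used: rows (30, 70), cols (20, 80), n = 100)
  m <- matrix(0, 5, 5)
  m[1:2, 1:2] <- outer(c(30, 70), c(20, 80)) / 100
  k0 <- cohen_kappa(confusion_matrix(m))
  expect_equal(k0$kappa, 0)
  expect_true(k0$ci[1] <= 0 && k0$ci[2] >= 0)

  one <- matrix(0, 5, 5); one[3, 3] <- 50
  expect_error(cohen_kappa(confusion_matrix(one)), "undefined kappa")
})

test_that("kappa equals 1 iff agreement is 100% with non-degenerate marginals", {
  set.seed(21)
  for (i in 1:10) {
    counts <- matrix(rpois(25, 3), 5, 5)
    counts[1, 1] <- counts[1, 1] + 1 # nonempty
    cm <- confusion_matrix(counts)
    k <- cohen_kappa(cm)$kappa
    agree <- agreement_percentage(cm)
    expect_true(k <= 1 + 1e-12)
    expect_identical(isTRUE(all.equal(k, 1)), isTRUE(all.equal(agree, 100)))
  }
})

test_that("weighted kappa: schemes, collapse to unweighted on 2 categories", {
  d <- confusion_matrix(diag(c(10, 20, 30, 25, 15)))
  expect_equal(weighted_kappa(d, "linear"), 1)
  expect_equal(weighted_kappa(d, "quadratic"), 1)

  # any 2-category table: linear weights are the identity weights
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(0, 5, 5)
    m[1:2, 1:2] <- matrix(rpois(4, 20) + 1, 2, 2)
    cm2 <- confusion_matrix(m)
    k2 <- (cohen_kappa(cm2)$kappa)
    # weights 1 - |i-j|/4 over 5 levels differ; restrict to a true 2-level table
    cm_small <- structure(
      list(counts = m[1:2, 1:2], n_total = sum(m[1:2, 1:2])),
      class = "lordist_confusion"
    )
    expect_equal(weighted_kappa(cm_small, "linear"), cohen_kappa(cm_small)$kappa)
  }
})

test_that("the Fleiss variance flag gives a finite SE near the asymptotic one", {
  cm <- bundled_confusion()
  se_a <- cohen_kappa(cm)$se
  se_f <- cohen_kappa(cm, se = "fleiss")$se
  expect_true(is.finite(se_f) && se_f > 0)
  expect_lt(abs(se_f - se_a) / se_a, 0.5)
})

test_that("ICC(2,1) matches an independently coded ANOVA oracle to 1e-10", {
  icc_oracle <- function(y) {
    n <- nrow(y); k <- ncol(y)
    df <- data.frame(
      v = as.vector(y),
      subj = factor(rep(seq_len(n), k)),
      rater = factor(rep(seq_len(k), each = n))
    )
    fit <- stats::aov(v ~ subj + rater, data = df)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  set.seed(17)
  for (i in 1:8) {
    y <- matrix(rnorm(40, sd = runif(1, 0.5, 3)), 10, 4) +
      rnorm(10) # subject effects
    fit <- icc21(y)
    expect_equal(fit$icc, icc_oracle(y), tolerance = 1e-10)
    expect_true(fit$ci[1] <= fit$icc && fit$icc <= fit$ci[2])
  }
})

test_that("ICC behaves at the variance extremes and under shifts", {
  # identical ratings across raters, varying subjects -> ICC = 1
  y <- matrix(rep(rnorm(12), 3), 12, 3)
  expect_equal(icc21(y)$icc, 1)
  expect_equal(icc21(y)$label, "excellent")

  # one rater = other + overwhelming noise -> ICC near 0
  set.seed(4)
  subj <- rnorm(50, sd = 1)
  y2 <- cbind(subj, subj + rnorm(50, sd = 20))
  expect_lt(icc21(y2)$icc, 0.2)

  # shift invariance
  y3 <- matrix(rnorm(30), 10, 3)
  expect_equal(icc21(y3 + 100)$icc, icc21(y3)$icc, tolerance = 1e-9)

  expect_error(icc21(matrix(1, 1, 3)), "at least 2 subjects")
  expect_error(icc21(matrix(c(1, NA, 2, 3), 2, 2)), "complete grid")
})

test_that("repeatability is 2.77 times the within-subject SD", {
  # identical repeats -> 0
  r0 <- repeatability_error(rep(c(3, 3, 5, 5), 2), rep(1:4, each = 2))
  expect_equal(r0$repeatability, 0)

  # constant pair difference d -> 2.77 d / sqrt(2)
  d <- 0.8
  base <- rnorm(20)
  r1 <- repeatability_error(c(rbind(base, base + d)), rep(1:20, each = 2))
  expect_equal(r1$s_w, d / sqrt(2), tolerance = 1e-12)
  expect_equal(r1$repeatability, 2.77 * d / sqrt(2), tolerance = 1e-12)

  # Monte-Carlo consistency: estimate ~ 2.77 sigma at n = 1000
  set.seed(31)
  sigma <- 0.6
  vals <- rnorm(1000, sd = 3)[rep(1:1000, each = 2)] + rnorm(2000, sd = sigma)
  r2 <- repeatability_error(vals, rep(1:1000, each = 2))
  expect_equal(r2$repeatability, 2.77 * sigma, tolerance = 0.08)

  # shift invariance and insufficient replication
  r3 <- repeatability_error(vals + 50, rep(1:1000, each = 2))
  expect_equal(r3$repeatability, r2$repeatability, tolerance = 1e-9)
  expect_error(repeatability_error(1:3, c(1, 1, 2)), "insufficient replication")
})

test_that("correlation matrix: identity diagonal, rank vs linear, copula recovery", {
  set.seed(12)
  df <- tibble::tibble(a = rnorm(100))
  df$b <- exp(2 * df$a) # exactly monotone, nonlinear
  df$c <- rnorm(100)
  sp <- correlation_matrix(df, method = "spearman")
  pe <- correlation_matrix(df, method = "pearson")
  get <- function(tbl, v1, v2) tbl$r[tbl$var1 == v1 & tbl$var2 == v2]
  expect_equal(get(sp, "a", "a"), 1)
  expect_equal(get(sp, "b", "a"), 1)
  expect_lt(get(pe, "b", "a"), 1)
  expect_true(all(c("var1", "var2", "r", "p_value", "significant") %in% names(sp)))

  # constant column -> NA, reported not raised
  df$k <- 1
  ccm <- correlation_matrix(df)
  expect_true(is.na(get(ccm, "k", "a")))

  # Gaussian-copula generated grades recover the target Spearman rho
  set.seed(77)
  x <- rnorm(500, 62.7, 4.4)
  g <- generate_correlated_grades(x, target_rho = -0.45, seed = 99)
  rho_hat <- suppressWarnings(cor.test(x, g, method = "spearman", exact = FALSE)$estimate)
  expect_lt(abs(rho_hat - (-0.45)), 0.1)
})

test_that("landmark reliability: perfect duplicates give ICC 1 and zero error", {
  g <- generate_cohort(n_subjects = 8, jitter_sd = 0, seed = 2)
  rel <- landmark_reliability(g$readings)
  expect_equal(min(rel$intraobserver$icc), 1, tolerance = 1e-9)
  expect_equal(max(rel$intraobserver$repeatability), 0, tolerance = 1e-9)
  expect_equal(min(rel$interobserver$pearson_r), 1, tolerance = 1e-9)
  expect_identical(unique(rel$interobserver$band), "very strong")

  # mismatched subject sets between observers -> pairing error
  broken <- g$readings[!(g$readings$subject_id == "S001" & g$readings$observer_id == "obs2"), ]
  expect_error(landmark_reliability(broken), "incomplete|pairing")
})

test_that("tidiers return broom-shaped tibbles", {
  rep_t <- agreement_report(bundled_confusion())
  td <- tidy(rep_t)
  expect_identical(nrow(td), 3L)
  gl <- glance(rep_t)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$agreement_percent, 88.33, tolerance = 0.01)

  y <- matrix(rnorm(20), 10, 2) + rnorm(10)
  expect_identical(nrow(tidy(icc21(y))), 1L)

  curve <- random_curve(1)
  expect_identical(nrow(tidy(curve)), 7L)
})
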