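test_that("rho angle is the analytic arctangent at the apex", {
  expect_equal(rho_angle(50, 25), atan(0.5) * 180 / pi)
  expect_equal(rho_angle(50, 25), 26.565, tolerance = 1e-3)
  expect_equal(rho_angle(80, 0), 0)
  expect_equal(rho_angle(60, 60), 45)
  expect_error(rho_angle(0, 10), "strictly right")
})

test_that("digression percentage locates the apex on the span", {
  expect_equal(digression_percentage(50, 100), 50)
  expect_equal(digression_percentage(100, 100), 100)
  expect_equal(digression_percentage(62.68, 100), 62.68)
  expect_error(digression_percentage(10, 0), "degenerate frame")
  expect_error(digression_percentage(110, 100), "outside")
})

test_that("expansion percentages match analytic integrals and conserve 100", {
  # parabola with equally spaced nodes: closed-form shares
  g <- parabola_reading(L = 100, h = 25)
  curve <- fit_lagrange(align_frame(compute_centroids(g$landmarks)))
  a <- expansion_percentages(curve)
  analytic <- 100 * c(200, 500, 650, 650, 500, 200) / 2700
  expect_equal(unname(a), analytic, tolerance = 1e-9)
  expect_equal(analytic, c(7.407, 18.519, 24.074, 24.074, 18.519, 7.407), tolerance = 1e-3)
  expect_equal(sum(a), 100, tolerance = 1e-9)

  # symmetric curve -> mirror-symmetric shares
  expect_equal(unname(a), rev(unname(a)), tolerance = 1e-9)

  # random curves: each share matches adaptive quadrature
  for (seed in 1:5) {
    curve <- random_curve(seed + 300)
    total <- integrate_curve(curve, curve$x[1], curve$x[7])
    if (abs(total) < 1e-6) next
    a <- suppressWarnings(expansion_percentages(curve))
    oracle <- vapply(1:6, function(i) {
      100 * stats::integrate(function(t) eval_curve(curve, t),
        curve$x[i], curve$x[i + 1],
        rel.tol = 1e-10
      )$value / total
    }, numeric(1))
    expect_equal(unname(a), oracle, tolerance = 1e-8)
    expect_equal(sum(a), 100, tolerance = 1e-6)
  }

  # zero curve -> no area to distribute
  zero <- fit_lagrange(list(x = 0:6, y = rep(0, 7)))
  expect_error(expansion_percentages(zero), "zero total area")
})

test_that("Cobb angle is the acute angle between the two endplate lines", {
  g <- generate_spine(spine_spec(subject_id = "C"))
  lm <- g$landmarks
  set_line <- function(lm, vert, side, slope_deg, x0 = 0, y0 = 0) {
    sel_a <- lm$vertebra == vert & lm$corner == paste0(side, "_ant")
    sel_p <- lm$vertebra == vert & lm$corner == paste0(side, "_post")
    lm$x[sel_a] <- x0; lm$y[sel_a] <- y0
    lm$x[sel_p] <- x0 + 10
    lm$y[sel_p] <- y0 + 10 * tan(slope_deg * pi / 180)
    lm
  }
  lm1 <- set_line(set_line(lm, "L1", "sup", 10, 0, 50), "L5", "inf", -20, 200, 10)
  expect_equal(cobb_angle(lm1), 30, tolerance = 1e-9)
  expect_equal(cobb_angle(lm1, signed = TRUE), 30, tolerance = 1e-9)

  lm2 <- set_line(set_line(lm, "L1", "sup", 15, 0, 50), "L5", "inf", 15, 200, 10)
  expect_equal(cobb_angle(lm2), 0, tolerance = 1e-9)

  lm3 <- set_line(set_line(lm, "L1", "sup", 45, 0, 50), "L5", "inf", -45, 200, 10)
  expect_equal(cobb_angle(lm3), 90, tolerance = 1e-9)

  bad <- lm
  bad$x[bad$vertebra == "L1" & bad$corner == "sup_post"] <-
    bad$x[bad$vertebra == "L1" & bad$corner == "sup_ant"]
  bad$y[bad$vertebra == "L1" & bad$corner == "sup_post"] <-
    bad$y[bad$vertebra == "L1" & bad$corner == "sup_ant"]
  expect_error(cobb_angle(bad), "degenerate endplate")
})

test_that("noiseless synthetic spines are recovered exactly end to end", {
  for (f in c(0.55, 0.6268, 0.70)) {
    spec <- spine_spec(apex_fraction = f, rho_deg = 9, subject_id = "X")
    g <- generate_spine(spec)
    p <- compute_lordosis(g$landmarks)
    expect_equal(p$k_percent, 100 * f, tolerance = 1e-6)
    expect_equal(p$rho_deg, g$truth$rho_deg, tolerance = 1e-9)
    expect_equal(p$cobb_deg, g$truth$cobb_deg, tolerance = 1e-6)
    expect_equal(
      unlist(p[paste0("a", 1:6)]),
      unlist(g$truth[paste0("a", 1:6)]),
      tolerance = 1e-6
    )
    expect_false(p$degenerate_apex)
  }
})

test_that("all parameters are invariant under similarity transforms", {
  g <- generate_spine(spine_spec(apex_fraction = 0.63, subject_id = "I"))
  p0 <- compute_lordosis(g$landmarks)
  vars <- c("cobb_deg", "rho_deg", "k_percent", paste0("a", 1:6))

  # rotation by 30 degrees + uniform scaling x2 + translation + reflection
  moved <- transform_landmarks(g$landmarks, angle_rad = pi / 6, dx = 120, dy = -44)
  moved <- dplyr::mutate(moved, x = 2 * x, y = 2 * y)
  p1 <- compute_lordosis(moved)
  expect_equal(unlist(p1[vars]), unlist(p0[vars]), tolerance = 1e-9)

  mirrored <- dplyr::mutate(g$landmarks, y = -y)
  p2 <- compute_lordosis(mirrored)
  expect_equal(unlist(p2[vars]), unlist(p0[vars]), tolerance = 1e-9)
})

test_that("shares sum to 100 across a cohort and K grows with the apex fraction", {
  cohort <- generate_cohort(n_subjects = 10, seed = 5)
  p <- compute_lordosis(cohort$readings)
  expect_identical(nrow(p), 40L) # 10 subjects x 2 observers x 2 sessions
  sums <- rowSums(p[, paste0("a", 1:6)])
  expect_equal(sums, rep(100, 40), tolerance = 1e-6)

  ks <- vapply(seq(0.52, 0.74, by = 0.02), function(f) {
    g <- generate_spine(spine_spec(apex_fraction = f, subject_id = "M"))
    compute_lordosis(g$landmarks)$k_percent
  }, numeric(1))
  expect_true(all(diff(ks) > 0))
})

test_that("coordinate-level averaging of repeated readings is the mean of the four", {
  cohort <- generate_cohort(n_subjects = 4, seed = 11)
  avg <- average_readings(cohort$readings)
  expect_identical(nrow(avg), 4L * 26L)
  manual <- dplyr::summarise(
    dplyr::group_by(cohort$readings, subject_id, vertebra, corner),
    x = mean(x), y = mean(y), .groups = "drop"
  )
  joined <- dplyr::inner_join(avg, manual, by = c("subject_id", "vertebra", "corner"))
  expect_equal(joined$x.x, joined$x.y)
  expect_equal(joined$y.x, joined$y.y)
})

test_that("summaries and the lower-arc expansion aggregator work on both inputs", {
  cohort <- generate_cohort(n_subjects = 6, seed = 3)
  p <- compute_lordosis(cohort$readings)
  s <- summarize_lordosis(p)
  expect_identical(s$parameter[1:3], c("cobb_deg", "rho_deg", "k_percent"))
  expect_equal(
    expansion_share(s, 4:6),
    sum(s$mean[s$parameter %in% c("a4", "a5", "a6")])
  )
  expect_equal(expansion_share(p, 1:6), 100, tolerance = 1e-6)
})
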