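# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a named substream seed from a global seed
#'
#' One global seed fans out to independent, reproducible substreams (spine
#' geometry, observer jitter, grades) so each generator stage can be rerun in
#' isolation.
#'
#' @param seed Integer global seed.
#' @param name Substream name.
#' @param index Optional extra index (e.g. subject number).
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, name, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) + 1000003 * h + 7919 * as.numeric(index)) %% 2147483647)
}

# Reflect an ascending-coefficient polynomial about x = L/2: r(x) = p(L - x).
poly_reflect <- function(coef, L) {
  n <- length(coef)
  out <- numeric(n)
  for (j in seq_len(n)) {
    jj <- j - 1 # power of p-term
    for (m in 0:jj) {
      out[m + 1] <- out[m + 1] + coef[j] * choose(jj, m) * L^(jj - m) * (-1)^m
    }
  }
  out
}

# Derivative coefficients (ascending) of an ascending-coefficient polynomial.
poly_deriv <- function(coef) {
  if (length(coef) <= 1) return(0)
  coef[-1] * seq_len(length(coef) - 1)
}

# Exact definite integral of an ascending-coefficient polynomial.
poly_integral <- function(coef, a, b) {
  anti <- coef / seq_along(coef)
  sum(anti * b^seq_along(coef)) - sum(anti * a^seq_along(coef))
}

# Fractions of the T12-sacrum span at which the seven vertebral centers sit.
# Slightly unequal, roughly proportional to lumbar vertebral body heights, so
# nothing downstream can silently rely on uniform spacing.
default_node_fractions <- function() {
  c(0, cumsum(c(0.150, 0.158, 0.165, 0.170, 0.175, 0.182)))
}

#' Specify a synthetic lordotic spine
#'
#' The midline is a polynomial of degree at most 6, positive on the open
#' span, vanishing at both ends, with a unique interior maximum at exactly
#' `apex_fraction * span`. For `apex_fraction = 0.5` this is the parabola
#' c x (L - x); otherwise a quartic whose derivative is
#' c (x_S - x)(x^2 + q) with q > 0 chosen so that p(L) = 0 — valid for apex
#' fractions in (0.25, 0.75), which covers the lumbar range.
#'
#' @param span T12-sacrum distance in pixels.
#' @param apex_fraction Apex location as a fraction of the span, in
#'   (0.25, 0.75).
#' @param apex_height Apex height in pixels; if `NULL`, derived from
#'   `rho_deg` as `tan(rho) * apex_fraction * span`.
#' @param rho_deg Target maximum-deflection angle in degrees (used only when
#'   `apex_height` is `NULL`).
#' @param node_fractions Seven increasing span fractions (first 0, last 1)
#'   placing the vertebral centers.
#' @param body_depth,body_height Vertebral body depth (along the midline
#'   tangent) and height (along the normal), in pixels.
#' @param subject_id Identifier carried into generated tables.
#' @return An object of class `spine_spec` with the midline's ascending
#'   monomial coefficients and analytic apex.
#' @export
spine_spec <- function(span = 352, apex_fraction = 0.6268, apex_height = NULL,
                       rho_deg = 7.80, node_fractions = default_node_fractions(),
                       body_depth = 70, body_height = 56, subject_id = "S01") {
  if (!(apex_fraction > 0.25 && apex_fraction < 0.75)) {
    abort("apex_fraction must lie in (0.25, 0.75) for a unique interior apex")
  }
  if (span <= 0) abort("span must be positive")
  if (length(node_fractions) != 7 || node_fractions[1] != 0 ||
    node_fractions[7] != 1 || any(diff(node_fractions) <= 0)) {
    abort("node_fractions must be 7 strictly increasing values from 0 to 1")
  }
  L <- span
  xs <- apex_fraction * L
  if (is.null(apex_height)) apex_height <- tan(rho_deg * pi / 180) * xs
  if (apex_height <= 0) abort("apex height must be positive")

  if (apex_fraction == 0.5) {
    unit <- c(0, L, -1) # x (L - x)
  } else {
    f <- apex_fraction
    mirrored <- f < 0.5
    if (mirrored) {
      f <- 1 - f
      xs_c <- f * L
    } else {
      xs_c <- xs
    }
    q <- -L^2 * (xs_c / 3 - L / 4) / (xs_c - L / 2)
    stopifnot(q > 0)
    # antiderivative of (xs_c - x)(x^2 + q): q*xs_c x - q/2 x^2 + xs_c/3 x^3 - 1/4 x^4
    unit <- c(0, q * xs_c, -q / 2, xs_c / 3, -1 / 4)
    if (mirrored) unit <- poly_reflect(unit, L)
  }
  peak <- poly_eval(unit, xs)
  coef <- unit * (apex_height / peak)

  # construction-time check: unique interior maximum at the requested apex
  d <- poly_deriv(coef)
  probe <- seq(1e-6 * L, L * (1 - 1e-6), length.out = 201)
  sgn <- sign(poly_eval(d, probe))
  if (any(sgn[probe < xs * (1 - 1e-6)] <= 0) || any(sgn[probe > xs * (1 + 1e-6)] >= 0)) {
    abort("midline construction failed: apex is not the unique interior maximum")
  }

  structure(
    list(
      span = L, apex_fraction = apex_fraction, apex_height = apex_height,
      apex_x = xs, coef = coef, node_fractions = node_fractions,
      body_depth = body_depth, body_height = body_height,
      subject_id = subject_id
    ),
    class = "spine_spec"
  )
}

fold_angle_deg <- function(d) {
  d <- ((d + 90) %% 180) - 90
  ifelse(d == -90, 90, d)
}

# Analytic ground-truth parameters of a spine_spec.
spec_truth <- function(spec) {
  nodes <- spec$node_fractions * spec$span
  t_i <- vapply(1:6, function(i) poly_integral(spec$coef, nodes[i], nodes[i + 1]), numeric(1))
  a <- 100 * t_i / sum(t_i)
  d <- poly_deriv(spec$coef)
  slope_deg <- atan(poly_eval(d, nodes)) * 180 / pi
  cobb <- abs(fold_angle_deg(slope_deg[2] - slope_deg[6]))
  tibble::tibble(
    subject_id = spec$subject_id,
    cobb_deg = cobb,
    rho_deg = atan(spec$apex_height / spec$apex_x) * 180 / pi,
    k_percent = 100 * spec$apex_fraction,
    !!!setNames(as.list(a), paste0("a", 1:6)),
    apex_x = spec$apex_x, apex_y = spec$apex_height
  )
}

#' Generate noiseless landmarks from a spine specification
#'
#' Places a rectangular vertebral body at each midline node: corners are the
#' center offset by half the body depth along the local tangent and half the
#' body height along the normal, so the corner centroid inverts the
#' construction exactly. S1 contributes only its two superior corners, whose
#' midpoint is the sacral node.
#'
#' @param spec A [spine_spec()].
#' @return A list: `landmarks` (validated tibble, observer `"truth"`, session
#'   `"1"`, y-up orientation) and `truth` (one-row tibble of the analytic
#'   parameters: `cobb_deg`, `rho_deg`, `k_percent`, `a1`..`a6`, apex).
#' @export
generate_spine <- function(spec) {
  stopifnot(inherits(spec, "spine_spec"))
  nodes <- spec$node_fractions * spec$span
  ys <- poly_eval(spec$coef, nodes)
  slopes <- poly_eval(poly_deriv(spec$coef), nodes)
  hd <- spec$body_depth / 2
  hh <- spec$body_height / 2

  rows <- purrr::map(1:7, function(i) {
    nrm <- 1 / sqrt(1 + slopes[i]^2)
    tg <- c(1, slopes[i]) * nrm
    nv <- c(-slopes[i], 1) * nrm
    ctr <- c(nodes[i], ys[i])
    if (LEVELS[i] == "S1") {
      corners <- list(
        sup_ant = ctr - hd * tg,
        sup_post = ctr + hd * tg
      )
    } else {
      corners <- list(
        sup_ant = ctr + hh * nv - hd * tg,
        sup_post = ctr + hh * nv + hd * tg,
        inf_ant = ctr - hh * nv - hd * tg,
        inf_post = ctr - hh * nv + hd * tg
      )
    }
    tibble::tibble(
      vertebra = LEVELS[i],
      corner = names(corners),
      x = unname(vapply(corners, `[`, numeric(1), 1)),
      y = unname(vapply(corners, `[`, numeric(1), 2))
    )
  })
  lm <- dplyr::bind_rows(rows)
  lm <- dplyr::mutate(lm,
    subject_id = spec$subject_id, observer_id = "truth", session_id = "1",
    .before = 1
  )
  list(landmarks = validate_landmarks(lm), truth = spec_truth(spec))
}

#' Apply a rigid transform to landmark coordinates
#'
#' Emulates an arbitrary image frame: rotates by `angle_rad` and translates.
#' All lordosis parameters are invariant to this.
#'
#' @param landmarks A landmark tibble.
#' @param angle_rad Rotation angle (radians).
#' @param dx,dy Translation (pixels).
#' @return The transformed landmark tibble.
#' @export
transform_landmarks <- function(landmarks, angle_rad = 0, dx = 0, dy = 0) {
  lm <- validate_landmarks(landmarks)
  ct <- cos(angle_rad); st <- sin(angle_rad)
  x <- ct * lm$x - st * lm$y + dx
  y <- st * lm$x + ct * lm$y + dy
  lm$x <- x; lm$y <- y
  lm
}

#' Simulate repeated observer readings of true landmarks
#'
#' Each (observer, session) reading adds independent Gaussian jitter to every
#' corner coordinate, plus an optional constant per-observer bias, emulating
#' manual corner picking by multiple observers in multiple sessions.
#'
#' @param landmarks True landmark tibble (any number of subjects).
#' @param n_observers,n_sessions Reading design (default 2 x 2).
#' @param jitter_sd Landmark jitter SD in pixels.
#' @param observer_bias_sd SD of the per-observer constant offset (pixels).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A landmark tibble with observer ids `obs1..`, session ids `s1..`.
#' @export
perturb_readings <- function(landmarks, n_observers = 2, n_sessions = 2,
                             jitter_sd = 0.5, observer_bias_sd = 0, seed = 1) {
  if (jitter_sd < 0 || observer_bias_sd < 0) abort("jitter SDs must be nonnegative")
  lm <- validate_landmarks(landmarks)
  npt <- nrow(lm)
  out <- purrr::map(seq_len(n_observers), function(o) {
    bias <- with_seed(
      substream_seed(seed, "observer_bias", o),
      rnorm(2, 0, observer_bias_sd)
    )
    purrr::map(seq_len(n_sessions), function(s) {
      jit <- with_seed(
        substream_seed(seed, "observer_jitter", o * 1000 + s),
        matrix(rnorm(2 * npt, 0, jitter_sd), ncol = 2)
      )
      dplyr::mutate(lm,
        observer_id = paste0("obs", o),
        session_id = paste0("s", s),
        x = .data$x + bias[1] + jit[, 1],
        y = .data$y + bias[2] + jit[, 2]
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  validate_landmarks(out)
}

#' Generate a synthetic cohort of lordotic spines with repeated readings
#'
#' Subject geometry is sampled around the published clinical distribution of
#' the parameters (digression percentage mean 62.68, SD 4.36; Rho angle mean
#' 7.80 deg, SD 2.97), at a typical midsagittal pixel scale, and each subject
#' is read by `n_observers` observers in `n_sessions` sessions with Gaussian
#' landmark jitter. Each subject's image frame is randomly rotated and
#' translated so raw files exercise the alignment step.
#'
#' @param n_subjects Number of subjects (default 60).
#' @inheritParams perturb_readings
#' @param span_mean,span_sd T12-sacrum span distribution (pixels).
#' @param apex_fraction_mean,apex_fraction_sd Apex-location distribution
#'   (fraction of span), truncated to (0.51, 0.74).
#' @param rho_mean,rho_sd Rho-angle distribution (degrees), truncated to
#'   (1.5, 25).
#' @param image_transform Randomly rotate/translate each subject's frame?
#' @return A list: `readings` (landmark tibble, all observers x sessions),
#'   `truth_landmarks` (noiseless, in the same image frames), `truth`
#'   (per-subject analytic parameter tibble).
#' @export
generate_cohort <- function(n_subjects = 60, n_observers = 2, n_sessions = 2,
                            jitter_sd = 0.5, observer_bias_sd = 0, seed = 1,
                            span_mean = 352, span_sd = 25,
                            apex_fraction_mean = 0.6268, apex_fraction_sd = 0.0436,
                            rho_mean = 7.80, rho_sd = 2.97,
                            image_transform = TRUE) {
  ids <- sprintf("S%03d", seq_len(n_subjects))
  draws <- with_seed(substream_seed(seed, "spine"), {
    tibble::tibble(
      span = pmax(rnorm(n_subjects, span_mean, span_sd), 100),
      f = pmin(pmax(rnorm(n_subjects, apex_fraction_mean, apex_fraction_sd), 0.51), 0.74),
      rho = pmin(pmax(rnorm(n_subjects, rho_mean, rho_sd), 1.5), 25),
      angle = if (image_transform) stats::runif(n_subjects, -0.35, 0.35) else 0,
      dx = if (image_transform) stats::runif(n_subjects, 0, 200) else 0,
      dy = if (image_transform) stats::runif(n_subjects, 0, 200) else 0
    )
  })
  spines <- purrr::map(seq_len(n_subjects), function(i) {
    sp <- spine_spec(
      span = draws$span[i], apex_fraction = draws$f[i], rho_deg = draws$rho[i],
      subject_id = ids[i]
    )
    g <- generate_spine(sp)
    g$landmarks <- transform_landmarks(
      g$landmarks,
      angle_rad = draws$angle[i], dx = draws$dx[i], dy = draws$dy[i]
    )
    g
  })
  truth_landmarks <- dplyr::bind_rows(purrr::map(spines, "landmarks"))
  truth <- dplyr::bind_rows(purrr::map(spines, "truth"))
  readings <- perturb_readings(
    truth_landmarks,
    n_observers = n_observers, n_sessions = n_sessions,
    jitter_sd = jitter_sd, observer_bias_sd = observer_bias_sd,
    seed = substream_seed(seed, "observer")
  )
  list(readings = readings, truth_landmarks = truth_landmarks, truth = truth)
}

# Default latent Pfirrmann marginals: averaged observer marginals of the
# bundled published 300-disc cross-tabulation.
default_grade_marginals <- function() c(0.020, 0.310, 0.320, 0.245, 0.105)

# Conditional distribution of a reported grade given the latent grade under
# the adjacent-misread model (probability `misread` of moving one grade up or
# down with equal odds, clipped to 1..5).
misread_kernel <- function(misread) {
  k <- matrix(0, 5, 5)
  for (g in 1:5) {
    k[g, g] <- 1 - misread
    k[g, max(g - 1, 1)] <- k[g, max(g - 1, 1)] + misread / 2
    k[g, min(g + 1, 5)] <- k[g, min(g + 1, 5)] + misread / 2
  }
  k
}

#' Analytic interobserver agreement of the misread model
#'
#' Two observers independently report a latent grade through the
#' adjacent-misread channel; the expected agreement percentage is
#' 100 sum_g pi_g sum_r P(r|g)^2.
#'
#' @param marginals Latent grade probabilities (length 5, summing to 1).
#' @param misread Adjacent-confusion probability.
#' @return Expected agreement in percent.
#' @export
analytic_agreement <- function(marginals = default_grade_marginals(), misread = 0.06) {
  stopifnot(abs(sum(marginals) - 1) < 1e-9, misread >= 0, misread <= 1)
  k <- misread_kernel(misread)
  100 * sum(marginals * rowSums(k^2))
}

#' Simulate paired Pfirrmann gradings from a latent-grade misread model
#'
#' A latent grade is drawn per disc from `marginals`; each observer reports it
#' or, with probability `misread`, an adjacent grade (clipped to 1-5),
#' independently across observers.
#'
#' @param n_discs Number of discs (a multiple of 5; 5 per subject).
#' @param marginals Latent grade probabilities (length 5, summing to 1).
#' @param misread Adjacent-confusion probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list: grade tibbles `observer1`, `observer2`, and the integer
#'   `latent` vector.
#' @export
generate_grades <- function(n_discs = 300, marginals = default_grade_marginals(),
                            misread = 0.06, seed = 1) {
  if (abs(sum(marginals) - 1) > 1e-9 || any(marginals < 0)) {
    abort("marginals must be a probability vector of length 5")
  }
  if (length(marginals) != 5) abort("marginals must have length 5")
  if (misread < 0 || misread > 1) abort("misread must be in [0, 1]")
  if (n_discs %% 5 != 0) abort("n_discs must be a multiple of 5 (5 discs per subject)")
  latent <- with_seed(
    substream_seed(seed, "grades_latent"),
    sample(1:5, n_discs, replace = TRUE, prob = marginals)
  )
  report <- function(obs_index) {
    with_seed(substream_seed(seed, "grades_report", obs_index), {
      flip <- stats::runif(n_discs) < misread
      dir <- sample(c(-1L, 1L), n_discs, replace = TRUE)
      pmin(pmax(latent + flip * dir, 1L), 5L)
    })
  }
  base <- tibble::tibble(
    subject_id = sprintf("S%03d", rep(seq_len(n_discs / 5), each = 5)),
    disc = rep(DISCS, n_discs / 5)
  )
  list(
    observer1 = validate_grades(dplyr::mutate(base, observer_id = "obs1", grade = report(1))),
    observer2 = validate_grades(dplyr::mutate(base, observer_id = "obs2", grade = report(2))),
    latent = latent
  )
}

#' Grades correlated with a continuous covariate via a Gaussian copula
#'
#' Generates one grade per element of `x` whose Spearman correlation with `x`
#' targets `target_rho`: normal scores of `x` are mixed with independent
#' Gaussian noise at the latent correlation 2 sin(pi rho / 6) and cut at the
#' marginal quantiles. Discretization into 5 grades attenuates the realized
#' correlation slightly below the target.
#'
#' @param x Continuous covariate (e.g. per-subject digression percentage).
#' @param target_rho Target Spearman correlation in (-1, 1).
#' @param marginals Grade probabilities (length 5).
#' @param seed Integer seed.
#' @return Integer grades in 1..5, same length as `x`.
#' @export
generate_correlated_grades <- function(x, target_rho = -0.45,
                                       marginals = default_grade_marginals(),
                                       seed = 1) {
  stopifnot(abs(target_rho) < 1, abs(sum(marginals) - 1) < 1e-9)
  n <- length(x)
  zx <- qnorm((rank(x, ties.method = "average") - 0.5) / n)
  r <- 2 * sin(pi * target_rho / 6)
  zg <- with_seed(
    substream_seed(seed, "copula_grades"),
    r * zx + sqrt(1 - r^2) * rnorm(n)
  )
  cuts <- cumsum(marginals)[1:4]
  as.integer(findInterval(pnorm(zg), cuts) + 1L)
}

#' Write a synthetic cohort to disk
#'
#' Emits the landmark CSV of all readings, the noiseless truth landmarks, and
#' a ground-truth parameter sidecar JSON, all in the package's standard
#' formats.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param y_axis Orientation for the landmark files.
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir, y_axis = "image_down") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    readings = file.path(dir, "landmarks.csv"),
    truth_landmarks = file.path(dir, "truth_landmarks.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_landmarks(cohort$readings, files[["readings"]], y_axis = y_axis)
  write_landmarks(cohort$truth_landmarks, files[["truth_landmarks"]], y_axis = y_axis)
  jsonlite::write_json(cohort$truth, files[["truth"]], digits = NA, dataframe = "rows")
  invisible(files)
}
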