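#' Rho angle: maximum deflection angle of the lordosis
#'
#' With the apex S = (x_S, y_S) and its projection Z = (x_S, 0) onto the
#' T12-sacrum axis, the Rho angle is the angle at the origin in the right
#' triangle P0-S-Z: atan(y_S / x_S), in degrees.
#'
#' @param apex_x,apex_y Apex coordinates in the aligned frame (`apex_x > 0`).
#' @return The Rho angle in degrees, in (-90, 90).
#' @export
rho_angle <- function(apex_x, apex_y) {
  if (any(apex_x <= 0)) abort("rho_angle() needs an apex strictly right of the T12 origin")
  atan(apex_y / apex_x) * 180 / pi
}

#' Digression percentage K%: location of the maximum deflection
#'
#' The apex abscissa as a percentage of the T12-sacrum span: K = 100 x_S / x_6.
#' K = 50 means the lordosis peaks midway; the clinically typical lumbar spine
#' peaks below the midpoint (K > 50, toward L4).
#'
#' @param apex_x Apex abscissa in the aligned frame.
#' @param x6 Sacral abscissa (span), positive.
#' @return K in percent, 0-100.
#' @export
digression_percentage <- function(apex_x, x6) {
  if (any(x6 <= 0)) abort("degenerate frame: sacral abscissa must be positive")
  if (any(apex_x < -1e-9 * x6) || any(apex_x > x6 * (1 + 1e-9))) {
    abort("apex abscissa outside the [0, x6] span")
  }
  100 * apex_x / x6
}

#' Expansion percentages A1..A6: segmental shares of the lordosis area
#'
#' A_i = 100 T_i / T where T_i is the signed area under the curve between
#' adjacent vertebral centers and T the total area over [x0, x6]. Signed
#' segment areas are kept (a curve dipping below the axis yields a negative
#' share) so the shares always sum to exactly 100.
#'
#' @param curve A `lordosis_curve` with seven nodes.
#' @return Named numeric vector `A1`..`A6`, in percent.
#' @export
expansion_percentages <- function(curve) {
  x <- curve$x
  n_seg <- length(x) - 1
  t_i <- vapply(seq_len(n_seg), function(i) integrate_curve(curve, x[i], x[i + 1]), numeric(1))
  total <- sum(t_i)
  if (abs(total) < 1e-12 * max(1, curve$s * max(abs(curve$y), 1e-300))) {
    abort("zero total area: no lordosis to distribute")
  }
  if (any(t_i < 0)) {
    warn("lordosis curve dips below the T12-sacrum axis; negative segment share kept signed")
  }
  setNames(100 * t_i / total, paste0("A", seq_len(n_seg)))
}

line_angle <- function(p, q) {
  d <- q - p
  if (sqrt(sum(d^2)) < 1e-12) abort("degenerate endplate: coincident corner landmarks")
  atan2(d[2], d[1])
}

#' Cobb angle between the L1 superior and L5 inferior endplates
#'
#' The angle between the line through L1's two superior corners and the line
#' through L5's two inferior corners. By default the acute, unsigned
#' intersection angle in [0, 90] degrees is returned (the convention of
#' magnitude-only reporting); `signed = TRUE` returns the oriented difference
#' of endplate inclinations in (-90, 90].
#'
#' @param landmarks Landmark tibble for a single reading (y-up orientation).
#' @param signed Return a signed angle?
#' @return The Cobb angle in degrees.
#' @export
cobb_angle <- function(landmarks, signed = FALSE) {
  lm <- validate_landmarks(landmarks)
  if (nrow(dplyr::distinct(lm, .data$subject_id, .data$observer_id, .data$session_id)) != 1) {
    abort("cobb_angle() expects a single reading; use compute_lordosis() for cohorts")
  }
  pick <- function(vert, corner) {
    r <- lm[lm$vertebra == vert & lm$corner == corner, ]
    unname(c(r$x, r$y))
  }
  a1 <- line_angle(pick("L1", "sup_ant"), pick("L1", "sup_post"))
  a5 <- line_angle(pick("L5", "inf_ant"), pick("L5", "inf_post"))
  d <- (a1 - a5) * 180 / pi
  # fold the line-angle difference into (-90, 90]
  d <- ((d + 90) %% 180) - 90
  if (d == -90) d <- 90
  if (signed) d else abs(d)
}

#' Compute all lordosis distribution parameters for a cohort
#'
#' Runs the full pipeline per reading: corner validation, centroids, rigid
#' alignment, degree-6 Lagrange interpolation, apex search, then Cobb angle,
#' Rho angle, digression percentage K% and expansion percentages A1..A6.
#'
#' @param landmarks A landmark tibble (one or more readings, y-up orientation;
#'   use [read_landmarks()] which normalizes orientation on input).
#' @param signed_cobb Passed to [cobb_angle()].
#' @param on_error `"stop"` (default) aborts on the first failing reading with
#'   its (subject, observer, session) context; `"skip"` drops failing readings
#'   and records them in the `skipped` attribute.
#' @return A tibble with one row per reading: the id columns, `cobb_deg`,
#'   `rho_deg`, `k_percent`, `a1`..`a6`, `apex_x`, `apex_y`,
#'   `degenerate_apex`.
#' @export
compute_lordosis <- function(landmarks, signed_cobb = FALSE,
                             on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  lm <- validate_landmarks(landmarks)
  readings <- split(lm, paste(lm$subject_id, lm$observer_id, lm$session_id, sep = "\r"))
  skipped <- list()
  rows <- purrr::map(readings, function(grp) {
    ctx <- paste0(grp$subject_id[1], "/", grp$observer_id[1], "/", grp$session_id[1])
    res <- tryCatch(
      {
        frame <- align_frame(compute_centroids(grp))
        curve <- fit_lagrange(frame)
        apex <- find_apex(curve)
        a <- suppressWarnings(expansion_percentages(curve))
        tibble::tibble(
          subject_id = grp$subject_id[1],
          observer_id = grp$observer_id[1],
          session_id = grp$session_id[1],
          cobb_deg = cobb_angle(grp, signed = signed_cobb),
          rho_deg = rho_angle(apex$x, apex$y),
          k_percent = digression_percentage(apex$x, frame$points$x[7]),
          !!!setNames(as.list(a), paste0("a", 1:6)),
          apex_x = apex$x, apex_y = apex$y,
          degenerate_apex = apex$degenerate
        )
      },
      error = function(e) {
        if (on_error == "stop") {
          abort(paste0("reading ", ctx, ": ", conditionMessage(e)))
        }
        skipped[[ctx]] <<- conditionMessage(e)
        NULL
      }
    )
    res
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out <- dplyr::arrange(out, .data$subject_id, .data$observer_id, .data$session_id)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Average repeated readings at the landmark-coordinate level
#'
#' Replicate readings (observers x sessions) of the same subject are averaged
#' coordinate-wise before any parameter computation, the stabler of the two
#' possible averaging policies (the alternative, averaging computed
#' parameters, is available by averaging the output of [compute_lordosis()]).
#'
#' @param landmarks A landmark tibble.
#' @return A landmark tibble with one reading per subject
#'   (`observer_id = session_id = "avg"`).
#' @export
average_readings <- function(landmarks) {
  lm <- validate_landmarks(landmarks)
  out <- dplyr::summarise(
    dplyr::group_by(lm, .data$subject_id, .data$vertebra, .data$corner),
    x = mean(.data$x), y = mean(.data$y), .groups = "drop"
  )
  out <- dplyr::mutate(out, observer_id = "avg", session_id = "avg")
  validate_landmarks(out)
}

#' Summarize a parameter table
#'
#' @param params Output of [compute_lordosis()].
#' @return A tibble with `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_lordosis <- function(params) {
  vars <- c("cobb_deg", "rho_deg", "k_percent", paste0("a", 1:6))
  long <- tidyr::pivot_longer(
    params[, c("subject_id", vars)],
    dplyr::all_of(vars),
    names_to = "parameter", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$parameter),
    mean = mean(.data$value), sd = stats::sd(.data$value), n = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, match(.data$parameter, vars))
}

#' Combined expansion share of a run of segments
#'
#' Sums the mean expansion percentages of the chosen segments — e.g. segments
#' 4:6 give the share of total lordosis expanded between the L3 center and
#' the sacrum (the lower arc).
#'
#' @param x Either a summary tibble with columns `parameter` and `mean` (as
#'   from [summarize_lordosis()], or a published summary table with rows
#'   `a1`..`a6`), or a raw parameter table from [compute_lordosis()].
#' @param segments Integer segment indices in 1..6.
#' @return The summed mean share, in percent.
#' @export
expansion_share <- function(x, segments = 4:6) {
  stopifnot(all(segments %in% 1:6))
  if (!("parameter" %in% names(x) && "mean" %in% names(x))) {
    x <- summarize_lordosis(x)
  }
  want <- paste0("a", segments)
  rows <- x[tolower(x$parameter) %in% want, ]
  if (nrow(rows) != length(segments)) {
    abort(paste0("summary table lacks rows for: ", paste(want, collapse = ", ")))
  }
  sum(rows$mean)
}

#' Write a parameter table to CSV
#'
#' @param params Output of [compute_lordosis()].
#' @param path Output path.
#' @export
write_parameters <- function(params, path) {
  readr::write_csv(params, path)
  invisible(path)
}
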