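#' Vertebral centroids and the sacral midpoint
#'
#' The centroid of T12 and of each lumbar vertebra is the arithmetic mean of
#' its four corner landmarks; the sacral point is the midpoint of S1's two
#' superior corners. Together they give the seven points the lordosis model
#' interpolates.
#'
#' @param landmarks A validated landmark tibble (one or more readings).
#' @return A tibble with one row per (reading, vertebra): `subject_id`,
#'   `observer_id`, `session_id`, `vertebra`, `x`, `y`.
#' @export
compute_centroids <- function(landmarks) {
  lm <- validate_landmarks(landmarks)
  out <- dplyr::summarise(
    dplyr::group_by(
      lm,
      .data$subject_id, .data$observer_id, .data$session_id, .data$vertebra
    ),
    x = mean(.data$x), y = mean(.data$y), .groups = "drop"
  )
  dplyr::arrange(
    out,
    .data$subject_id, .data$observer_id, .data$session_id,
    match(.data$vertebra, LEVELS)
  )
}

#' Align seven spine points to the standard frame
#'
#' Applies a rigid transform (translation + rotation, optionally a reflection,
#' never a scaling) that puts the T12 centroid at the origin and the sacral
#' point on the positive x axis; the reflection is chosen so the lumbar
#' centroids lie above the axis (mean of y1..y5 nonnegative). Angles and
#' percentages downstream are invariant to this choice, but preserving pixel
#' scale keeps measurement-error statistics interpretable.
#'
#' @param points A 7-row tibble with columns `vertebra`, `x`, `y` (one
#'   reading's centroids, any order).
#' @return An object of class `spine_frame`: `points` (7-row tibble ordered
#'   T12..S1 with `x[1] = y[1] = 0` and `y[7] = 0` exactly) and `transform`
#'   (list with `angle_rad`, `origin`, `reflected`).
#' @export
align_frame <- function(points) {
  pts <- tibble::as_tibble(points)
  if (!all(c("vertebra", "x", "y") %in% names(pts)) || nrow(pts) != 7) {
    abort("align_frame() expects a 7-row tibble with columns vertebra, x, y")
  }
  pts <- pts[match(LEVELS, pts$vertebra), ]
  if (anyNA(pts$vertebra)) abort("align_frame() needs one point per level T12..S1")

  p0 <- c(pts$x[1], pts$y[1])
  p6 <- c(pts$x[7], pts$y[7])
  chord <- p6 - p0
  len <- sqrt(sum(chord^2))
  if (len < 1e-12) abort("degenerate frame: T12 centroid coincides with the sacral point")

  theta <- atan2(chord[2], chord[1])
  ct <- cos(-theta); st <- sin(-theta)
  xr <- ct * (pts$x - p0[1]) - st * (pts$y - p0[2])
  yr <- st * (pts$x - p0[1]) + ct * (pts$y - p0[2])

  reflected <- mean(yr[2:6]) < 0
  if (reflected) yr <- -yr

  # chord endpoints are exact by construction
  xr[1] <- 0; yr[1] <- 0; yr[7] <- 0

  if (any(diff(xr) <= 0)) {
    abort("vertebral centers not x-ordered after alignment (deformity outside the model's domain)")
  }

  structure(
    list(
      points = tibble::tibble(vertebra = LEVELS, x = xr, y = yr),
      transform = list(angle_rad = -theta, origin = p0, reflected = reflected)
    ),
    class = "spine_frame"
  )
}

#' @export
print.spine_frame <- function(x, ...) {
  cat("Aligned spine frame (T12 at origin, sacrum on x-axis)\n")
  print(x$points)
  invisible(x)
}

# Barycentric weights for nodes u (scale-invariant up to a common factor).
bary_weights <- function(u) {
  vapply(seq_along(u), function(i) 1 / prod(u[i] - u[-i]), numeric(1))
}

# Monomial coefficients (ascending powers) of the interpolant on rescaled
# nodes u in [0, 1], via the Vandermonde system; 7 nodes on [0, 1] are well
# conditioned enough for exact calculus.
monomial_coef <- function(u, y) {
  v <- outer(u, 0:(length(u) - 1), "^")
  as.numeric(solve(v, y))
}

#' Fit the degree-6 Lagrange interpolant through the aligned spine points
#'
#' The unique polynomial of degree at most 6 through the seven aligned points
#' models the lordosis curve. Evaluation uses the numerically stable
#' barycentric form; calculus (derivative roots for the apex, definite
#' integrals for the expansion percentages) uses monomial coefficients on the
#' rescaled abscissa u = (x - x0)/(x6 - x0).
#'
#' @param frame A `spine_frame`, or any list/tibble with numeric fields `x`
#'   and `y` of equal length (at least 2, strictly increasing x).
#' @return An object of class `lordosis_curve` with fields `x`, `y` (nodes),
#'   `w` (barycentric weights on u), `coef_u` (monomial coefficients on u),
#'   `a` (= x0) and `s` (= x6 - x0).
#' @export
fit_lagrange <- function(frame) {
  if (inherits(frame, "spine_frame")) {
    x <- frame$points$x; y <- frame$points$y
  } else {
    x <- frame$x; y <- frame$y
  }
  if (length(x) < 2 || length(x) != length(y)) {
    abort("fit_lagrange() needs matching x and y of length >= 2")
  }
  if (any(diff(x) <= 0)) abort("singular interpolation: nodes must be strictly increasing")
  a <- x[1]; s <- x[length(x)] - x[1]
  u <- (x - a) / s
  structure(
    list(x = x, y = y, u = u, w = bary_weights(u), coef_u = monomial_coef(u, y), a = a, s = s),
    class = "lordosis_curve"
  )
}

#' @export
print.lordosis_curve <- function(x, ...) {
  cat("Lordosis curve: degree-", length(x$x) - 1, " Lagrange interpolant on [",
    format(x$x[1]), ", ", format(x$x[length(x$x)]), "]\n",
    sep = ""
  )
  invisible(x)
}

#' Evaluate the interpolant
#'
#' @param curve A `lordosis_curve`.
#' @param xout Abscissae at which to evaluate.
#' @return `p(xout)`, via the barycentric formula (exact at the nodes).
#' @export
eval_curve <- function(curve, xout) {
  u <- (xout - curve$a) / curve$s
  vapply(u, function(ui) {
    d <- ui - curve$u
    hit <- which(d == 0)
    if (length(hit) > 0) return(curve$y[hit[1]])
    q <- curve$w / d
    sum(q * curve$y) / sum(q)
  }, numeric(1))
}

#' Lagrange basis functions
#'
#' Returns the matrix of cardinal basis values L_i(x): L_i is 1 at node i and
#' 0 at the others, and the basis sums to 1 at every abscissa.
#'
#' @inheritParams eval_curve
#' @return A `length(xout)` x `n_nodes` matrix.
#' @export
lagrange_basis <- function(curve, xout) {
  u <- (xout - curve$a) / curve$s
  t(vapply(u, function(ui) {
    d <- ui - curve$u
    hit <- which(d == 0)
    if (length(hit) > 0) {
      e <- numeric(length(curve$u)); e[hit[1]] <- 1
      return(e)
    }
    q <- curve$w / d
    q / sum(q)
  }, numeric(length(curve$u))))
}

# Evaluate a polynomial given ascending coefficients (Horner).
poly_eval <- function(coef, x) {
  out <- rep(0, length(x))
  for (c_j in rev(coef)) out <- out * x + c_j
  out
}

#' Monomial coefficients on the original x scale
#'
#' @param object A `lordosis_curve`.
#' @param ... Unused.
#' @return Ascending-power coefficients of p(x).
#' @export
coef.lordosis_curve <- function(object, ...) {
  # expand sum_j c_j ((x - a)/s)^j by accumulating powers of (x - a)/s
  n <- length(object$coef_u)
  base <- c(-object$a / object$s, 1 / object$s)
  acc <- 1
  out <- numeric(n)
  for (j in seq_len(n)) {
    cj <- object$coef_u[j]
    out[seq_along(acc)] <- out[seq_along(acc)] + cj * acc
    if (j < n) {
      # acc <- acc * base
      new <- numeric(length(acc) + 1)
      new[seq_along(acc)] <- new[seq_along(acc)] + acc * base[1]
      new[seq_along(acc) + 1] <- new[seq_along(acc) + 1] + acc * base[2]
      acc <- new
    }
  }
  out
}

#' Locate the apex (maximum deflection) of the lordosis curve
#'
#' Finds the global maximum of p on [x0, x6] from the real roots of p' inside
#' the interval plus the two endpoints. Ties are broken toward the smallest
#' abscissa; an endpoint argmax is flagged degenerate rather than raised, so
#' cohort pipelines can log and skip such readings.
#'
#' @param curve A `lordosis_curve`.
#' @return A list with `x`, `y` (the apex S) and logical `degenerate`.
#' @export
find_apex <- function(curve) {
  dcoef <- curve$coef_u[-1] * seq_len(length(curve$coef_u) - 1)
  cand_u <- c(0, 1)
  nz <- which(dcoef != 0)
  if (length(nz) > 0) {
    dcoef <- dcoef[seq_len(max(nz))] # strip trailing zeros before polyroot
    if (length(dcoef) >= 2) {
      rts <- polyroot(dcoef)
      real <- Re(rts)[abs(Im(rts)) < 1e-9 * pmax(1, Mod(rts))]
      real <- real[real > 0 & real < 1]
      if (length(real) > 0) {
        # polish roots of p' with two Newton steps
        d2 <- dcoef[-1] * seq_len(length(dcoef) - 1)
        for (it in 1:2) {
          g <- poly_eval(dcoef, real)
          h <- poly_eval(d2, real)
          step <- ifelse(h != 0, g / h, 0)
          real <- pmin(pmax(real - step, 0), 1)
        }
        cand_u <- c(cand_u, real[real > 0 & real < 1])
      }
    }
  }
  cand_u <- sort(unique(cand_u))
  cand_x <- curve$a + cand_u * curve$s
  vals <- eval_curve(curve, cand_x)
  i <- which.max(vals) # first occurrence = smallest x on ties
  degenerate <- cand_u[i] <= 0 || cand_u[i] >= 1
  list(x = cand_x[i], y = vals[i], degenerate = degenerate)
}

#' Exact definite integral of the lordosis curve
#'
#' Integrates the monomial form analytically; no quadrature error.
#'
#' @param curve A `lordosis_curve`.
#' @param a,b Integration bounds, inside the curve's node interval.
#' @return The signed area under p between `a` and `b`.
#' @export
integrate_curve <- function(curve, a, b) {
  lo <- curve$a; hi <- curve$a + curve$s
  tol <- 1e-9 * curve$s
  if (a < lo - tol || b > hi + tol || a > b + tol) {
    abort("integration bounds must satisfy x0 <= a <= b <= x6")
  }
  n <- length(curve$coef_u)
  anti <- curve$coef_u / seq_len(n) # coefficients of the antiderivative in u (u^1..u^n)
  ua <- (a - curve$a) / curve$s
  ub <- (b - curve$a) / curve$s
  F_of <- function(u) sum(anti * u^seq_len(n))
  curve$s * (F_of(ub) - F_of(ua))
}
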