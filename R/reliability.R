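#' Agreement percentage of a confusion matrix
#'
#' @param cm A `lordist_confusion`.
#' @return 100 x trace / n, in percent.
#' @export
agreement_percentage <- function(cm) {
  stopifnot(inherits(cm, "lordist_confusion"))
  if (cm$n_total == 0) abort("empty confusion matrix")
  100 * sum(diag(cm$counts)) / cm$n_total
}

#' Landis-Koch agreement band for a kappa value
#'
#' @param kappa Kappa value(s).
#' @return Character label: slight / fair / moderate / substantial / excellent
#'   agreement (negative kappa is labelled "poor agreement").
#' @export
landis_koch <- function(kappa) {
  cut(kappa,
    breaks = c(-Inf, 0, 0.20, 0.40, 0.60, 0.80, Inf),
    labels = c(
      "poor agreement", "slight agreement", "fair agreement",
      "moderate agreement", "substantial agreement", "excellent agreement"
    ),
    right = TRUE
  ) |> as.character()
}

#' Winer band for an intraclass correlation
#'
#' @param icc ICC value(s).
#' @return Character label: weak / low / average / good / excellent.
#' @export
winer_band <- function(icc) {
  cut(icc,
    breaks = c(-Inf, 0.25, 0.50, 0.70, 0.90, Inf),
    labels = c("weak", "low", "average", "good", "excellent"),
    right = FALSE
  ) |> as.character()
}

#' Evans band for the magnitude of a correlation coefficient
#'
#' @param r Correlation value(s); the band is on |r|.
#' @return Character label: very weak / weaker / significant / strong /
#'   very strong.
#' @export
evans_band <- function(r) {
  cut(abs(r),
    breaks = c(-Inf, 0.20, 0.40, 0.60, 0.80, Inf),
    labels = c("very weak", "weaker", "significant", "strong", "very strong"),
    right = FALSE
  ) |> as.character()
}

kappa_core <- function(cm, weights_matrix) {
  p <- cm$counts / cm$n_total
  r <- rowSums(p); cc <- colSums(p)
  po <- sum(weights_matrix * p)
  pe <- sum(weights_matrix * outer(r, cc))
  if (abs(1 - pe) < 1e-12) abort("undefined kappa: expected agreement is 1 (degenerate marginals)")
  list(kappa = (po - pe) / (1 - pe), po = po, pe = pe)
}

#' Cohen's kappa with standard error and confidence interval
#'
#' Chance-corrected agreement kappa = (Po - Pe)/(1 - Pe) with Pe from the
#' product of the row and column marginals. The default standard error is the
#' simple asymptotic form sqrt(Po (1 - Po) / (n (1 - Pe)^2)); the
#' Fleiss-Cohen-Everitt large-sample variance is available via
#' `se = "fleiss"`. The confidence interval is kappa +/- z * SE.
#'
#' @param cm A `lordist_confusion`.
#' @param conf_level Confidence level (default 0.95, i.e. z = 1.96).
#' @param se Standard-error formula.
#' @return An object of class `lordist_kappa`: `kappa`, `se`, `ci` (length-2),
#'   `po`, `pe`, `n`, `label` (Landis-Koch band).
#' @export
cohen_kappa <- function(cm, conf_level = 0.95, se = c("asymptotic", "fleiss")) {
  stopifnot(inherits(cm, "lordist_confusion"))
  se <- match.arg(se)
  if (cm$n_total == 0) abort("empty confusion matrix")
  k <- nrow(cm$counts)
  core <- kappa_core(cm, diag(k))
  kap <- core$kappa; po <- core$po; pe <- core$pe
  n <- cm$n_total
  if (se == "asymptotic") {
    se_hat <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  } else {
    p <- cm$counts / n
    ri <- rowSums(p); cj <- colSums(p)
    t1 <- sum(diag(p) * (1 - (ri + cj) * (1 - kap))^2)
    # off-diagonal cell (i, j) weighted by (col marginal of i + row marginal of j)^2
    wmat <- outer(cj, ri, "+")^2
    off <- (1 - kap)^2 * sum((p * wmat)[row(p) != col(p)])
    t3 <- (kap - pe * (1 - kap))^2
    se_hat <- sqrt((t1 + off - t3) / (n * (1 - pe)^2))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      kappa = kap, se = se_hat,
      ci = c(kap - z * se_hat, kap + z * se_hat),
      po = po, pe = pe, n = n, weights = "none",
      label = landis_koch(kap)
    ),
    class = "lordist_kappa"
  )
}

#' @export
print.lordist_kappa <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa%s = %.3f (SE %.3f, 95%% CI %.3f-%.3f): %s\n",
    if (x$weights == "none") "" else paste0(" (", x$weights, " weights)"),
    x$kappa, x$se, x$ci[1], x$ci[2], x$label
  ))
  invisible(x)
}

#' Weighted kappa
#'
#' Weighted agreement with weights w_ij = 1 - |i - j|/(k - 1) (linear,
#' default) or w_ij = 1 - (i - j)^2/(k - 1)^2 (quadratic). With k = 2
#' categories the linear weights reduce to the identity, so the linear
#' weighted kappa equals the unweighted kappa.
#'
#' @param cm A `lordist_confusion`.
#' @param weights Weighting scheme.
#' @return The weighted kappa (numeric scalar).
#' @export
weighted_kappa <- function(cm, weights = c("linear", "quadratic")) {
  stopifnot(inherits(cm, "lordist_confusion"))
  weights <- match.arg(weights)
  if (cm$n_total == 0) abort("empty confusion matrix")
  k <- nrow(cm$counts)
  d <- abs(row(cm$counts) - col(cm$counts))
  w <- if (weights == "linear") 1 - d / (k - 1) else 1 - d^2 / (k - 1)^2
  kappa_core(cm, w)$kappa
}

#' Full interobserver agreement report
#'
#' Bundles the agreement percentage, Cohen's kappa (with SE and CI), the
#' weighted kappa and the Landis-Koch agreement category for a paired-grading
#' confusion matrix.
#'
#' @inheritParams cohen_kappa
#' @param weights Scheme for the weighted kappa.
#' @return An object of class `lordist_agreement`.
#' @export
agreement_report <- function(cm, weights = c("linear", "quadratic"), conf_level = 0.95) {
  weights <- match.arg(weights)
  kap <- cohen_kappa(cm, conf_level = conf_level)
  structure(
    list(
      agreement_percent = agreement_percentage(cm),
      kappa = kap$kappa, kappa_se = kap$se, kappa_ci = kap$ci,
      weighted_kappa = weighted_kappa(cm, weights),
      weights = weights, n = cm$n_total, label = kap$label,
      conf_level = conf_level
    ),
    class = "lordist_agreement"
  )
}

#' @export
print.lordist_agreement <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Interobserver agreement over %d paired gradings\n",
      "  agreement percentage: %.2f%%\n",
      "  Cohen's kappa: %.3f (SE %.3f, %d%% CI %.3f-%.3f)\n",
      "  weighted kappa (%s): %.3f\n  category: %s\n"
    ),
    x$n, x$agreement_percent, x$kappa, x$kappa_se,
    round(100 * x$conf_level), x$kappa_ci[1], x$kappa_ci[2],
    x$weights, x$weighted_kappa, x$label
  ))
  invisible(x)
}

as_ratings_matrix <- function(ratings) {
  if (is.data.frame(ratings)) ratings <- as.matrix(ratings)
  if (!is.matrix(ratings) || !is.numeric(ratings)) {
    abort("ratings must be a numeric subjects x raters matrix")
  }
  if (anyNA(ratings)) abort("ICC needs a complete grid: missing ratings found")
  if (nrow(ratings) < 2 || ncol(ratings) < 2) {
    abort("ICC needs at least 2 subjects and 2 ratings")
  }
  ratings
}

#' ICC(2,1): single-measurement absolute-agreement intraclass correlation
#'
#' Two-way random-effects ANOVA decomposition (subjects and raters both
#' random), single rater, absolute agreement:
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).
#' The confidence interval is the F-based interval with Satterthwaite degrees
#' of freedom.
#'
#' @param ratings Numeric subjects x raters matrix (or data frame), complete.
#' @param conf_level Confidence level for the interval.
#' @return An object of class `lordist_icc`: `icc`, `ci`, `label` (Winer
#'   band), mean squares `msr`, `msc`, `mse`, and `n`, `k`.
#' @export
icc21 <- function(ratings, conf_level = 0.95) {
  y <- as_ratings_matrix(ratings)
  n <- nrow(y); k <- ncol(y)
  gm <- mean(y)
  rm_ <- rowMeans(y); cm_ <- colMeans(y)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm_ - gm)^2) / (k - 1)
  resid <- y - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + gm
  mse <- sum(resid^2) / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom) < 1e-300) abort("undefined ICC: no variance in the ratings")
  icc <- (msr - mse) / denom

  alpha <- 1 - conf_level
  if (mse == 0 && msc == msr) {
    ci <- c(1, 1)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lo, hi)
  }
  structure(
    list(
      icc = icc, ci = ci, conf_level = conf_level,
      label = winer_band(icc), msr = msr, msc = msc, mse = mse, n = n, k = k
    ),
    class = "lordist_icc"
  )
}

#' @export
print.lordist_icc <- function(x, ...) {
  cat(sprintf(
    "ICC(2,1) = %.4f (%d%% CI %.4f-%.4f): %s  [n = %d subjects, k = %d ratings]\n",
    x$icc, round(100 * x$conf_level), x$ci[1], x$ci[2], x$label, x$n, x$k
  ))
  invisible(x)
}

#' Repeatability: 2.77 times the within-subject standard deviation
#'
#' The within-subject variance is the one-way ANOVA within-subject mean
#' square; 2.77 s_w is the expected upper bound (95%) on the absolute
#' difference between two repeated measurements of the same subject.
#'
#' @param values Numeric vector of repeated measurements.
#' @param subject Subject identifier parallel to `values` (>= 2 readings per
#'   subject).
#' @return A one-row tibble: `s_w`, `repeatability`, `n_subjects`,
#'   `n_readings`.
#' @export
repeatability_error <- function(values, subject) {
  if (length(values) != length(subject)) abort("values and subject must have equal length")
  groups <- split(values, subject)
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    abort("insufficient replication: every subject needs at least 2 readings")
  }
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_w <- sum(sizes - 1)
  s_w <- sqrt(ss_w / df_w)
  tibble::tibble(
    s_w = s_w, repeatability = 2.77 * s_w,
    n_subjects = length(groups), n_readings = length(values)
  )
}

#' Pairwise correlation matrix in long lower-triangle form
#'
#' Correlates every pair of numeric columns (Spearman by default, the
#' appropriate choice when normality fails), returning the lower triangle
#' including the unit diagonal, with two-sided p values and a significance
#' flag. Constant columns yield NA correlations for their pairs (reported,
#' not raised).
#'
#' @param data A data frame of numeric columns (non-numeric columns dropped).
#' @param method `"spearman"` or `"pearson"`.
#' @param alpha Significance level for the flag (default 0.05, two-sided).
#' @return A tibble: `var1`, `var2`, `r`, `p_value`, `significant`, with
#'   attribute `method`.
#' @export
correlation_matrix <- function(data, method = c("spearman", "pearson"), alpha = 0.05) {
  method <- match.arg(method)
  if (!(alpha > 0 && alpha < 1)) abort("significance level must be in (0, 1)")
  num <- dplyr::select(tibble::as_tibble(data), dplyr::where(is.numeric))
  vars <- names(num)
  if (length(vars) < 2) abort("correlation_matrix() needs at least two numeric columns")
  pairs <- tidyr::expand_grid(i = seq_along(vars), j = seq_along(vars))
  pairs <- pairs[pairs$i >= pairs$j, ]
  rows <- purrr::pmap(pairs, function(i, j) {
    if (i == j) {
      constant <- stats::sd(num[[i]]) == 0
      return(tibble::tibble(
        var1 = vars[i], var2 = vars[j],
        r = if (constant) NA_real_ else 1, p_value = NA_real_, significant = NA
      ))
    }
    x <- num[[i]]; y <- num[[j]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(
        var1 = vars[i], var2 = vars[j],
        r = NA_real_, p_value = NA_real_, significant = NA
      ))
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method, exact = FALSE))
    tibble::tibble(
      var1 = vars[i], var2 = vars[j],
      r = unname(ct$estimate), p_value = ct$p.value,
      significant = ct$p.value < alpha
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  out
}

#' Landmark-coordinate reliability analysis
#'
#' Treats each landmark coordinate (vertebra x corner x axis) as one measured
#' quantity and evaluates, per coordinate: intraobserver ICC(2,1) across
#' sessions (per observer) with its repeatability, and the interobserver
#' Pearson r between the two observers' session-averaged values.
#'
#' @param landmarks A landmark tibble with >= 2 sessions per observer (for
#'   ICC/repeatability) and exactly 2 observers (for Pearson r).
#' @param conf_level Confidence level for ICC intervals.
#' @return An object of class `landmark_reliability`: tibbles `intraobserver`
#'   (icc, ci, Winer label, repeatability per observer x coordinate),
#'   `interobserver` (Pearson r + Evans label per coordinate), and a one-row
#'   `summary` (mean/min ICC and r).
#' @export
landmark_reliability <- function(landmarks, conf_level = 0.95) {
  lm <- validate_landmarks(landmarks)
  long <- tidyr::pivot_longer(lm, c("x", "y"), names_to = "axis", values_to = "value")
  observers <- sort(unique(long$observer_id))
  sessions <- sort(unique(long$session_id))
  if (length(sessions) < 2 && length(observers) < 2) {
    abort("insufficient replication: need >= 2 sessions per observer or >= 2 observers")
  }

  coord_groups <- dplyr::group_split(
    dplyr::group_by(long, .data$vertebra, .data$corner, .data$axis)
  )

  intra <- purrr::map(coord_groups, function(g) {
    purrr::map(observers, function(obs) {
      go <- g[g$observer_id == obs, ]
      if (length(unique(go$session_id)) < 2) return(NULL)
      wide <- tidyr::pivot_wider(
        go[, c("subject_id", "session_id", "value")],
        names_from = "session_id", values_from = "value"
      )
      mat <- as.matrix(wide[, -1])
      fit <- icc21(mat, conf_level = conf_level)
      rep_ <- repeatability_error(go$value, go$subject_id)
      tibble::tibble(
        vertebra = g$vertebra[1], corner = g$corner[1], axis = g$axis[1],
        observer_id = obs,
        icc = fit$icc, icc_lower = fit$ci[1], icc_upper = fit$ci[2],
        icc_label = fit$label,
        s_w = rep_$s_w, repeatability = rep_$repeatability
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  inter <- NULL
  if (length(observers) == 2) {
    inter <- purrr::map(coord_groups, function(g) {
      means <- dplyr::summarise(
        dplyr::group_by(g, .data$subject_id, .data$observer_id),
        value = mean(.data$value), .groups = "drop"
      )
      wide <- tidyr::pivot_wider(means, names_from = "observer_id", values_from = "value")
      if (anyNA(wide)) abort("pairing error: subject sets differ between observers")
      r <- stats::cor(wide[[observers[1]]], wide[[observers[2]]])
      tibble::tibble(
        vertebra = g$vertebra[1], corner = g$corner[1], axis = g$axis[1],
        pearson_r = r, band = evans_band(r)
      )
    }) |> dplyr::bind_rows()
  }

  summary <- tibble::tibble(
    mean_icc = mean(intra$icc), min_icc = min(intra$icc),
    mean_repeatability = mean(intra$repeatability),
    mean_pearson_r = if (is.null(inter)) NA_real_ else mean(inter$pearson_r),
    min_pearson_r = if (is.null(inter)) NA_real_ else min(inter$pearson_r),
    n_coordinates = nrow(intra) / max(1, length(unique(intra$observer_id)))
  )

  structure(
    list(intraobserver = intra, interobserver = inter, summary = summary),
    class = "landmark_reliability"
  )
}

#' @export
print.landmark_reliability <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Landmark reliability over %d coordinates\n  intraobserver ICC(2,1): mean %.4f, min %.4f\n",
    s$n_coordinates, s$mean_icc, s$min_icc
  ))
  if (!is.na(s$mean_pearson_r)) {
    cat(sprintf(
      "  interobserver Pearson r: mean %.4f, min %.4f\n",
      s$mean_pearson_r, s$min_pearson_r
    ))
  }
  cat(sprintf("  mean repeatability (2.77 s_w): %.4f px\n", s$mean_repeatability))
  invisible(x)
}
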