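#' Expected corner labels for one complete reading
#'
#' A complete reading digitizes the four corners of T12 and L1-L5 plus the two
#' superior corners of S1: 26 points in total.
#'
#' @return A tibble with columns `vertebra` and `corner`, one row per expected
#'   landmark (26 rows), in canonical order.
#' @export
landmark_schema <- function() {
  body <- tidyr::expand_grid(
    vertebra = setdiff(LEVELS, "S1"),
    corner = BODY_CORNERS
  )
  s1 <- tibble::tibble(vertebra = "S1", corner = S1_CORNERS)
  out <- dplyr::bind_rows(body, s1)
  dplyr::arrange(out, match(.data$vertebra, LEVELS), match(.data$corner, BODY_CORNERS))
}

reading_id_cols <- c("subject_id", "observer_id", "session_id")

#' Validate a landmark table
#'
#' Checks the long landmark table against the data model: required columns,
#' finite numeric coordinates, known vertebra/corner labels, no duplicate
#' (reading, vertebra, corner) keys, and a complete 26-point set per reading.
#'
#' @param landmarks A data frame with columns `subject_id`, `observer_id`,
#'   `session_id`, `vertebra`, `corner`, `x`, `y`.
#' @return The validated table as a tibble, invisibly ordered canonically.
#' @export
validate_landmarks <- function(landmarks) {
  required <- c(reading_id_cols, "vertebra", "corner", "x", "y")
  missing_cols <- setdiff(required, names(landmarks))
  if (length(missing_cols) > 0) {
    abort(paste0("landmark table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  lm <- tibble::as_tibble(landmarks)
  lm <- dplyr::mutate(lm, dplyr::across(dplyr::all_of(reading_id_cols), as.character))

  bad_num <- !is.numeric(lm$x) || !is.numeric(lm$y)
  if (bad_num) {
    abort("landmark coordinates must be numeric; got non-numeric x or y column")
  }
  nonfinite <- which(!is.finite(lm$x) | !is.finite(lm$y))
  if (length(nonfinite) > 0) {
    abort(paste0(
      "non-finite landmark coordinate at row(s): ",
      paste(head(nonfinite, 5), collapse = ", ")
    ))
  }

  bad_vert <- setdiff(unique(lm$vertebra), LEVELS)
  if (length(bad_vert) > 0) {
    abort(paste0("unknown vertebra label(s): ", paste(bad_vert, collapse = ", ")))
  }
  bad_corner <- setdiff(unique(lm$corner), BODY_CORNERS)
  if (length(bad_corner) > 0) {
    abort(paste0("unknown corner label(s): ", paste(bad_corner, collapse = ", ")))
  }

  key <- paste(lm$subject_id, lm$observer_id, lm$session_id, lm$vertebra, lm$corner)
  dup <- duplicated(key)
  if (any(dup)) {
    abort(paste0(
      "duplicate landmark record(s): ",
      paste(head(unique(key[dup]), 3), collapse = "; ")
    ))
  }

  schema <- landmark_schema()
  schema_key <- paste(schema$vertebra, schema$corner)
  for (grp in split(lm, paste(lm$subject_id, lm$observer_id, lm$session_id, sep = "/"))) {
    have <- paste(grp$vertebra, grp$corner)
    lack <- setdiff(schema_key, have)
    if (length(lack) > 0) {
      abort(paste0(
        "incomplete landmark set: ", gsub(" ", "/", lack[1]),
        " (reading ", grp$subject_id[1], "/", grp$observer_id[1], "/", grp$session_id[1], ")"
      ))
    }
    extra <- setdiff(have, schema_key)
    if (length(extra) > 0) {
      abort(paste0("unexpected landmark: ", gsub(" ", "/", extra[1])))
    }
  }

  lm <- dplyr::arrange(
    lm,
    .data$subject_id, .data$observer_id, .data$session_id,
    match(.data$vertebra, LEVELS), match(.data$corner, BODY_CORNERS)
  )
  invisible(lm)
}

#' Read a landmark file
#'
#' Reads vertebral-corner landmarks from CSV (columns `subject_id`,
#' `observer_id`, `session_id`, `vertebra`, `corner`, `x`, `y`) or the
#' equivalent JSON shape (array of reading objects, each with the id fields
#' and a `corners` array). Coordinates are pixel positions.
#'
#' Image viewers use a downward-pointing y axis while the lordosis model uses
#' an upward one; with `y_axis = "image_down"` (the default, the screen
#' convention) y is negated on input so that all downstream geometry works in
#' mathematical orientation.
#'
#' @param path Path to the landmark file.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @param y_axis Orientation of the y axis in the file: `"image_down"` or
#'   `"math_up"`.
#' @return A validated landmark tibble in mathematical (y-up) orientation.
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json"),
                           y_axis = c("image_down", "math_up")) {
  format <- match.arg(format)
  y_axis <- match.arg(y_axis)
  if (!file.exists(path)) abort(paste0("landmark file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    # coordinates are read as strings and parsed with R's correctly rounded
    # strtod so that full-precision files round trip bit-exactly
    lm <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  } else {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    lm <- tidyr::unnest(
      tibble::as_tibble(raw),
      dplyr::all_of("corners")
    )
  }
  for (col in intersect(c("x", "y"), names(lm))) {
    v <- suppressWarnings(as.numeric(lm[[col]]))
    bad <- which(is.na(v) & !is.na(lm[[col]]))
    if (length(bad) > 0) {
      abort(paste0(
        "landmark parse error at row ", bad[1], ": non-numeric ", col,
        " value '", lm[[col]][bad[1]], "'"
      ))
    }
    lm[[col]] <- v
  }
  if (y_axis == "image_down") lm$y <- -lm$y
  validate_landmarks(lm)
}

#' Write a landmark file
#'
#' Inverse of [read_landmarks()]: writes the table in deterministic order,
#' flipping y back to image orientation when `y_axis = "image_down"`.
#' A write/read round trip preserves coordinates exactly.
#'
#' @param landmarks A landmark tibble in mathematical (y-up) orientation.
#' @param path Output path.
#' @inheritParams read_landmarks
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, format = c("auto", "csv", "json"),
                            y_axis = c("image_down", "math_up")) {
  format <- match.arg(format)
  y_axis <- match.arg(y_axis)
  lm <- validate_landmarks(landmarks)
  if (y_axis == "image_down") lm$y <- -lm$y
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  # serialize coordinates as 17-significant-digit decimal strings so a
  # write -> read round trip reproduces every double bit-exactly
  out <- lm[, c(reading_id_cols, "vertebra", "corner", "x", "y")]
  out$x <- sprintf("%.17g", out$x)
  out$y <- sprintf("%.17g", out$y)
  if (format == "csv") {
    readr::write_csv(out, path)
  } else {
    nested <- tidyr::nest(out, corners = c("vertebra", "corner", "x", "y"))
    jsonlite::write_json(nested, path, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Validate a Pfirrmann grade table
#'
#' @param grades Data frame with columns `subject_id`, `observer_id`, `disc`,
#'   `grade`; every grade in 1-5 and all five lumbar discs present per
#'   (subject, observer).
#' @return The validated tibble, invisibly.
#' @export
validate_grades <- function(grades) {
  required <- c("subject_id", "observer_id", "disc", "grade")
  missing_cols <- setdiff(required, names(grades))
  if (length(missing_cols) > 0) {
    abort(paste0("grade table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  g <- tibble::as_tibble(grades)
  g <- dplyr::mutate(
    g,
    subject_id = as.character(.data$subject_id),
    observer_id = as.character(.data$observer_id)
  )
  bad_disc <- setdiff(unique(g$disc), DISCS)
  if (length(bad_disc) > 0) {
    abort(paste0("unknown disc label(s): ", paste(bad_disc, collapse = ", ")))
  }
  if (!all(g$grade %in% PFIRRMANN_GRADES)) {
    abort("Pfirrmann grades must be integers in 1..5")
  }
  key <- paste(g$subject_id, g$observer_id, g$disc)
  if (anyDuplicated(key)) abort("duplicate (subject, observer, disc) grade record")
  for (grp in split(g, paste(g$subject_id, g$observer_id))) {
    lack <- setdiff(DISCS, grp$disc)
    if (length(lack) > 0) {
      abort(paste0(
        "missing disc grade ", lack[1], " for ",
        grp$subject_id[1], "/", grp$observer_id[1]
      ))
    }
  }
  g <- dplyr::arrange(g, .data$subject_id, .data$observer_id, match(.data$disc, DISCS))
  invisible(g)
}

#' Read or write a Pfirrmann grade CSV
#'
#' @param path Path to a CSV with columns `subject_id`, `observer_id`, `disc`,
#'   `grade`.
#' @return A validated grade tibble.
#' @export
read_grades <- function(path) {
  if (!file.exists(path)) abort(paste0("grade file not found: ", path))
  g <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      observer_id = readr::col_character(),
      disc = readr::col_character(),
      grade = readr::col_integer()
    )
  )
  validate_grades(g)
}

#' @rdname read_grades
#' @param grades A grade tibble.
#' @export
write_grades <- function(grades, path) {
  g <- validate_grades(grades)
  readr::write_csv(g, path)
  invisible(path)
}
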