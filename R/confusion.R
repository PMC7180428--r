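#' Construct a 5x5 grade confusion matrix
#'
#' Rows index observer 1's Pfirrmann grade, columns observer 2's.
#'
#' @param counts A 5x5 matrix of nonnegative integer counts.
#' @return An object of class `lordist_confusion`: the counts with grade
#'   dimnames, plus `n_total`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(5L, 5L))) abort("confusion matrix must be 5x5")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("confusion matrix cells must be nonnegative integers")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(
    observer1 = paste0("G", 1:5),
    observer2 = paste0("G", 1:5)
  )
  structure(
    list(counts = counts, n_total = sum(counts)),
    class = "lordist_confusion"
  )
}

#' @export
print.lordist_confusion <- function(x, ...) {
  cat("Pfirrmann grade confusion matrix (rows: observer 1, cols: observer 2)\n")
  print(x$counts)
  cat("n =", x$n_total, "\n")
  invisible(x)
}

#' Cross-tabulate two observers' Pfirrmann gradings
#'
#' Pairs the two grade tables on (subject, disc) and counts cell (i, j) as
#' the number of discs graded i by observer 1 and j by observer 2.
#'
#' @param g1,g2 Grade tibbles (see [validate_grades()]), one observer each.
#' @return A [confusion_matrix()] with `n_total` equal to the number of
#'   shared discs.
#' @export
build_confusion <- function(g1, g2) {
  g1 <- validate_grades(g1)
  g2 <- validate_grades(g2)
  k1 <- paste(g1$subject_id, g1$disc)
  k2 <- paste(g2$subject_id, g2$disc)
  unmatched <- c(setdiff(k1, k2), setdiff(k2, k1))
  if (length(unmatched) > 0) {
    abort(paste0(
      "grade tables do not pair: unmatched (subject, disc) key(s): ",
      paste(head(unmatched, 5), collapse = "; ")
    ))
  }
  m <- match(k1, k2)
  counts <- table(
    factor(g1$grade, levels = PFIRRMANN_GRADES),
    factor(g2$grade[m], levels = PFIRRMANN_GRADES)
  )
  confusion_matrix(unclass(counts))
}

#' Read or write a confusion matrix as JSON
#'
#' The JSON holds a 5x5 integer array (rows: observer 1).
#'
#' @param path Path to the JSON file.
#' @return A `lordist_confusion` object.
#' @export
read_confusion <- function(path) {
  if (!file.exists(path)) abort(paste0("confusion-matrix file not found: ", path))
  raw <- jsonlite::fromJSON(path)
  if (is.list(raw) && !is.null(raw$counts)) raw <- raw$counts
  confusion_matrix(raw)
}

#' @rdname read_confusion
#' @param cm A `lordist_confusion` object.
#' @export
write_confusion <- function(cm, path) {
  stopifnot(inherits(cm, "lordist_confusion"))
  jsonlite::write_json(
    list(counts = unname(cm$counts), n_total = cm$n_total),
    path,
    digits = NA, auto_unbox = TRUE, matrix = "rowmajor"
  )
  invisible(path)
}

#' @export
autoplot.lordist_confusion <- function(object, ...) {
  df <- tibble::as_tibble(as.table(object$counts))
  names(df) <- c("observer1", "observer2", "n")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$observer2,
    y = factor(.data$observer1, levels = rev(paste0("G", 1:5))),
    fill = .data$n
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = "Observer 2 grade", y = "Observer 1 grade",
      title = "Interobserver Pfirrmann grade cross-tabulation"
    ) +
    ggplot2::theme_minimal()
}
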