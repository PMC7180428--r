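# Shared fixture builders. Everything is generated in code; no stored data.

# A spine whose midline is the symmetric parabola y = h * x(L-x)/(L/2)^2 ...
# i.e. apex height h at L/2, with equally spaced vertebral centers.
parabola_reading <- function(L = 100, h = 25, subject_id = "P1") {
  spec <- spine_spec(
    span = L, apex_fraction = 0.5, apex_height = h,
    node_fractions = seq(0, 1, length.out = 7),
    subject_id = subject_id
  )
  generate_spine(spec)
}

# Naive Lagrange product-formula evaluation (the spec's defining formula),
# kept independent of the package's barycentric implementation.
naive_lagrange <- function(x, y, xout) {
  vapply(xout, function(x0) {
    sum(vapply(seq_along(x), function(i) {
      y[i] * prod((x0 - x[-i]) / (x[i] - x[-i]))
    }, numeric(1)))
  }, numeric(1))
}

# A random degree-6 curve on [0, 1] with strictly increasing nodes.
random_curve <- function(seed) {
  set.seed(seed)
  x <- c(0, sort(runif(5, 0.05, 0.95)), 1)
  while (any(diff(x) < 0.02)) {
    x <- c(0, sort(runif(5, 0.05, 0.95)), 1)
  }
  y <- rnorm(7)
  fit_lagrange(list(x = x, y = y))
}

# Grade tibble for one observer from a vector of 5 * n_subjects grades.
grade_table <- function(grades, observer_id) {
  n <- length(grades) / 5
  tibble::tibble(
    subject_id = sprintf("S%03d", rep(seq_len(n), each = 5)),
    observer_id = observer_id,
    disc = rep(c("L1-L2", "L2-L3", "L3-L4", "L4-L5", "L5-S1"), n),
    grade = as.integer(grades)
  )
}

# The published 300-disc confusion matrix bundled with the package.
bundled_confusion <- function() {
  read_confusion(system.file("extdata", "pfirrmann_interobserver_counts.json",
    package = "lordist"
  ))
}
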