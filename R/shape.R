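#' Construct a target 2D contour
#'
#' Returns `m` ordered points tracing a named contour, used as the target of
#' the shape-constrained embedder. Available shapes:
#' * `"circle"`: the unit circle, sampled counter-clockwise from (1, 0).
#' * `"two_moons"`: two interleaved half-circle arcs (the classic two-moons
#'   layout), upper arc first.
#' * `"elephant"`: a truncated Fourier contour resembling an elephant outline;
#'   the coefficients ship with the package as a versioned fixture
#'   (`inst/extdata/elephant_fourier.tsv`) and the curve is closed over a full
#'   period.
#'
#' @param name One of `"circle"`, `"two_moons"`, `"elephant"`.
#' @param m Number of contour points (>= 3).
#' @return An object of class `shape_spec`: list with `points` (m x 2 matrix),
#'   `name`, and `diameter` (max pairwise distance, cached).
#' @examples
#' sh <- make_shape("circle", 4)
#' sh$points
#' @export
make_shape <- function(name, m = 200L) {
  available <- c("circle", "two_moons", "elephant")
  if (!is.character(name) || !(name %in% available)) {
    abort(paste0("unknown shape '", name, "'; available: ",
                 paste(available, collapse = ", ")))
  }
  m <- as.integer(m)
  if (m < 3) abort("m must be >= 3")
  pts <- switch(name,
    circle = {
      t <- 2 * pi * (seq_len(m) - 1) / m
      cbind(cos(t), sin(t))
    },
    two_moons = {
      m1 <- ceiling(m / 2)
      m2 <- m - m1
      t1 <- seq(0, pi, length.out = m1)
      t2 <- seq(0, pi, length.out = m2)
      rbind(cbind(cos(t1), sin(t1)),
            cbind(1 - cos(t2), 0.5 - sin(t2)))
    },
    elephant = {
      t <- 2 * pi * (seq_len(m) - 1) / m
      elephant_contour(t)
    }
  )
  new_shape(pts, name)
}

# Evaluate the elephant truncated Fourier series at angles t.
elephant_contour <- function(t) {
  coef <- elephant_coefficients()
  x <- numeric(length(t))
  y <- numeric(length(t))
  for (r in seq_len(nrow(coef))) {
    k <- coef$k[r]
    x <- x + coef$x_cos[r] * cos(k * t) + coef$x_sin[r] * sin(k * t)
    y <- y + coef$y_cos[r] * cos(k * t) + coef$y_sin[r] * sin(k * t)
  }
  cbind(x, y)
}

elephant_coefficients <- function() {
  path <- system.file("extdata", "elephant_fourier.tsv",
                      package = "embedbench", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

new_shape <- function(points, name) {
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 1)
  check_finite(points, "shape points")
  diameter <- if (nrow(points) >= 2) max(cpp_pairwise_dist(points)) else 0
  structure(list(points = unname(points), name = name, diameter = diameter),
            class = "shape_spec")
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec> %s: %d points, diameter %.3g\n",
              x$name, nrow(x$points), x$diameter))
  invisible(x)
}

#' Read / write a shape as 2-column TSV
#'
#' Columns `x`, `y`, rows ordered along the contour.
#'
#' @param shape A `shape_spec`.
#' @param path File path.
#' @param name Shape name to attach on read.
#' @return `write_shape()`: `path` invisibly. `read_shape()`: a `shape_spec`.
#' @export
write_shape <- function(shape, path) {
  stopifnot(inherits(shape, "shape_spec"))
  readr::write_tsv(tibble(x = shape$points[, 1], y = shape$points[, 2]), path)
  invisible(path)
}

#' @rdname write_shape
#' @export
read_shape <- function(path, name = "custom") {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  new_shape(cbind(tab$x, tab$y), name)
}
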