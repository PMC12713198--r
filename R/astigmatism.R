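#' Canonical astigmatism: cylinder magnitude and axis
#'
#' Constructs a normalized astigmatism record from clinical cylinder notation.
#' Clinical refractions write the cylinder either in minus or plus form; the
#' two are transpositions of one another (a cylinder \eqn{-C} at axis
#' \eqn{\alpha} equals \eqn{+C} at \eqn{\alpha + 90^\circ}). All vector
#' arithmetic in this package runs on the normalized plus form: magnitude
#' \eqn{C \ge 0}, axis in \eqn{[0, 180)} degrees (TABO convention,
#' counterclockwise from the horizontal).
#'
#' @param cylinder numeric vector of signed cylinder powers in diopters;
#'   negative values are transposed to plus form.
#' @param axis numeric vector of axes in degrees (any finite value; reduced
#'   modulo 180). Recycled against `cylinder`.
#' @return An object of class `astig`: a data frame with columns
#'   `magnitude` (diopters, \eqn{\ge 0}) and `axis` (degrees in `[0, 180)`).
#'   Zero-magnitude entries have their axis canonicalized to 0.
#' @examples
#' astig(-1.50, 30)   # transposes to 1.50 D at 120 degrees
#' astig(1.00, 180)   # axis reduced to 0
#' @export
astig <- function(cylinder, axis) {
  if (!is.numeric(cylinder) || !is.numeric(axis))
    stop("'cylinder' and 'axis' must be numeric", call. = FALSE)
  n <- max(length(cylinder), length(axis))
  cylinder <- rep_len(cylinder, n)
  axis <- rep_len(axis, n)
  if (any(!is.finite(cylinder)) || any(!is.finite(axis)))
    stop("non-finite cylinder or axis", call. = FALSE)
  magnitude <- abs(cylinder)
  ax <- (axis + ifelse(cylinder < 0, 90, 0)) %% 180
  ax[magnitude == 0] <- 0
  structure(data.frame(magnitude = magnitude, axis = ax),
            class = c("astig", "data.frame"))
}

#' @export
print.astig <- function(x, ...) {
  cat(sprintf("<astig: %d eye%s>\n", nrow(x), if (nrow(x) == 1) "" else "s"))
  print(format(data.frame(magnitude_D = round(x$magnitude, 4),
                          axis_deg = round(x$axis, 2))), ...)
  invisible(x)
}

is_astig <- function(x) inherits(x, "astig")

as_astig <- function(x) {
  if (is_astig(x)) return(x)
  stop("expected an 'astig' object; build one with astig(cylinder, axis)",
       call. = FALSE)
}

#' Map astigmatism into the double-angle plane
#'
#' A cylinder of magnitude \eqn{C} at axis \eqn{\alpha} maps to the Cartesian
#' point \eqn{(X, Y) = (C\cos 2\alpha,\; C\sin 2\alpha)}. Because the axis is
#' doubled, cylinders 180 degrees apart coincide and vector
#' addition/subtraction of astigmatisms becomes ordinary addition in the
#' plane. This is the space in which TIA, SIA, DV and cohort centroids are
#' computed.
#'
#' @param a an [astig] object.
#' @return Data frame with columns `x`, `y` (diopters); row lengths match `a`.
#' @export
to_double_angle <- function(a) {
  a <- as_astig(a)
  two_alpha <- 2 * a$axis * pi / 180
  data.frame(x = a$magnitude * cos(two_alpha),
             y = a$magnitude * sin(two_alpha))
}

#' Invert the double-angle map
#'
#' @param x numeric vector of X components (diopters), or a data frame with
#'   columns `x` and `y` as returned by [to_double_angle()].
#' @param y numeric vector of Y components; ignored when `x` is a data frame.
#' @return An [astig] with `magnitude = sqrt(x^2 + y^2)` and
#'   `axis = atan2(y, x) / 2` reduced into `[0, 180)`. The zero vector maps
#'   to magnitude 0 at axis 0.
#' @export
from_double_angle <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    y <- x$y
    x <- x$x
  }
  magnitude <- sqrt(x^2 + y^2)
  ax <- (atan2(y, x) / 2 * 180 / pi) %% 180
  ax[magnitude == 0] <- 0
  structure(data.frame(magnitude = magnitude, axis = ax),
            class = c("astig", "data.frame"))
}

# double-angle difference a - b, returned as astig
da_diff <- function(a, b) {
  va <- to_double_angle(as_astig(a))
  vb <- to_double_angle(as_astig(b))
  from_double_angle(va$x - vb$x, va$y - vb$y)
}

zero_astig <- function(n = 1L) astig(rep(0, n), rep(0, n))

#' Cohort vector mean of astigmatisms
#'
#' Averages a set of astigmatisms in the double-angle plane (the centroid),
#' maps the centroid back to a cylinder, and separately returns the
#' arithmetic mean of the scalar magnitudes. The two summaries answer
#' different questions: the centroid magnitude is attenuated by axis scatter
#' (it is zero for axes spread uniformly), while the scalar mean ignores
#' axes entirely; the centroid magnitude can never exceed the scalar mean.
#'
#' @param a an [astig] with one row per eye; must be non-empty.
#' @return A list with components `centroid` (named numeric, `x` and `y`
#'   in diopters), `mean_astig` (single-row [astig], the vector mean), and
#'   `arithmetic_mean_magnitude` (diopters).
#' @export
vector_mean <- function(a) {
  a <- as_astig(a)
  if (nrow(a) == 0L) stop("empty cohort: no astigmatisms to average", call. = FALSE)
  v <- to_double_angle(a)
  cx <- mean(v$x)
  cy <- mean(v$y)
  list(centroid = c(x = cx, y = cy),
       mean_astig = from_double_angle(cx, cy),
       arithmetic_mean_magnitude = mean(a$magnitude))
}

#' Spherical equivalent of a sphero-cylindrical refraction
#'
#' @param sphere,cylinder numeric vectors, diopters (cylinder signed, either
#'   notation; SE is notation-invariant).
#' @return `sphere + cylinder / 2`, diopters.
#' @export
spherical_equivalent <- function(sphere, cylinder) sphere + cylinder / 2
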