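#' Residual astigmatism from a rotated cylindrical correction
#'
#' Closed-form cross-cylinder result of treating an eye with cylinder `C` at
#' axis `alpha` using a full-power correction applied `theta` degrees away
#' from the intended axis: the residual is the double-angle difference
#' between the eye's astigmatism and the rotated correction. Its magnitude
#' is \eqn{2 C \sin|\theta|} and its axis is
#' \eqn{\alpha + \theta/2 - 45 \,\mathrm{sign}(\theta) \pmod{180}}. At 30
#' degrees of rotation the full treated cylinder is left behind; beyond it
#' the correction adds astigmatism.
#'
#' @param C treated cylinder magnitude, diopters (\eqn{\ge 0}). Vectorized.
#' @param alpha intended cylinder axis, degrees.
#' @param theta signed rotation of the applied correction, degrees,
#'   \eqn{|\theta| \le 90}.
#' @return [astig] residual, one row per input.
#' @examples
#' residual_after_rotation(2, 0, 10)   # 0.695 D at 140 degrees
#' residual_after_rotation(1, 30, 30)  # magnitude exactly 1 D
#' @export
residual_after_rotation <- function(C, alpha, theta) {
  n <- max(length(C), length(alpha), length(theta))
  C <- rep_len(C, n)
  alpha <- rep_len(alpha, n)
  theta <- rep_len(theta, n)
  if (any(!is.finite(C)) || any(C < 0))
    stop("C must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(theta)) || any(abs(theta) > 90))
    stop("theta must satisfy |theta| <= 90 degrees", call. = FALSE)
  eye <- astig(C, alpha)
  correction <- astig(C, alpha + theta)
  da_diff(eye, correction)
}

#' Fractional undercorrection caused by axis misalignment
#'
#' For a full-power cylindrical correction rotated by `theta` degrees, the
#' residual astigmatism as a fraction of the treated cylinder is
#' \eqn{2\sin\theta}, independent of the cylinder's size. About 3.5% per
#' degree for small rotations: roughly 14% at 4 degrees, 100% at 30
#' degrees (the correction accomplishes nothing), 200% at 90 degrees
#' (astigmatism doubled).
#'
#' @param theta rotation magnitude in degrees, in \eqn{[0, 90]}. Vectorized.
#' @return Dimensionless fraction in \eqn{[0, 2]}.
#' @examples
#' undercorrection_fraction(4)   # ~0.14
#' undercorrection_fraction(30)  # exactly 1
#' @export
undercorrection_fraction <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 90))
    stop("theta must lie in [0, 90] degrees", call. = FALSE)
  2 * sin(theta * pi / 180)
}

#' Alpins indices of a pure misalignment
#'
#' For an eye whose only correction error is an axis rotation `theta`
#' (full-power cylinder delivered at the wrong meridian), the Alpins
#' parameters follow exactly: the delivered correction has the intended
#' magnitude, so CI = 1 and ME = 0; the angle of error equals `theta`; and
#' IOS equals the undercorrection fraction \eqn{2\sin\theta}. Computed
#' numerically through the vector-analysis layer, not asserted.
#'
#' @param C treated cylinder magnitude, diopters (> 0 for defined ratios).
#' @param alpha intended axis, degrees.
#' @param theta rotation, degrees in \eqn{(0, 90]}. Vectorized.
#' @return Data frame as from [alpins_indices()].
#' @export
pure_misalignment_indices <- function(C, alpha, theta) {
  n <- max(length(C), length(alpha), length(theta))
  C <- rep_len(C, n)
  alpha <- rep_len(alpha, n)
  theta <- rep_len(theta, n)
  preop <- astig(C, alpha)
  postop <- residual_after_rotation(C, alpha, theta)
  alpins_indices(preop, postop, warn = FALSE)
}

#' Simulated surgical outcome under rotation and partial efficacy
#'
#' Generator hook mapping one preoperative refraction to its postoperative
#' refraction when the cylindrical correction is (a) delivered at an axis
#' rotated by `theta` and (b) scaled by an `efficacy` fraction modelling
#' systematic undercorrection (tissue response folded into one factor).
#' In the double-angle plane the postoperative cylinder is the preoperative
#' vector minus an `efficacy`-scaled vector at the rotated axis; the
#' spherical channel is reduced to `(1 - efficacy)` of its preoperative
#' value. Input notation (plus or minus cylinder) is irrelevant; output is
#' clinical minus-cylinder notation with the transposition-adjusted sphere,
#' so the returned refraction is optically equivalent to the plus form.
#'
#' @param sphere,cylinder,axis preoperative refraction (cylinder signed,
#'   either notation; degrees). Vectorized, equal lengths recycled.
#' @param theta rotation applied to the correction axis, degrees.
#' @param efficacy fraction of the planned power actually delivered, in
#'   \eqn{[0, 1]}; may be given per eye. `efficacy = 1` with `theta = 0`
#'   yields plano; `efficacy = 0` returns the eye untreated.
#' @return Data frame `sphere_D`, `cyl_D` (\eqn{\le 0}), `axis_deg`.
#' @export
apply_misalignment_to_eye <- function(sphere, cylinder, axis, theta, efficacy = 1) {
  n <- max(length(sphere), length(cylinder), length(axis), length(theta),
           length(efficacy))
  sphere <- rep_len(sphere, n)
  cylinder <- rep_len(cylinder, n)
  axis <- rep_len(axis, n)
  theta <- rep_len(theta, n)
  efficacy <- rep_len(efficacy, n)
  if (any(!is.finite(efficacy)) || any(efficacy < 0) || any(efficacy > 1))
    stop("efficacy must lie in [0, 1]", call. = FALSE)
  pre <- astig(cylinder, axis)
  # plus-form sphere: transposing (S, C<0, ax) gives (S + C, |C|, ax + 90)
  sphere_plus <- sphere + pmin(cylinder, 0)
  treated <- astig(efficacy * pre$magnitude, pre$axis + theta)
  res <- da_diff(pre, treated)
  post_sphere_plus <- (1 - efficacy) * sphere_plus
  # back to minus notation
  data.frame(sphere_D = post_sphere_plus + res$magnitude,
             cyl_D = -res$magnitude,
             axis_deg = (res$axis + 90) %% 180)
}
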