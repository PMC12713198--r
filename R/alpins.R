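#' Target-induced astigmatism (TIA)
#'
#' The astigmatic correction the surgery intends: the double-angle vector
#' difference between the preoperative astigmatism and the refractive target.
#' Under the usual full-correction plan the target is zero astigmatism and
#' TIA equals the preoperative cylinder.
#'
#' @param preop preoperative [astig].
#' @param target target [astig]; `NULL` (default) means a plano target.
#' @return [astig] of the same length as `preop`.
#' @export
compute_tia <- function(preop, target = NULL) {
  preop <- as_astig(preop)
  if (is.null(target)) return(preop)
  da_diff(preop, as_astig(target))
}

#' Surgically induced astigmatism (SIA)
#'
#' The astigmatic change the surgery actually produced: preoperative minus
#' postoperative astigmatism in the double-angle plane.
#'
#' @param preop,postop [astig] objects of equal length.
#' @return [astig].
#' @export
compute_sia <- function(preop, postop) da_diff(preop, postop)

#' Difference vector (DV)
#'
#' The correction still needed after surgery to reach the target. Under the
#' same orientation convention as TIA and SIA (a correction is the vector
#' from the current to the desired state, current minus desired), DV is the
#' achieved minus the target astigmatism in the double-angle plane,
#' algebraically identical to TIA minus SIA. Its magnitude is the residual
#' astigmatism; under a plano target it equals the postoperative cylinder.
#'
#' @param target target [astig] (`NULL` = plano target).
#' @param achieved postoperative [astig].
#' @return [astig].
#' @export
compute_dv <- function(target, achieved) {
  achieved <- as_astig(achieved)
  if (is.null(target)) target <- zero_astig(nrow(achieved))
  da_diff(achieved, target)
}

#' Angle of error (AoE)
#'
#' Signed axis separation between the achieved (SIA) and intended (TIA)
#' correction, wrapped into \eqn{(-90, 90]} degrees. Zero means perfect
#' alignment; positive means the achieved correction sits counterclockwise
#' of the intended axis. Undefined (NA) when either vector has zero
#' magnitude, since a zero-length cylinder has no axis.
#'
#' @param tia,sia [astig] objects of equal length.
#' @return Numeric vector of signed degrees in \eqn{(-90, 90]}, NA where
#'   either magnitude is zero.
#' @export
compute_angle_of_error <- function(tia, sia) {
  tia <- as_astig(tia)
  sia <- as_astig(sia)
  d <- (sia$axis - tia$axis) %% 180
  d[d > 90] <- d[d > 90] - 180
  d[tia$magnitude == 0 | sia$magnitude == 0] <- NA_real_
  d
}

#' Scalar Alpins indices: ME, CI, IOS
#'
#' Magnitude of error `ME = |SIA| - |TIA|` (positive = overcorrection),
#' correction index `CI = |SIA| / |TIA|` (1 = complete correction, below 1 =
#' undercorrection) and index of success `IOS = |DV| / |TIA|` (0 = perfect).
#' The two ratios are undefined (NA) for eyes with zero TIA; such eyes are
#' excluded from cohort aggregates rather than dropped silently.
#'
#' @param tia,sia,dv [astig] objects of equal length.
#' @return Data frame with columns `me`, `ci`, `ios`.
#' @export
compute_scalar_indices <- function(tia, sia, dv) {
  tia <- as_astig(tia)
  sia <- as_astig(sia)
  dv <- as_astig(dv)
  zero <- tia$magnitude == 0
  me <- sia$magnitude - tia$magnitude
  ci <- ifelse(zero, NA_real_, sia$magnitude / tia$magnitude)
  ios <- ifelse(zero, NA_real_, dv$magnitude / tia$magnitude)
  data.frame(me = me, ci = ci, ios = ios)
}

#' Per-eye Alpins vector analysis
#'
#' Computes the full set of Alpins parameters for each eye: TIA, SIA and DV
#' (magnitude and axis), angle of error, magnitude of error, correction
#' index and index of success.
#'
#' @param preop,postop [astig] objects of equal length (one row per eye).
#' @param target optional target [astig]; `NULL` means plano target, under
#'   which TIA equals the preoperative astigmatism and the DV magnitude
#'   equals the postoperative cylinder.
#' @param warn warn when zero-TIA eyes make CI/IOS/AoE undefined.
#' @return Data frame with one row per eye: `tia_D`, `tia_axis_deg`,
#'   `sia_D`, `sia_axis_deg`, `dv_D`, `dv_axis_deg`, `ae_deg`, `me_D`,
#'   `ci`, `ios`.
#' @examples
#' pre <- astig(c(-1.5, -2.0), c(10, 95))
#' post <- astig(c(-0.25, 0), c(40, 0))
#' alpins_indices(pre, post)
#' @export
alpins_indices <- function(preop, postop, target = NULL, warn = TRUE) {
  preop <- as_astig(preop)
  postop <- as_astig(postop)
  if (nrow(preop) != nrow(postop))
    stop("preop and postop must have the same number of eyes", call. = FALSE)
  tia <- compute_tia(preop, target)
  sia <- compute_sia(preop, postop)
  dv <- compute_dv(target, postop)
  ae <- compute_angle_of_error(tia, sia)
  sc <- compute_scalar_indices(tia, sia, dv)
  if (warn && any(tia$magnitude == 0))
    warning(sprintf("%d eye(s) with zero TIA: CI, IOS and AoE set to NA and excluded from aggregates",
                    sum(tia$magnitude == 0)), call. = FALSE)
  data.frame(tia_D = tia$magnitude, tia_axis_deg = tia$axis,
             sia_D = sia$magnitude, sia_axis_deg = sia$axis,
             dv_D = dv$magnitude, dv_axis_deg = dv$axis,
             ae_deg = ae, me_D = sc$me, ci = sc$ci, ios = sc$ios)
}

#' Cohort summary of an Alpins analysis
#'
#' Scalar means plus double-angle vector means (centroids) of TIA, SIA and
#' DV over a cohort, the summaries conventionally reported alongside
#' per-eye Alpins tables.
#'
#' @param preop,postop [astig] objects; `target` as in [alpins_indices()].
#' @return Data frame with one row per parameter (TIA, SIA, DV):
#'   `scalar_mean_D`, `centroid_x_D`, `centroid_y_D`, `vector_mean_D`,
#'   `vector_mean_axis_deg`.
#' @export
alpins_cohort_summary <- function(preop, postop, target = NULL) {
  preop <- as_astig(preop)
  postop <- as_astig(postop)
  vecs <- list(TIA = compute_tia(preop, target),
               SIA = compute_sia(preop, postop),
               DV = compute_dv(target, postop))
  rows <- lapply(names(vecs), function(nm) {
    vm <- vector_mean(vecs[[nm]])
    data.frame(parameter = nm,
               scalar_mean_D = vm$arithmetic_mean_magnitude,
               centroid_x_D = unname(vm$centroid["x"]),
               centroid_y_D = unname(vm$centroid["y"]),
               vector_mean_D = vm$mean_astig$magnitude,
               vector_mean_axis_deg = vm$mean_astig$axis)
  })
  do.call(rbind, rows)
}
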