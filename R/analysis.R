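visit_prefix <- c("1m" = "post1m", "3m" = "post3m")

visit_astig <- function(cohort, visit) {
  p <- visit_prefix[[visit]]
  astig(cohort[[paste0(p, "_cyl_D")]], cohort[[paste0(p, "_axis_deg")]])
}

# per-eye derived table for one visit: Alpins parameters + raw CYL/AXIS
visit_parameters <- function(cohort, visit) {
  pre <- astig(cohort$pre_cyl_D, cohort$pre_axis_deg)
  post <- visit_astig(cohort, visit)
  al <- alpins_indices(pre, post, warn = FALSE)
  p <- visit_prefix[[visit]]
  cbind(data.frame(eye_id = cohort$eye_id,
                   rotation_deg = cohort$rotation_deg,
                   cyl_D = cohort[[paste0(p, "_cyl_D")]],
                   axis_deg = cohort[[paste0(p, "_axis_deg")]],
                   residual_D = post$magnitude),
        al)
}

corr_row <- function(name, x, y) {
  pr <- tryCatch(suppressWarnings(pearson_r(x, y)),
                 error = function(e) list(r = NA_real_, p_value = NA_real_,
                                          n = sum(stats::complete.cases(x, y))))
  data.frame(indicator = name,
             mean = mean(y, na.rm = TRUE), sd = stats::sd(y, na.rm = TRUE),
             r = pr$r, p_value = pr$p_value, n = pr$n)
}

#' Analyze a cohort: the rotation-vs-residual-astigmatism pipeline
#'
#' Runs the full inferential chain on a per-eye cohort table, per
#' postoperative visit: (i) per-eye Alpins vector analysis and cohort
#' vector means; (ii) a covariate correlation screen of residual
#' astigmatism against rotation magnitude, preoperative refraction and
#' biometry; (iii) multiple linear regression of residual astigmatism on
#' rotation, IOP and preoperative cylinder with standardized coefficients;
#' (iv) rotation-versus-vector-parameter correlations (CYL, AXIS, and the
#' magnitudes/axes of SIA, TIA, DV plus AoE, ME, IOS, CI); (v) simple
#' linear fits of each vector magnitude on rotation; and (vi) ROC analysis
#' of rotation magnitude predicting dichotomized residual astigmatism with
#' the Youden-optimal cutoff. Correlations against zero-variance columns
#' are reported as NA rather than failing. p-values are two-tailed and no
#' multiplicity correction is applied.
#'
#' @param cohort an `eye_cohort` data frame ([generate_cohort()] /
#'   [read_cohort()]).
#' @param residual_cutoff diopters of residual cylinder defining the ROC
#'   positive class (default 0.50 D).
#' @param visits character subset of `c("1m", "3m")`.
#' @param screen_visit visit whose residual feeds the covariate screen and
#'   the regression (default `"3m"`, the follow-up at which rotational
#'   error is least masked by early corneal remodelling).
#' @return Object of class `rotastig_analysis`: a list with `per_eye`,
#'   `vector_means`, `covariate_screen`, `regression`, `rotation_vs_vector`,
#'   `linear_fits`, `roc` (per visit), plus `visits`, `residual_cutoff`,
#'   `n`, `call`. Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_eyes = 60, seed = 11))
#' fit <- analyze_cohort(coh)
#' print(fit)
#' coef(fit)
#' @export
analyze_cohort <- function(cohort, residual_cutoff = 0.5,
                           visits = c("1m", "3m"), screen_visit = "3m") {
  missing <- setdiff(cohort_columns, names(cohort))
  if (length(missing))
    stop("cohort is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  visits <- match.arg(visits, several.ok = TRUE)
  if (!screen_visit %in% visits) screen_visit <- visits[length(visits)]

  per_eye <- lapply(visits, function(v) visit_parameters(cohort, v))
  names(per_eye) <- visits

  pre <- astig(cohort$pre_cyl_D, cohort$pre_axis_deg)
  vector_means <- lapply(visits, function(v)
    alpins_cohort_summary(pre, visit_astig(cohort, v)))
  names(vector_means) <- visits

  # covariate screen against the screening visit's residual magnitude
  resid <- per_eye[[screen_visit]]$residual_D
  screen_vars <- list("Magnitude of ocular rotation (deg)" = cohort$rotation_deg,
                      "IOP (mmHg)" = cohort$iop_mmHg,
                      "Axial length (mm)" = cohort$al_mm,
                      "WTW (mm)" = cohort$wtw_mm,
                      "Kappa x (mm)" = cohort$kappa_x_mm,
                      "Kappa y (mm)" = cohort$kappa_y_mm,
                      "Preoperative cylinder (D)" = cohort$pre_cyl_D,
                      "Preoperative sphere (D)" = cohort$pre_sphere_D,
                      "Preoperative SE (D)" =
                        spherical_equivalent(cohort$pre_sphere_D, cohort$pre_cyl_D))
  covariate_screen <- do.call(rbind, lapply(names(screen_vars), function(nm) {
    row <- corr_row(nm, resid, screen_vars[[nm]])
    row
  }))

  reg_df <- data.frame(residual_D = resid,
                       rotation_deg = cohort$rotation_deg,
                       iop_mmHg = cohort$iop_mmHg,
                       pre_cyl_D = cohort$pre_cyl_D)
  reg_terms <- c("rotation_deg", "iop_mmHg", "pre_cyl_D")
  regression <- tryCatch(
    multiple_regression(reg_df, "residual_D", reg_terms),
    error = function(e) {
      warning("regression degenerate, coefficients set to NA: ",
              conditionMessage(e), call. = FALSE)
      list(coefficients = data.frame(term = c("(Intercept)", reg_terms),
                                     estimate = NA_real_,
                                     std_beta = NA_real_, t = NA_real_,
                                     p_value = NA_real_),
           r_squared = NA_real_, sigma = NA_real_, n = nrow(reg_df),
           fit = NULL, degenerate = conditionMessage(e))
    })

  rot <- cohort$rotation_deg
  rot_vs_vec <- lapply(per_eye, function(pe) {
    rows <- list(c("Postoperative CYL (D)", "cyl_D"),
                 c("Postoperative AXIS (deg)", "axis_deg"),
                 c("SIA (D)", "sia_D"), c("SIA (deg)", "sia_axis_deg"),
                 c("TIA (D)", "tia_D"), c("TIA (deg)", "tia_axis_deg"),
                 c("AE (deg)", "ae_deg"), c("ME (D)", "me_D"),
                 c("DV (D)", "dv_D"), c("DV (deg)", "dv_axis_deg"),
                 c("IOS", "ios"), c("CI", "ci"))
    do.call(rbind, lapply(rows, function(rw) corr_row(rw[1], rot, pe[[rw[2]]])))
  })

  linear_fits <- lapply(per_eye, function(pe) {
    pars <- c(CYL_D = "residual_D", TIA_D = "tia_D",
              SIA_D = "sia_D", DV_D = "dv_D")
    do.call(rbind, lapply(names(pars), function(nm) {
      fit <- tryCatch(suppressWarnings(simple_linear_fit(rot, pe[[pars[nm]]])),
                      error = function(e) list(slope = NA_real_,
                        intercept = NA_real_, r = NA_real_,
                        p_value = NA_real_, n = NA_integer_))
      data.frame(parameter = nm, slope = fit$slope,
                 intercept = fit$intercept, r = fit$r,
                 p_value = fit$p_value)
    }))
  })

  roc <- lapply(per_eye, function(pe)
    roc_analysis(rot, dichotomize_residual(pe$residual_D, residual_cutoff)))

  structure(list(per_eye = per_eye, vector_means = vector_means,
                 covariate_screen = covariate_screen,
                 regression = regression,
                 rotation_vs_vector = rot_vs_vec,
                 linear_fits = linear_fits, roc = roc,
                 visits = visits, screen_visit = screen_visit,
                 residual_cutoff = residual_cutoff,
                 n = nrow(cohort), call = match.call()),
            class = "rotastig_analysis")
}

#' @export
print.rotastig_analysis <- function(x, ...) {
  cat(sprintf("Rotation vs residual astigmatism analysis: %d eyes, visits %s\n",
              x$n, paste(x$visits, collapse = ", ")))
  rot_row <- x$covariate_screen[
    x$covariate_screen$indicator == "Magnitude of ocular rotation (deg)", ]
  cat(sprintf("Residual (%s) ~ rotation: r = %.3f (p = %.3g)\n",
              x$screen_visit, rot_row$r, rot_row$p_value))
  beta <- x$regression$coefficients
  b <- beta[beta$term == "rotation_deg", ]
  cat(sprintf("Regression: std beta(rotation) = %.3f (p = %.3g), R^2 = %.3f\n",
              b$std_beta, b$p_value, x$regression$r_squared))
  for (v in x$visits) {
    r <- x$roc[[v]]
    cat(sprintf("ROC %s (residual >= %.2f D): AUC %.3f, Youden cutoff %.2f deg\n",
                v, x$residual_cutoff, r$auc, r$optimal_cutoff))
  }
  invisible(x)
}

#' @export
summary.rotastig_analysis <- function(object, ...) {
  x <- object
  print(x)
  cat("\nCohort vector means:\n")
  for (v in x$visits) {
    cat(sprintf("  visit %s:\n", v))
    print(cbind(x$vector_means[[v]][1],
                round(x$vector_means[[v]][-1], 3)), row.names = FALSE)
  }
  cat("\nCovariate screen (residual astigmatism vs covariates):\n")
  scr <- x$covariate_screen
  print(data.frame(indicator = scr$indicator,
                   mean_sd = sprintf("%.3f +/- %.3f", scr$mean, scr$sd),
                   r = round(scr$r, 3), p = signif(scr$p_value, 3)),
        row.names = FALSE)
  cat("\nRegression coefficients:\n")
  print(cbind(x$regression$coefficients[1],
              round(x$regression$coefficients[-1], 4)), row.names = FALSE)
  cat("\nRotation vs vector parameters:\n")
  for (v in x$visits) {
    cat(sprintf("  visit %s:\n", v))
    tb <- x$rotation_vs_vector[[v]]
    print(data.frame(indicator = tb$indicator,
                     mean_sd = sprintf("%.3f +/- %.3f", tb$mean, tb$sd),
                     r = round(tb$r, 3), p = signif(tb$p_value, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.rotastig_analysis <- function(object, ...) {
  co <- object$regression$coefficients
  stats::setNames(co$estimate, co$term)
}

#' Diagnostic plots for a cohort analysis
#'
#' Two base-graphics panels per requested visit: residual astigmatism (and
#' the fitted line) against rotation magnitude, and the empirical ROC curve
#' with the Youden-optimal operating point marked.
#'
#' @param x a `rotastig_analysis`.
#' @param visit which visit to draw (default the screening visit).
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.rotastig_analysis <- function(x, visit = x$screen_visit, ...) {
  pe <- x$per_eye[[visit]]
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(pe$rotation_deg, pe$residual_D,
                 xlab = "Rotation magnitude (deg)",
                 ylab = "Residual astigmatism (D)",
                 main = sprintf("Visit %s", visit), ...)
  ft <- x$linear_fits[[visit]]
  cy <- ft[ft$parameter == "CYL_D", ]
  if (is.finite(cy$slope)) graphics::abline(cy$intercept, cy$slope, col = 2)
  r <- x$roc[[visit]]
  graphics::plot(1 - r$specificity, r$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC, AUC = %.3f", r$auc))
  graphics::abline(0, 1, lty = 3)
  best <- which(r$thresholds == r$optimal_cutoff)[1]
  graphics::points(1 - r$specificity[best], r$sensitivity[best],
                   pch = 19, col = 2)
  invisible(x)
}

#' Write all report tables of an analysis to CSV
#'
#' One CSV per report component: covariate screen, regression, per-visit
#' rotation-vs-vector correlations, linear fits, ROC coordinates, Alpins
#' per-eye tables and cohort vector means.
#'
#' @param x a `rotastig_analysis`.
#' @param dir output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "rotastig_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  put(x$covariate_screen, "covariate_screen.csv")
  reg <- x$regression$coefficients
  reg$r_squared <- x$regression$r_squared
  put(reg, "regression.csv")
  for (v in x$visits) {
    put(x$rotation_vs_vector[[v]], sprintf("rotation_vs_vector_%s.csv", v))
    put(x$linear_fits[[v]], sprintf("linear_fits_%s.csv", v))
    r <- x$roc[[v]]
    put(data.frame(threshold_deg = r$thresholds,
                   sensitivity = r$sensitivity,
                   specificity = r$specificity, youden_j = r$youden_j),
        sprintf("roc_curve_%s.csv", v))
    put(data.frame(auc = r$auc, optimal_cutoff_deg = r$optimal_cutoff,
                   youden_j = r$youden_max, n_pos = r$n_pos,
                   n_neg = r$n_neg),
        sprintf("roc_summary_%s.csv", v))
    put(x$per_eye[[v]], sprintf("alpins_per_eye_%s.csv", v))
    put(x$vector_means[[v]], sprintf("vector_means_%s.csv", v))
  }
  invisible(files)
}
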