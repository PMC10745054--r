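#' @name kinetic_fits
#' @title Candidate release-kinetics models
#'
#' @description
#' Three candidate models describe the cumulative amount permeated Q(t)
#' (ug/cm2):
#'
#' * zero order: \eqn{Q(t) = J \cdot \max(t - T_l, 0)} — constant-rate
#'   release; fitted by ordinary least squares of Q on t (slope J,
#'   x-intercept \eqn{T_l}), 2 parameters.
#' * first order: \eqn{Q(t) = Q_\infty (1 - e^{-k t})} — saturating
#'   release; fitted by bounded Levenberg–Marquardt nonlinear least squares,
#'   2 parameters.
#' * Higuchi: \eqn{Q(t) = K_H \sqrt{t}} — diffusion-controlled matrix
#'   release; one-parameter least squares through the origin in
#'   \eqn{\sqrt{t}}.
#'
#' Each fit reports \eqn{R^2} and the degrees-of-freedom-adjusted
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(N - 1)/(N - p - 1)} used by
#' [select_model()]. Profiles with no variance (e.g. all-zero) are flagged
#' `degenerate` rather than erroring.
#'
#' @param profile A `cumulative_profile` from [cumulative_amount()].
#' @return An object of class `kinetic_fit`: list with `model`,
#'   `parameters` (named), `fitted`, `residuals`, `r2`, `r2_adj`,
#'   `n_points`, `n_par`, `degenerate`, `diagnostics`.
NULL

new_kinetic_fit <- function(model, parameters, q, fitted, n_par,
                            degenerate = FALSE, diagnostics = NULL) {
  n <- length(q)
  ss_tot <- sum((q - mean(q))^2)
  if (degenerate || ss_tot == 0) {
    r2 <- NA_real_
    r2_adj <- NA_real_
    degenerate <- TRUE
  } else {
    r2 <- 1 - sum((q - fitted)^2) / ss_tot
    r2_adj <- if (n - n_par - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - n_par - 1)
              else NA_real_
  }
  structure(
    list(model = model, parameters = parameters, fitted = fitted,
         residuals = q - fitted, r2 = r2, r2_adj = r2_adj,
         n_points = n, n_par = n_par, degenerate = degenerate,
         diagnostics = diagnostics),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: %s (%d points)%s\n", x$model, x$n_points,
              if (x$degenerate) " [degenerate]" else ""))
  cat("  parameters:",
      paste(sprintf("%s = %.6g", names(x$parameters),
                    unlist(x$parameters)), collapse = ", "), "\n")
  if (!is.na(x$r2)) {
    cat(sprintf("  R2 = %.6f, adjusted R2 = %.6f\n", x$r2, x$r2_adj))
  }
  invisible(x)
}

#' @rdname kinetic_fits
#' @export
fit_zero_order <- function(profile) {
  stopifnot(inherits(profile, "cumulative_profile"))
  t <- profile$times_h
  q <- profile$q_ug_cm2
  if (length(t) < 3) stop("zero-order fit needs at least 3 points",
                          call. = FALSE)
  if (all(q == 0)) {
    return(new_kinetic_fit("zero_order",
                           list(flux_j = 0, lag_tl = 0, intercept = 0),
                           q, fitted = rep(0, length(q)), n_par = 2,
                           degenerate = TRUE,
                           diagnostics = "all-zero profile"))
  }
  fit <- stats::lm.fit(cbind(1, t), q)
  intercept <- fit$coefficients[1]
  slope <- fit$coefficients[2]
  j <- max(slope, 0)
  lag <- if (j > 0) min(max(-intercept / slope, 0), max(t)) else 0
  new_kinetic_fit("zero_order",
                  list(flux_j = unname(j), lag_tl = unname(lag),
                       intercept = unname(intercept),
                       slope = unname(slope)),
                  q, fitted = unname(fit$fitted.values), n_par = 2,
                  degenerate = slope <= 0)
}

#' @rdname kinetic_fits
#' @param max_restarts Bounded number of jittered restarts for the
#'   first-order nonlinear solve.
#' @export
fit_first_order <- function(profile, max_restarts = 5) {
  stopifnot(inherits(profile, "cumulative_profile"))
  t <- profile$times_h
  q <- profile$q_ug_cm2
  if (length(t) < 3) stop("first-order fit needs at least 3 points",
                          call. = FALSE)
  if (all(q == 0)) {
    return(new_kinetic_fit("first_order", list(q_inf = 0, k = 0),
                           q, fitted = rep(0, length(q)), n_par = 2,
                           degenerate = TRUE,
                           diagnostics = "all-zero profile"))
  }
  # starting values: Qinf0 = 1.2 max(Q); k0 from the log-linearisation
  # log(1 - Q/Qinf0) = -k t over the nonzero samples
  q_inf0 <- 1.2 * max(q)
  nz <- which(q > 0 & t > 0)
  k0 <- if (length(nz) >= 1) {
    y <- log(pmax(1 - q[nz] / q_inf0, 1e-8))
    -sum(y * t[nz]) / sum(t[nz]^2)
  } else 1
  if (!is.finite(k0) || k0 <= 0) k0 <- 1
  dat <- data.frame(t = t, q = q)
  attempt <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(q ~ q_inf * (1 - exp(-k * t)), data = dat,
                        start = start,
                        lower = c(q_inf = 1e-12, k = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
  }
  fit <- attempt(list(q_inf = q_inf0, k = k0))
  tries <- 0
  while (inherits(fit, "error") && tries < max_restarts) {
    tries <- tries + 1
    fit <- attempt(list(q_inf = q_inf0 * stats::runif(1, 0.5, 2),
                        k = k0 * stats::runif(1, 0.2, 5)))
  }
  if (inherits(fit, "error")) {
    return(new_kinetic_fit("first_order",
                           list(q_inf = NA_real_, k = NA_real_),
                           q, fitted = rep(mean(q), length(q)), n_par = 2,
                           degenerate = TRUE,
                           diagnostics = paste("no convergence after",
                                               max_restarts, "restarts:",
                                               conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  new_kinetic_fit("first_order",
                  list(q_inf = unname(cf["q_inf"]), k = unname(cf["k"])),
                  q, fitted = as.numeric(stats::fitted(fit)), n_par = 2)
}

#' @rdname kinetic_fits
#' @export
fit_higuchi <- function(profile) {
  stopifnot(inherits(profile, "cumulative_profile"))
  t <- profile$times_h
  q <- profile$q_ug_cm2
  if (length(t) < 2) stop("Higuchi fit needs at least 2 points",
                          call. = FALSE)
  # through-origin OLS in sqrt(t): KH = sum(Q sqrt(t)) / sum(t)
  st <- sqrt(t)
  kh <- if (sum(t) > 0) sum(q * st) / sum(t) else 0
  new_kinetic_fit("higuchi", list(kh = kh), q, fitted = kh * st, n_par = 1,
                  degenerate = all(q == 0))
}

#' Select the best kinetic model by adjusted R-squared
#'
#' Returns the candidate fit with the highest degrees-of-freedom-adjusted
#' R-squared. Ties are broken toward the model with fewer parameters, then
#' by the fixed order zero-order, Higuchi, first-order. Degenerate fits
#' never win; if every candidate is degenerate, selection fails.
#'
#' @param fits A list of `kinetic_fit` objects (see [kinetic_fits]).
#' @return The winning `kinetic_fit`.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "kinetic_fit")))
  ok <- !vapply(fits, `[[`, logical(1), "degenerate")
  if (!any(ok)) {
    stop("all candidate fits are degenerate; cannot select a model",
         call. = FALSE)
  }
  fits <- fits[ok]
  r2a <- vapply(fits, `[[`, numeric(1), "r2_adj")
  npar <- vapply(fits, `[[`, numeric(1), "n_par")
  model_rank <- match(vapply(fits, `[[`, character(1), "model"),
                      c("zero_order", "higuchi", "first_order"))
  fits[[order(-r2a, npar, model_rank)[1]]]
}

#' Steady-state flux and lag time from the linear portion
#'
#' Identifies the "linear portion" of a cumulative permeation profile as the
#' longest contiguous terminal window (ending at the last sample) of at
#' least `min_window` points whose ordinary least-squares fit reaches
#' \eqn{r^2 \ge} `r2_threshold`; if no window qualifies, the terminal
#' `min_window` points are used. The steady-state flux J is the slope of
#' that window's line (floored at 0), and the lag time \eqn{T_l} is the
#' line's x-intercept (floored at 0).
#'
#' @param profile A `cumulative_profile`.
#' @param r2_threshold Minimum window r-squared to count as linear
#'   (default 0.99).
#' @param min_window Minimum window length (default 3 points).
#' @return A list with `flux_j` (ug/(cm2 h)), `lag_tl` (h), `window`
#'   (indices into the profile), `window_times`, `slope`, `intercept`,
#'   `r2`, and `qualified` (whether any window met the threshold).
#' @examples
#' p <- structure(list(times_h = c(1, 2, 4), q_ug_cm2 = 10 * (c(1, 2, 4) - 0.5),
#'                     cell_id = "c1", n_samples = 3L),
#'                class = "cumulative_profile")
#' steady_state_flux(p)  # J = 10, Tl = 0.5
#' @export
steady_state_flux <- function(profile, r2_threshold = 0.99, min_window = 3) {
  stopifnot(inherits(profile, "cumulative_profile"))
  t <- profile$times_h
  q <- profile$q_ug_cm2
  n <- length(t)
  if (n < min_window) {
    stop("steady-state flux needs at least ", min_window, " points",
         call. = FALSE)
  }
  window_fit <- function(idx) {
    ti <- t[idx]; qi <- q[idx]
    fit <- stats::lm.fit(cbind(1, ti), qi)
    ss_tot <- sum((qi - mean(qi))^2)
    r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
    list(intercept = unname(fit$coefficients[1]),
         slope = unname(fit$coefficients[2]), r2 = r2)
  }
  chosen <- NULL
  qualified <- FALSE
  for (start in seq_len(n - min_window + 1)) {  # longest window first
    f <- window_fit(start:n)
    if (!is.na(f$r2) && f$r2 >= r2_threshold) {
      chosen <- c(f, list(idx = start:n))
      qualified <- TRUE
      break
    }
  }
  if (is.null(chosen)) {
    idx <- (n - min_window + 1):n
    chosen <- c(window_fit(idx), list(idx = idx))
  }
  slope <- chosen$slope
  j <- max(slope, 0)
  lag <- if (slope > 0) max(-chosen$intercept / slope, 0) else 0
  list(flux_j = j, lag_tl = lag, window = chosen$idx,
       window_times = t[chosen$idx], slope = slope,
       intercept = chosen$intercept, r2 = chosen$r2, qualified = qualified)
}

#' Permeability coefficient from steady-state flux
#'
#' \eqn{K_p = J / C_0}: the steady-state flux (ug/(cm2 h)) divided by the
#' donor concentration (ug/mL = ug/cm3), giving cm/h.
#'
#' @param flux_j Steady-state flux J in ug/(cm2 h).
#' @param dose A [dose_spec()] providing `c0_ug_ml`, or a bare donor
#'   concentration in ug/mL.
#' @return Kp in cm/h.
#' @examples
#' permeability_coefficient(547, dose_spec())  # 0.0547 cm/h
#' @export
permeability_coefficient <- function(flux_j, dose = dose_spec()) {
  c0 <- if (inherits(dose, "dose_spec")) dose$c0_ug_ml else as.numeric(dose)
  if (!(c0 > 0)) stop("donor concentration must be > 0", call. = FALSE)
  flux_j / c0
}

#' Maximum concentration and its time
#'
#' Peak observed quantities of a permeation run: the maximum measured
#' receptor concentration (Cmax, ug/mL), the maximum cumulative amount per
#' area (Qmax, ug/cm2) and the earliest sampling time at which the
#' concentration maximum is attained (tmax, h). Cmax is reported in ug/mL
#' and per-area units are available through Qmax because both conventions
#' are in common use.
#'
#' @param series The measured [conc_series()].
#' @param profile The matching `cumulative_profile` (optional; if missing,
#'   `qmax` is `NA`).
#' @return A list with `cmax_ug_ml`, `qmax_ug_cm2`, `tmax_h`.
#' @export
cmax_tmax <- function(series, profile = NULL) {
  stopifnot(inherits(series, "conc_series"), length(series$conc_ug_ml) >= 1)
  i <- which.max(series$conc_ug_ml)  # earliest index at the maximum
  list(cmax_ug_ml = series$conc_ug_ml[i],
       qmax_ug_cm2 = if (is.null(profile)) NA_real_ else
         max(profile$q_ug_cm2),
       tmax_h = series$times_h[i])
}

#' Trapezoidal area under the cumulative profile
#'
#' Linear trapezoid rule over the sampled times; exact on piecewise-linear
#' profiles. Units ug h/cm2.
#'
#' @param profile A `cumulative_profile` with at least 2 points.
#' @return The area under Q(t) over the sampled interval.
#' @export
auc_trapezoid <- function(profile) {
  stopifnot(inherits(profile, "cumulative_profile"))
  t <- profile$times_h
  q <- profile$q_ug_cm2
  if (length(t) < 2) stop("AUC needs at least 2 points", call. = FALSE)
  sum(diff(t) * (q[-1] + q[-length(q)]) / 2)
}

#' Full kinetic analysis of one permeation run
#'
#' Runs the complete per-cell pipeline: optional LoQ censoring, the
#' sampling-corrected cumulative amount, the three candidate kinetic fits
#' with adjusted-R2 selection, steady-state flux from the linear portion,
#' permeability coefficient, lag times (both the linear-portion x-intercept
#' and, when available, the zero-order model's own lag), peak quantities
#' and trapezoidal AUC.
#'
#' @param series A [conc_series()].
#' @param cell A [franz_cell()].
#' @param dose A [dose_spec()].
#' @param censor_policy Censoring policy passed to [censor_below_loq()]
#'   when the series' analyte defines an LoQ; `"keep"` skips censoring.
#' @param r2_threshold,min_window Linear-portion detection settings, see
#'   [steady_state_flux()].
#' @param models Candidate models to fit (default all three).
#' @return An object of class `permeation_parameters`: `flux_j`
#'   (ug/(cm2 h)), `kp` (cm/h, = J/C0 exactly), `lag_tl` (h, linear
#'   portion), `lag_tl_model` (h, zero-order fit), `cmax` (ug/mL), `qmax`
#'   (ug/cm2), `tmax` (h), `auc` (ug h/cm2), `selected_model`, `r2`,
#'   `r2_adj`, plus labels, the per-model `fits` and the `profile`.
#' @examples
#' s <- conc_series("c1", c(0, 0.5, 1, 2, 4), c(0, 60, 130, 260, 510),
#'                  membrane = "nuclepore", analyte = "caffeine")
#' p <- fit_permeation(s)
#' p$kp * 1e3  # Kp in 1e-3 cm/h
#' @export
fit_permeation <- function(series, cell = franz_cell(), dose = dose_spec(),
                           censor_policy = "keep",
                           r2_threshold = 0.99, min_window = 3,
                           models = c("zero_order", "first_order",
                                      "higuchi")) {
  stopifnot(inherits(series, "conc_series"))
  if (censor_policy != "keep" && !is.null(series$analyte) &&
      !is.na(series$analyte$loq)) {
    series <- censor_below_loq(series, policy = censor_policy)
  }
  profile <- cumulative_amount(series, cell)
  fitters <- list(zero_order = fit_zero_order,
                  first_order = fit_first_order,
                  higuchi = fit_higuchi)
  fits <- lapply(fitters[models], function(f) f(profile))
  best <- tryCatch(select_model(fits), error = function(e) NULL)
  ss <- steady_state_flux(profile, r2_threshold = r2_threshold,
                          min_window = min_window)
  peaks <- cmax_tmax(series, profile)
  lag_model <- if (!is.null(fits$zero_order) &&
                   !fits$zero_order$degenerate) {
    fits$zero_order$parameters$lag_tl
  } else NA_real_
  structure(
    list(cell_id = series$cell_id, membrane = series$membrane,
         formulation = series$formulation,
         analyte = if (is.null(series$analyte)) NA_character_ else
           series$analyte$name,
         selected_model = if (is.null(best)) "degenerate" else best$model,
         flux_j = ss$flux_j,
         kp = permeability_coefficient(ss$flux_j, dose),
         lag_tl = ss$lag_tl, lag_tl_model = lag_model,
         cmax = peaks$cmax_ug_ml, qmax = peaks$qmax_ug_cm2,
         tmax = peaks$tmax_h,
         auc = auc_trapezoid(profile),
         r2 = if (is.null(best)) NA_real_ else best$r2,
         r2_adj = if (is.null(best)) NA_real_ else best$r2_adj,
         fits = fits, profile = profile, linear_window = ss),
    class = "permeation_parameters"
  )
}

#' @export
print.permeation_parameters <- function(x, ...) {
  cat(sprintf("Permeation parameters for cell '%s' (%s on %s)\n",
              x$cell_id, x$analyte, x$membrane))
  cat(sprintf("  model: %s (R2 = %.4f, adj = %.4f)\n", x$selected_model,
              x$r2, x$r2_adj))
  cat(sprintf("  J = %.4g ug/(cm2 h), Kp = %.4g cm/h, Tl = %.3g h\n",
              x$flux_j, x$kp, x$lag_tl))
  cat(sprintf("  Cmax = %.4g ug/mL, Qmax = %.4g ug/cm2, tmax = %g h, ",
              x$cmax, x$qmax, x$tmax))
  cat(sprintf("AUC = %.4g ug h/cm2\n", x$auc))
  invisible(x)
}
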