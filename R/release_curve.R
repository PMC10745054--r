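#' Censor receptor concentrations below the limit of quantification
#'
#' Applies the assay's LoQ to a measured series. Readings strictly below the
#' LoQ are replaced according to `policy`: set to zero (default), set to
#' half the LoQ, or kept as measured. A reading exactly at the LoQ is always
#' kept. The number of replacements is recorded in the series metadata
#' (`n_censored`).
#'
#' @param series A [conc_series()].
#' @param analyte An [analyte_spec()] with a defined `loq`; defaults to the
#'   analyte attached to the series.
#' @param policy One of `"zero"`, `"half_loq"`, `"keep"`.
#' @return The censored `conc_series`.
#' @export
censor_below_loq <- function(series, analyte = series$analyte,
                             policy = c("zero", "half_loq", "keep")) {
  stopifnot(inherits(series, "conc_series"))
  policy <- tryCatch(match.arg(policy),
                     error = function(e) stop(
                       "unknown censoring policy '", policy[1],
                       "' (use zero, half_loq or keep)", call. = FALSE))
  if (is.null(analyte) || is.na(analyte$loq)) {
    stop("analyte LoQ is not defined; cannot censor", call. = FALSE)
  }
  if (policy == "keep") {
    series$metadata$n_censored <- 0L
    return(series)
  }
  below <- series$conc_ug_ml < analyte$loq
  series$conc_ug_ml[below] <- switch(policy,
                                     zero = 0,
                                     half_loq = analyte$loq / 2)
  series$metadata$n_censored <- sum(below)
  series
}

#' Sampling-corrected cumulative amount permeated
#'
#' Converts measured receptor concentrations into the cumulative amount of
#' analyte that has crossed the membrane per unit area, correcting for the
#' analyte removed in earlier aliquots under a withdraw-and-replace sampling
#' protocol:
#'
#' \deqn{Q_n = \frac{C_n V_c + \sum_{i=1}^{n-1} C_i V_s}{A}}
#'
#' where \eqn{C_n} is the measured concentration at sample n (ug/mL),
#' \eqn{V_c} the receptor volume (mL), \eqn{V_s} the aliquot volume (mL) and
#' \eqn{A} the diffusion area (cm2). The correction sum runs over all
#' strictly earlier samples, including a time-0 sample when present. This is
#' exact mass bookkeeping: each withdrawn aliquot removes \eqn{C_i V_s} of
#' analyte that the current receptor concentration can no longer see.
#'
#' Negative measured concentrations (instrument noise) are clipped to zero
#' before the correction, with a warning.
#'
#' @param series A [conc_series()] (censor with [censor_below_loq()] first
#'   if the assay reports an LoQ).
#' @param cell A [franz_cell()]. Series times must be a subset of (or align
#'   with) the cell's schedule in the sense of being the actual sampled
#'   times; only the series' own times are used.
#' @return An object of class `cumulative_profile`: list with `cell_id`,
#'   `times_h`, `q_ug_cm2`, `n_samples`, and the originating labels.
#' @examples
#' s <- conc_series("c1", c(0.5, 1), c(10, 20))
#' cumulative_amount(s, franz_cell())$q_ug_cm2  # 16.129, 33.333 ug/cm2
#' @export
cumulative_amount <- function(series, cell = franz_cell()) {
  stopifnot(inherits(series, "conc_series"), inherits(cell, "franz_cell"))
  vc <- cell$receptor_volume_ml
  vs <- cell$sample_volume_ml
  a <- cell$area_cm2
  if (vs >= vc) {
    stop("sample volume must be smaller than the receptor volume",
         call. = FALSE)
  }
  conc <- series$conc_ug_ml
  if (any(conc < 0)) {
    warning(sum(conc < 0), " negative concentration(s) clipped to 0")
    conc <- pmax(conc, 0)
  }
  # running sum of earlier concentrations: sum_{i<n} C_i
  prior <- c(0, cumsum(conc)[-length(conc)])
  q <- (conc * vc + prior * vs) / a
  structure(
    list(cell_id = series$cell_id,
         times_h = series$times_h,
         q_ug_cm2 = q,
         n_samples = length(q),
         membrane = series$membrane,
         formulation = series$formulation,
         analyte = if (is.null(series$analyte)) NA_character_ else
           series$analyte$name),
    class = "cumulative_profile"
  )
}

#' @export
print.cumulative_profile <- function(x, ...) {
  cat(sprintf("Cumulative permeation profile '%s' (%d samples)\n",
              x$cell_id, x$n_samples))
  print(data.frame(time_h = x$times_h, q_ug_cm2 = x$q_ug_cm2),
        row.names = FALSE)
  invisible(x)
}

#' Cumulative permeation as percent of applied dose
#'
#' Expresses a cumulative profile as the percentage of the applied donor
#' mass recovered in the receptor:
#' \eqn{\%_n = Q_n A / m_{applied} \times 100}.
#'
#' @param profile A `cumulative_profile` from [cumulative_amount()].
#' @param dose A [dose_spec()] (`applied_mass_ug` > 0).
#' @param cell The [franz_cell()] providing the area A.
#' @param reference Normalise by the `"applied"` dose (default) or by the
#'   `"recovered"` maximum of the profile (the final cumulative amount);
#'   the latter rescales the profile to end at 100%.
#' @return An object of class `percent_profile`: list with `times_h`,
#'   `percent` and `reference`.
#' @examples
#' s <- conc_series("c1", c(0, 0.5, 4), c(0, 200, 507))
#' q <- cumulative_amount(s, franz_cell())
#' percent_of_dose(q, dose_spec(), franz_cell())$percent
#' @export
percent_of_dose <- function(profile, dose = dose_spec(), cell = franz_cell(),
                            reference = c("applied", "recovered")) {
  stopifnot(inherits(profile, "cumulative_profile"),
            inherits(dose, "dose_spec"), inherits(cell, "franz_cell"))
  reference <- match.arg(reference)
  denom <- switch(reference,
                  applied = dose$applied_mass_ug,
                  recovered = max(profile$q_ug_cm2) * cell$area_cm2)
  if (!(denom > 0)) {
    stop("reference mass must be positive (all-zero profile with ",
         "reference = 'recovered'?)", call. = FALSE)
  }
  structure(
    list(times_h = profile$times_h,
         percent = profile$q_ug_cm2 * cell$area_cm2 / denom * 100,
         reference = reference),
    class = "percent_profile"
  )
}
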