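#' Franz diffusion cell geometry and sampling protocol
#'
#' Bundles the constants of a static Franz diffusion cell experiment: the
#' receptor (acceptor) compartment volume, the aliquot volume withdrawn and
#' replaced at each sampling time, the orifice (diffusion) area, and the
#' sampling schedule. These constants are shared by the cumulative-release
#' correction, the kinetic fits and the simulator.
#'
#' Defaults are the protocol used throughout this package's reference
#' analyses: a 3 mL cell with a 1.86 cm2 orifice, 0.2 mL aliquots, sampled at
#' 0, 0.5, 1, 2 and 4 h.
#'
#' All internal computation in the package uses a single unit system:
#' micrograms, ug/mL, mL, cm2 and hours. TMWL values are kept separately in
#' g/(m2 h) and never mixed into this system.
#'
#' @param receptor_volume_ml Receptor compartment volume Vc (mL), > 0.
#' @param sample_volume_ml Withdrawn aliquot volume Vs (mL), 0 <= Vs < Vc.
#' @param area_cm2 Orifice (diffusion) area A (cm2), > 0.
#' @param times_h Sampling schedule (h), strictly increasing, first >= 0.
#' @return An object of class `franz_cell`.
#' @examples
#' franz_cell()
#' franz_cell(receptor_volume_ml = 5, sample_volume_ml = 0.3, area_cm2 = 2.54,
#'            times_h = c(0, 1, 2, 4, 8, 24))
#' @export
franz_cell <- function(receptor_volume_ml = 3,
                       sample_volume_ml = 0.2,
                       area_cm2 = 1.86,
                       times_h = c(0, 0.5, 1, 2, 4)) {
  stopifnot(is.numeric(receptor_volume_ml), length(receptor_volume_ml) == 1L,
            is.numeric(sample_volume_ml), length(sample_volume_ml) == 1L,
            is.numeric(area_cm2), length(area_cm2) == 1L,
            is.numeric(times_h), length(times_h) >= 1L)
  if (!(receptor_volume_ml > 0)) {
    stop("receptor_volume_ml must be > 0", call. = FALSE)
  }
  if (sample_volume_ml < 0 || sample_volume_ml >= receptor_volume_ml) {
    stop("sample_volume_ml must satisfy 0 <= Vs < Vc: replacing more than ",
         "the receptor volume is physically meaningless", call. = FALSE)
  }
  if (!(area_cm2 > 0)) stop("area_cm2 must be > 0", call. = FALSE)
  if (times_h[1] < 0 || any(diff(times_h) <= 0)) {
    stop("times_h must be strictly increasing with first time >= 0",
         call. = FALSE)
  }
  structure(
    list(receptor_volume_ml = as.numeric(receptor_volume_ml),
         sample_volume_ml = as.numeric(sample_volume_ml),
         area_cm2 = as.numeric(area_cm2),
         times_h = as.numeric(times_h)),
    class = "franz_cell"
  )
}

#' @export
print.franz_cell <- function(x, ...) {
  cat(sprintf("Franz cell: Vc = %g mL, Vs = %g mL, A = %g cm2\n",
              x$receptor_volume_ml, x$sample_volume_ml, x$area_cm2))
  cat("  sampling times (h):", paste(x$times_h, collapse = ", "), "\n")
  invisible(x)
}

#' Applied dose specification
#'
#' The donor-phase dose: applied volume and donor concentration C0. The
#' applied mass is derived as volume x C0. The default corresponds to a
#' pseudoinfinite dose of 300 uL of a 1% (w/v) solution, i.e.
#' C0 = 10,000 ug/mL and 3,000 ug applied.
#'
#' @param applied_volume_ml Applied donor volume (mL).
#' @param c0_ug_ml Donor concentration C0 (ug/mL), > 0.
#' @return An object of class `dose_spec` with fields `applied_volume_ml`,
#'   `c0_ug_ml` and the derived `applied_mass_ug`.
#' @examples
#' dose_spec()               # 300 uL of a 1% w/v solution -> 3000 ug
#' dose_spec(0.5, 20000)
#' @export
dose_spec <- function(applied_volume_ml = 0.3, c0_ug_ml = 10000) {
  stopifnot(is.numeric(applied_volume_ml), length(applied_volume_ml) == 1L,
            is.numeric(c0_ug_ml), length(c0_ug_ml) == 1L)
  if (!(c0_ug_ml > 0)) stop("c0_ug_ml must be > 0", call. = FALSE)
  if (!(applied_volume_ml > 0)) {
    stop("applied_volume_ml must be > 0", call. = FALSE)
  }
  structure(
    list(applied_volume_ml = as.numeric(applied_volume_ml),
         c0_ug_ml = as.numeric(c0_ug_ml),
         applied_mass_ug = as.numeric(applied_volume_ml) * as.numeric(c0_ug_ml)),
    class = "dose_spec"
  )
}

#' Analyte metadata
#'
#' Identity and assay metadata for one permeant: lipophilicity (log Ko/w),
#' molecular weight, and the HPLC assay's limits of detection and
#' quantification used by the censoring step.
#'
#' @param name Analyte identifier.
#' @param log_kow Octanol-water partition coefficient, log10 scale.
#' @param mw Molecular weight (Da), > 0.
#' @param lod Limit of detection (ug/mL).
#' @param loq Limit of quantification (ug/mL), >= lod.
#' @return An object of class `analyte_spec`.
#' @examples
#' analyte_spec("caffeine", log_kow = -0.1, mw = 194.2, lod = 0.82, loq = 2.49)
#' @export
analyte_spec <- function(name, log_kow = NA_real_, mw = NA_real_,
                         lod = 0, loq = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.na(mw) && mw <= 0) stop("mw must be > 0", call. = FALSE)
  if (!is.na(lod) && !is.na(loq) && lod > loq) {
    stop("lod must be <= loq", call. = FALSE)
  }
  structure(
    list(name = name, log_kow = as.numeric(log_kow), mw = as.numeric(mw),
         lod = as.numeric(lod), loq = as.numeric(loq)),
    class = "analyte_spec"
  )
}

#' Receptor concentration time course for one diffusion cell
#'
#' The measured receptor-compartment concentrations of one analyte in one
#' Franz cell over the sampling schedule. This is the raw input to the
#' sampling-corrected cumulative-amount calculation.
#'
#' @param cell_id Cell identifier.
#' @param times_h Sampling times (h), strictly increasing.
#' @param conc_ug_ml Measured receptor concentrations (ug/mL), one per time;
#'   must be non-negative (clip or censor upstream).
#' @param membrane Membrane label (e.g. `"nuclepore"`, `"sublingual_mucosa"`).
#' @param formulation Formulation label applied to the membrane, or `NA` for
#'   an unmodified membrane.
#' @param analyte An [analyte_spec()] or a bare analyte name.
#' @param metadata Optional named list of extra per-cell metadata.
#' @return An object of class `conc_series`.
#' @examples
#' conc_series("cell1", times_h = c(0, 0.5, 1, 2, 4),
#'             conc_ug_ml = c(0, 120, 260, 420, 500),
#'             membrane = "nuclepore", analyte = "caffeine")
#' @export
conc_series <- function(cell_id, times_h, conc_ug_ml,
                        membrane = NA_character_,
                        formulation = NA_character_,
                        analyte = NULL,
                        metadata = list()) {
  stopifnot(length(times_h) == length(conc_ug_ml), length(times_h) >= 1L)
  if (any(diff(times_h) <= 0)) {
    stop("times_h must be strictly increasing", call. = FALSE)
  }
  if (any(conc_ug_ml < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (is.character(analyte)) analyte <- analyte_spec(analyte)
  structure(
    list(cell_id = as.character(cell_id),
         times_h = as.numeric(times_h),
         conc_ug_ml = as.numeric(conc_ug_ml),
         membrane = as.character(membrane),
         formulation = as.character(formulation),
         analyte = analyte,
         metadata = metadata),
    class = "conc_series"
  )
}

#' @export
print.conc_series <- function(x, ...) {
  an <- if (is.null(x$analyte)) "?" else x$analyte$name
  cat(sprintf("Concentration series '%s' (%s on %s), %d samples\n",
              x$cell_id, an, x$membrane, length(x$times_h)))
  print(data.frame(time_h = x$times_h, conc_ug_ml = x$conc_ug_ml),
        row.names = FALSE)
  invisible(x)
}
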