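#' Read a permeation time-course table
#'
#' Reads a delimited text file of receptor concentrations (one row per cell
#' and sampling time) and splits it into one [conc_series()] per cell.
#' Required columns: `cell_id`, `membrane`, `formulation`, `analyte`,
#' `time_h`, `conc_ug_ml`. Rows are sorted by time within each cell; any
#' additional columns are preserved in the series metadata.
#'
#' @param path Path to a CSV file (comma separated, header row, "." decimal).
#' @param config A [franz_cell()]; attached to the result as an attribute so
#'   downstream stages use a consistent protocol.
#' @return A list of `conc_series`, one per `cell_id`, in first-appearance
#'   order, with attribute `"franz_cell"`.
#' @export
read_timecourse_table <- function(path, config = franz_cell()) {
  stopifnot(inherits(config, "franz_cell"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("cell_id", "membrane", "formulation", "analyte",
                "time_h", "conc_ug_ml")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("time-course table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & nzchar(trimws(df[[col]])))
    if (length(bad) || anyNA(x)) {
      row <- if (length(bad)) bad[1] else which(is.na(x))[1]
      stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                   col, row, df[[col]][row]), call. = FALSE)
    }
    x
  }
  df$time_h <- num("time_h")
  df$conc_ug_ml <- num("conc_ug_ml")
  neg <- which(df$conc_ug_ml < 0)
  if (length(neg)) {
    stop(sprintf("negative concentration at data row %d (%g ug/mL); ",
                 neg[1], df$conc_ug_ml[neg[1]]),
         "clip or censor measurements before import", call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  ids <- unique(df$cell_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$cell_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_h), , drop = FALSE]
    meta <- if (length(extra)) as.list(rows[1, extra, drop = FALSE]) else list()
    conc_series(cell_id = id,
                times_h = rows$time_h,
                conc_ug_ml = rows$conc_ug_ml,
                membrane = rows$membrane[1],
                formulation = rows$formulation[1],
                analyte = rows$analyte[1],
                metadata = meta)
  })
  names(out) <- ids
  attr(out, "franz_cell") <- config
  out
}

#' Write a permeation time-course table
#'
#' Inverse of [read_timecourse_table()]: one row per (cell, time).
#'
#' @param series A list of [conc_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse_table <- function(series, path) {
  rows <- lapply(series, function(s) {
    data.frame(cell_id = s$cell_id,
               membrane = s$membrane,
               formulation = s$formulation,
               analyte = if (is.null(s$analyte)) NA_character_ else s$analyte$name,
               time_h = s$times_h,
               conc_ug_ml = s$conc_ug_ml,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TMWL panel table
#'
#' Reads a transmucosal/transmembranal water loss panel: one row per
#' (membrane, formulation) measurement in g/(m2 h). Control rows (untreated
#' membrane) carry the formulation label `"control"` and are flagged; they
#' are required for [percent_reduction()]. Duplicate (membrane, formulation)
#' rows are kept as replicates.
#'
#' @param path Path to a CSV with columns `membrane`, `formulation`, `tmwl`
#'   and optionally `class` (formulation class) and `replicate`.
#' @param require_control Error if a membrane has no control row
#'   (default `TRUE`; a panel without controls supports correlation but not
#'   percent reduction).
#' @return A data frame of class `tmwl_panel` with columns `membrane`,
#'   `formulation`, `class`, `replicate`, `tmwl`, `is_control`.
#' @export
read_tmwl_table <- function(path, require_control = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("membrane", "formulation", "tmwl")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("TMWL table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    out <- data.frame(membrane = character(), formulation = character(),
                      class = character(), replicate = integer(),
                      tmwl = numeric(), is_control = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("tmwl_panel", "data.frame")
    return(out)
  }
  df$tmwl <- suppressWarnings(as.numeric(df$tmwl))
  if (anyNA(df$tmwl)) {
    stop(sprintf("non-numeric tmwl value at data row %d",
                 which(is.na(df$tmwl))[1]), call. = FALSE)
  }
  if (any(df$tmwl < 0)) {
    stop("tmwl values must be non-negative", call. = FALSE)
  }
  if (is.null(df$class)) df$class <- NA_character_
  if (is.null(df$replicate)) df$replicate <- 1L
  df$is_control <- df$formulation == "control"
  if (require_control) {
    no_ctrl <- setdiff(unique(df$membrane), unique(df$membrane[df$is_control]))
    if (length(no_ctrl)) {
      stop("no control row for membrane(s): ",
           paste(no_ctrl, collapse = ", "),
           " (needed to compute percent reduction)", call. = FALSE)
    }
  }
  out <- df[, c("membrane", "formulation", "class", "replicate",
                "tmwl", "is_control")]
  class(out) <- c("tmwl_panel", "data.frame")
  out
}

#' Write a permeation parameters table
#'
#' Writes one row per cell of fitted permeation parameters, in a fixed
#' column order, with full numeric precision (15 significant digits) so that
#' a read-back reproduces the values to better than 1e-12 relative.
#'
#' Column order: `cell_id`, `membrane`, `formulation`, `analyte`, `model`,
#' `flux_j_ug_cm2_h`, `kp_cm_h`, `lag_tl_h`, `lag_tl_model_h`, `cmax_ug_ml`,
#' `qmax_ug_cm2`, `tmax_h`, `auc_ug_h_cm2`, `r2`, `r2_adj`.
#'
#' @param params A list of `permeation_parameters` objects (see
#'   [fit_permeation()]) or a data frame already in the output layout.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameters_table <- function(params, path) {
  cols <- c("cell_id", "membrane", "formulation", "analyte", "model",
            "flux_j_ug_cm2_h", "kp_cm_h", "lag_tl_h", "lag_tl_model_h",
            "cmax_ug_ml", "qmax_ug_cm2", "tmax_h", "auc_ug_h_cm2",
            "r2", "r2_adj")
  df <- if (is.data.frame(params)) params else parameters_table(params)
  if (nrow(df) == 0) {
    df <- df[, intersect(cols, names(df)), drop = FALSE]
    for (nm in setdiff(cols, names(df))) df[[nm]] <- numeric(0)
  }
  df <- df[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collect permeation parameters into a data frame
#'
#' @param params A list of `permeation_parameters` objects.
#' @return A data frame with one row per element of `params`.
#' @export
parameters_table <- function(params) {
  if (inherits(params, "permeation_parameters")) params <- list(params)
  rows <- lapply(params, function(p) {
    data.frame(cell_id = p$cell_id, membrane = p$membrane,
               formulation = p$formulation, analyte = p$analyte,
               model = p$selected_model,
               flux_j_ug_cm2_h = p$flux_j, kp_cm_h = p$kp,
               lag_tl_h = p$lag_tl, lag_tl_model_h = p$lag_tl_model,
               cmax_ug_ml = p$cmax, qmax_ug_cm2 = p$qmax, tmax_h = p$tmax,
               auc_ug_h_cm2 = p$auc, r2 = p$r2, r2_adj = p$r2_adj,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(cell_id = character(), membrane = character(),
                      formulation = character(), analyte = character(),
                      model = character(), flux_j_ug_cm2_h = numeric(),
                      kp_cm_h = numeric(), lag_tl_h = numeric(),
                      lag_tl_model_h = numeric(), cmax_ug_ml = numeric(),
                      qmax_ug_cm2 = numeric(), tmax_h = numeric(),
                      auc_ug_h_cm2 = numeric(), r2 = numeric(),
                      r2_adj = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a study configuration file
#'
#' Parses a YAML configuration with keys `cell{vc_ml, vs_ml, area_cm2,
#' times_h}`, `dose{volume_ml, c0_ug_ml}` and
#' `analytes[{name, log_kow, mw, lod, loq}]`. Missing `cell`/`dose` blocks
#' fall back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `cell` ([franz_cell()]), `dose`
#'   ([dose_spec()]) and `analytes` (named list of [analyte_spec()]).
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cell <- if (is.null(cfg$cell)) franz_cell() else
    franz_cell(receptor_volume_ml = cfg$cell$vc_ml %||% 3,
               sample_volume_ml = cfg$cell$vs_ml %||% 0.2,
               area_cm2 = cfg$cell$area_cm2 %||% 1.86,
               times_h = unlist(cfg$cell$times_h %||% c(0, 0.5, 1, 2, 4)))
  dose <- if (is.null(cfg$dose)) dose_spec() else
    dose_spec(applied_volume_ml = cfg$dose$volume_ml %||% 0.3,
              c0_ug_ml = cfg$dose$c0_ug_ml %||% 10000)
  analytes <- lapply(cfg$analytes %||% list(), function(a) {
    analyte_spec(a$name, log_kow = a$log_kow %||% NA_real_,
                 mw = a$mw %||% NA_real_,
                 lod = a$lod %||% 0, loq = a$loq %||% 0)
  })
  names(analytes) <- vapply(analytes, `[[`, character(1), "name")
  list(cell = cell, dose = dose, analytes = analytes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference TMWL panel (two-membrane waterproofing screen)
#'
#' The packaged reference panel of transmucosal water loss measurements:
#' 16 waterproofing formulations (5 hydrophobic, 5 hydrophilic, 6 liposomal)
#' applied to a Nuclepore polycarbonate membrane and to porcine sublingual
#' mucosa, plus the untreated controls (one per membrane); 34 records of
#' reported means in g/(m2 h).
#'
#' @return A `tmwl_panel` data frame (see [read_tmwl_table()]).
#' @examples
#' panel <- tmwl_reference_panel()
#' percent_reduction(panel, "nuclepore")
#' @export
tmwl_reference_panel <- function() {
  read_tmwl_table(system.file("extdata", "tmwl_reference_panel.csv",
                              package = "permeatr", mustWork = TRUE))
}

#' Reference analyte metadata
#'
#' Assay and physicochemical metadata for the seven reference permeants
#' (four drugs, three biocides): log Ko/w, molecular weight, and HPLC limits
#' of detection/quantification in ug/mL.
#'
#' @return A named list of [analyte_spec()] objects.
#' @examples
#' analyte_reference()[["caffeine"]]$loq
#' @export
analyte_reference <- function() {
  df <- utils::read.csv(system.file("extdata", "analyte_reference.csv",
                                    package = "permeatr", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    analyte_spec(df$name[i], log_kow = df$log_kow[i], mw = df$mw[i],
                 lod = df$lod[i], loq = df$loq[i])
  })
  names(out) <- df$name
  out
}
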