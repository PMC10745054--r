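#' Generative Fickian membrane model
#'
#' A homogeneous membrane characterised by its diffusivity D (cm2/h),
#' thickness h (cm) and donor/membrane partition coefficient K
#' (dimensionless). Under sink conditions and a constant donor
#' concentration C0, such a membrane has steady-state flux
#' \eqn{J_\infty = K D C_0 / h} and lag time \eqn{T_{lag} = h^2 / (6 D)}.
#'
#' @param diffusivity_d Diffusivity D (cm2/h), > 0.
#' @param thickness_h Membrane thickness h (cm), > 0.
#' @param partition_k Partition coefficient K, > 0.
#' @param label Membrane label.
#' @return An object of class `membrane_model` with the fields above plus
#'   the implied `kp_cm_h` (= K D / h) and `lag_h` (= h^2 / 6D).
#' @examples
#' m <- membrane_model(1e-4, 0.05, 1, "example")
#' m$lag_h  # 25/6 h
#' @export
membrane_model <- function(diffusivity_d, thickness_h, partition_k = 1,
                           label = "membrane") {
  stopifnot(diffusivity_d > 0, thickness_h > 0, partition_k > 0)
  structure(
    list(diffusivity_d = diffusivity_d, thickness_h = thickness_h,
         partition_k = partition_k, label = label,
         kp_cm_h = partition_k * diffusivity_d / thickness_h,
         lag_h = thickness_h^2 / (6 * diffusivity_d)),
    class = "membrane_model"
  )
}

#' Illustrative membrane presets
#'
#' Order-of-magnitude presets for the three membrane types used in the
#' package's reference analyses. They are chosen so that the track-etched
#' polycarbonate surrogate (`"nuclepore"`) has a permeability coefficient
#' of order 50e-3 cm/h, the sublingual mucosa of order 35e-3 cm/h, and
#' split-thickness skin of order 2.5e-3 cm/h — spanning the range observed
#' for small-molecule permeants. Lag times are kept well inside the 4 h
#' sampling horizon of the standard protocol, so the steady-state linear
#' portion the analysis estimates actually exists in the sampled window.
#' The transport constants are illustrative placeholders, not fitted
#' tissue properties.
#'
#' @param name One of `"nuclepore"`, `"mucosa"`, `"skin"`.
#' @return A [membrane_model()].
#' @examples
#' membrane_preset("nuclepore")$kp_cm_h * 1e3  # ~50 (1e-3 cm/h)
#' @export
membrane_preset <- function(name = c("nuclepore", "mucosa", "skin")) {
  name <- match.arg(name)
  switch(name,
    # thin porous polycarbonate: negligible lag, high permeability
    nuclepore = membrane_model(3e-5, 6e-4, 1, "nuclepore"),
    # 500 um dermatomed mucosa: modest lag (~0.17 h)
    mucosa = membrane_model(2.5e-3, 0.05, 0.7, "sublingual_mucosa"),
    # 500 um split skin: strong partition-limited barrier, lag ~0.42 h
    skin = membrane_model(1e-3, 0.05, 0.125, "skin")
  )
}

#' Simulation configuration
#'
#' @param noise_cv Proportional measurement-noise coefficient of variation
#'   (>= 0). Noise is multiplicative Gaussian, truncated at -3 sigma so
#'   simulated concentrations stay non-negative for CV <= 1/3.
#' @param seed Integer root seed; all simulator randomness derives from it.
#' @param times_h Sampling times (h), strictly increasing.
#' @param n_terms Number of eigenfunction terms kept in the diffusion
#'   series (>= 20).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(noise_cv = 0.05, seed = 1,
                       times_h = c(0, 0.5, 1, 2, 4), n_terms = 50) {
  stopifnot(noise_cv >= 0, n_terms >= 20)
  if (any(diff(times_h) <= 0)) {
    stop("times_h must be strictly increasing", call. = FALSE)
  }
  structure(list(noise_cv = noise_cv, seed = as.integer(seed),
                 times_h = as.numeric(times_h),
                 n_terms = as.integer(n_terms)),
            class = "sim_config")
}

# Deterministic child-seed scheme: the i-th consumer of randomness under a
# root seed gets seed (root * 10007 + i) mod (2^31 - 1), so cells are
# independent and reproducible regardless of evaluation order.
child_seed <- function(root, counter) {
  as.integer((as.numeric(root) * 10007 + counter) %% 2147483647)
}

#' True cumulative diffusion profile through a membrane
#'
#' The exact transient solution for one-dimensional Fickian diffusion
#' through an initially drug-free membrane with a constant donor
#' concentration C0 on one face and a perfect sink on the other:
#'
#' \deqn{\frac{Q(t)}{A} = K h C_0 \left[\frac{D t}{h^2} - \frac{1}{6}
#'  - \frac{2}{\pi^2} \sum_{m \ge 1} \frac{(-1)^m}{m^2}
#'    e^{-D m^2 \pi^2 t / h^2}\right]}
#'
#' Its large-time asymptote has slope \eqn{K D C_0 / h} and time-intercept
#' \eqn{h^2/(6D)} — the steady-state flux and lag time the analysis stages
#' estimate. The eigenfunction series is truncated at `n_terms`; the
#' truncation tail at the earliest positive sampling time must be below
#' 1e-9 of the steady-state slope, otherwise an error asks for more terms.
#'
#' @param membrane A [membrane_model()].
#' @param c0_ug_ml Donor concentration C0 (ug/mL).
#' @param times_h Evaluation times (h), non-negative.
#' @param n_terms Series terms kept (default 50).
#' @return An object of class `true_profile`: list with `times_h`,
#'   `q_ug_cm2` (true cumulative amount per area), `membrane`, `c0_ug_ml`,
#'   `flux_inf` and `lag_h`.
#' @examples
#' m <- membrane_preset("mucosa")
#' diffusion_profile(m, 10000, c(0, 0.5, 1, 2, 4))$q_ug_cm2
#' @export
diffusion_profile <- function(membrane, c0_ug_ml, times_h, n_terms = 50) {
  stopifnot(inherits(membrane, "membrane_model"), c0_ug_ml > 0,
            all(times_h >= 0))
  d <- membrane$diffusivity_d
  h <- membrane$thickness_h
  k <- membrane$partition_k
  flux_inf <- k * d * c0_ug_ml / h
  tpos <- times_h[times_h > 0]
  if (length(tpos)) {
    tau_min <- d * pi^2 * min(tpos) / h^2
    # tail bound: sum_{m>M} e^{-tau m^2}/m^2 <= (pi^2/6) e^{-tau M^2}
    tail <- k * h * c0_ug_ml * (2 / pi^2) * (pi^2 / 6) *
      exp(-tau_min * n_terms^2)
    if (tail > 1e-9 * flux_inf) {
      stop("series truncation error exceeds tolerance at the earliest ",
           "sampling time; increase n_terms", call. = FALSE)
    }
  }
  m <- seq_len(n_terms)
  q <- vapply(times_h, function(t) {
    if (t == 0) return(0)
    s <- sum(((-1)^m / m^2) * exp(-d * m^2 * pi^2 * t / h^2))
    k * h * c0_ug_ml * (d * t / h^2 - 1 / 6 - (2 / pi^2) * s)
  }, numeric(1))
  q <- cummax(pmax(q, 0))  # guard residual truncation wiggle near t = 0
  structure(
    list(times_h = as.numeric(times_h), q_ug_cm2 = q,
         membrane = membrane, c0_ug_ml = c0_ug_ml,
         flux_inf = flux_inf, lag_h = membrane$lag_h),
    class = "true_profile"
  )
}

#' Simulate withdraw-and-replace Franz-cell sampling
#'
#' Turns a true cumulative diffusion profile into the concentrations an
#' analyst would actually measure under the standard protocol: at each
#' sampling time an aliquot Vs is withdrawn and replaced with fresh
#' receptor fluid, diluting the receptor. The simulator keeps an exact
#' receptor mass ledger — before sample n the receptor holds the true
#' transferred mass minus every previously withdrawn aliquot mass — and the
#' measured concentration is the true concentration times `(1 + eps)` with
#' `eps ~ Normal(0, noise_cv)` truncated at -3 sigma.
#'
#' The ledger (true concentrations, withdrawn masses, true cumulative
#' amounts) is retained in the series metadata as ground truth, so
#' [cumulative_amount()] can be checked against it exactly: with zero noise
#' the sampling-corrected Qn reproduces the true Q(t) to machine precision.
#'
#' @param true_profile A `true_profile` from [diffusion_profile()], defined
#'   at (at least) the cell's sampling times.
#' @param cell A [franz_cell()].
#' @param config A [sim_config()]; `config$noise_cv` and `config$seed`
#'   drive the measurement noise.
#' @param cell_id Identifier for the simulated cell.
#' @return A [conc_series()] whose `metadata` holds `true_q_ug_cm2`,
#'   `true_conc_ug_ml`, `withdrawn_ug` and `receptor_mass_ug`.
#' @export
simulate_franz_sampling <- function(true_profile, cell = franz_cell(),
                                    config = sim_config(),
                                    cell_id = "sim") {
  stopifnot(inherits(true_profile, "true_profile"),
            inherits(cell, "franz_cell"), inherits(config, "sim_config"))
  times <- cell$times_h
  idx <- match(times, true_profile$times_h)
  if (anyNA(idx)) {
    stop("true profile is not defined at all sampling times", call. = FALSE)
  }
  q_true <- true_profile$q_ug_cm2[idx]
  vc <- cell$receptor_volume_ml
  vs <- cell$sample_volume_ml
  a <- cell$area_cm2
  n <- length(times)
  eps <- if (config$noise_cv > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(config$seed)
    pmax(stats::rnorm(n, 0, config$noise_cv), -3 * config$noise_cv)
  } else rep(0, n)
  mass <- numeric(n)       # receptor mass just before sample n
  c_true <- numeric(n)
  withdrawn <- numeric(n)
  removed <- 0
  for (i in seq_len(n)) {
    mass[i] <- q_true[i] * a - removed
    c_true[i] <- mass[i] / vc
    withdrawn[i] <- c_true[i] * vs
    removed <- removed + withdrawn[i]
  }
  conc_series(cell_id = cell_id, times_h = times,
              conc_ug_ml = c_true * (1 + eps),
              membrane = true_profile$membrane$label,
              metadata = list(true_q_ug_cm2 = q_true,
                              true_conc_ug_ml = c_true,
                              withdrawn_ug = withdrawn,
                              receptor_mass_ug = mass,
                              true_flux_inf = true_profile$flux_inf,
                              true_lag_h = true_profile$lag_h,
                              noise_cv = config$noise_cv,
                              seed = config$seed))
}

#' Default formulation effects for the synthetic TMWL screen
#'
#' Multiplicative waterproofing effects (one per formulation, shared across
#' membranes) taken from the reference panel's surrogate-membrane ratios:
#' treated TMWL divided by the control TMWL. They span the three
#' formulation classes — strong hydrophobic barriers (down to ~0.03),
#' weak hydrophilic gels (~0.8-0.93) and intermediate liposomal films.
#'
#' @return A data frame with `formulation`, `class`, `multiplier`.
#' @export
default_formulation_effects <- function() {
  panel <- tmwl_reference_panel()
  red <- percent_reduction(panel, "nuclepore")
  data.frame(formulation = red$formulation, class = red$class,
             multiplier = red$treated_tmwl / red$control_tmwl,
             stringsAsFactors = FALSE)
}

#' Simulate a two-membrane TMWL waterproofing screen
#'
#' Generates a synthetic TMWL panel: each membrane has a baseline water
#' loss (defaults 80.8 and 72.4 g/(m2 h) for the surrogate and the tissue),
#' each formulation applies a shared multiplicative barrier effect, and
#' proportional noise is added per record:
#' `tmwl = baseline * multiplier * (1 + eps)`. Control rows use
#' multiplier 1. Because the formulation effect is shared across membranes,
#' the noise-free panel is exactly proportional between membranes and the
#' cross-membrane regression recovers R2 = 1.
#'
#' @param baselines Named numeric vector of per-membrane baseline TMWL
#'   (g/(m2 h)); >= 2 membranes.
#' @param effects A data frame with `formulation`, `class`, `multiplier`
#'   (see [default_formulation_effects()]).
#' @param config A [sim_config()] (noise and seed).
#' @param n_replicates Replicate measurements per (membrane, formulation).
#' @return A `tmwl_panel` data frame (as from [read_tmwl_table()]),
#'   controls included.
#' @export
simulate_tmwl_screen <- function(baselines = c(nuclepore = 80.8,
                                               sublingual_mucosa = 72.4),
                                 effects = default_formulation_effects(),
                                 config = sim_config(),
                                 n_replicates = 1) {
  stopifnot(length(baselines) >= 2, !is.null(names(baselines)),
            inherits(config, "sim_config"))
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      formulation = c("control", effects$formulation),
                      membrane = names(baselines),
                      stringsAsFactors = FALSE)
  mult <- ifelse(grid$formulation == "control", 1,
                 effects$multiplier[match(grid$formulation,
                                          effects$formulation)])
  cls <- ifelse(grid$formulation == "control", "control",
                effects$class[match(grid$formulation, effects$formulation)])
  eps <- if (config$noise_cv > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(config$seed)
    pmax(stats::rnorm(nrow(grid), 0, config$noise_cv),
         -3 * config$noise_cv)
  } else rep(0, nrow(grid))
  out <- data.frame(membrane = grid$membrane,
                    formulation = grid$formulation,
                    class = cls,
                    replicate = grid$replicate,
                    tmwl = unname(baselines[grid$membrane]) * mult *
                      (1 + eps),
                    stringsAsFactors = FALSE)
  out$is_control <- out$formulation == "control"
  class(out) <- c("tmwl_panel", "data.frame")
  out
}

#' Generate a complete synthetic study fixture on disk
#'
#' Writes a full synthetic study emulating the reference design — the seven
#' permeants applied to three membranes in triplicate cells, sampled at
#' 0, 0.5, 1, 2 and 4 h, plus a 16-formulation two-membrane TMWL panel —
#' together with the configuration and a ground-truth file:
#'
#' * `timecourse.csv` — measured receptor concentrations per cell,
#' * `tmwl_panel.csv` — the synthetic TMWL screen,
#' * `config.yaml` — cell, dose and analyte configuration,
#' * `ground_truth.json` — true per-(membrane, analyte) J, Kp and lag, and
#'   the formulation multipliers, for end-to-end recovery checks.
#'
#' On biological membranes each analyte's diffusivity is scaled by a
#' phenomenological lipophilicity penalty (more lipophilic, larger
#' permeants diffuse more slowly through tissue), while the porous
#' surrogate membrane treats all permeants alike. Output is deterministic:
#' the same seed yields byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed.
#' @param noise_cv Proportional measurement noise CV (default 0.05).
#' @param n_cells Replicate cells per (membrane, analyte) (default 3).
#' @param force Overwrite a non-empty existing directory (default `FALSE`).
#' @return `out_dir`, invisibly; side effect: the four files above.
#' @export
generate_study_fixture <- function(out_dir, seed = 1, noise_cv = 0.05,
                                   n_cells = 3, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop("output directory '", out_dir,
         "' is not empty; use force = TRUE to overwrite", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cell <- franz_cell()
  dose <- dose_spec()
  analytes <- analyte_reference()
  membranes <- list(nuclepore = membrane_preset("nuclepore"),
                    sublingual_mucosa = membrane_preset("mucosa"),
                    skin = membrane_preset("skin"))
  series <- list()
  truth <- list()
  counter <- 0
  for (mb in names(membranes)) {
    for (an in names(analytes)) {
      a <- analytes[[an]]
      # lipophilicity penalty on tissue diffusivity; none on the porous
      # polycarbonate surrogate
      penalty <- if (mb == "nuclepore") 1 else 10^(-0.12 * max(a$log_kow, 0))
      m0 <- membranes[[mb]]
      m <- membrane_model(m0$diffusivity_d * penalty, m0$thickness_h,
                          m0$partition_k, m0$label)
      prof <- diffusion_profile(m, dose$c0_ug_ml, cell$times_h)
      truth[[paste(mb, an, sep = ".")]] <-
        list(membrane = mb, analyte = an,
             flux_j_ug_cm2_h = prof$flux_inf,
             kp_cm_h = m$kp_cm_h, lag_h = m$lag_h)
      for (j in seq_len(n_cells)) {
        counter <- counter + 1
        cfg <- sim_config(noise_cv = noise_cv,
                          seed = child_seed(seed, counter),
                          times_h = cell$times_h)
        id <- sprintf("%s_%s_cell%d", mb, an, j)
        s <- simulate_franz_sampling(prof, cell, cfg, cell_id = id)
        s$analyte <- a
        s$formulation <- NA_character_
        series[[id]] <- s
      }
    }
  }
  write_timecourse_table(series, file.path(out_dir, "timecourse.csv"))
  effects <- default_formulation_effects()
  panel <- simulate_tmwl_screen(config = sim_config(noise_cv = noise_cv,
                                                    seed = child_seed(seed,
                                                                      counter + 1)))
  utils::write.csv(panel[, c("membrane", "formulation", "class",
                             "replicate", "tmwl")],
                   file.path(out_dir, "tmwl_panel.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(cell = list(vc_ml = cell$receptor_volume_ml,
                     vs_ml = cell$sample_volume_ml,
                     area_cm2 = cell$area_cm2,
                     times_h = cell$times_h),
         dose = list(volume_ml = dose$applied_volume_ml,
                     c0_ug_ml = dose$c0_ug_ml),
         analytes = lapply(unname(analytes), function(a) {
           list(name = a$name, log_kow = a$log_kow, mw = a$mw,
                lod = a$lod, loq = a$loq)
         })),
    file.path(out_dir, "config.yaml"))
  jsonlite::write_json(
    list(seed = seed, noise_cv = noise_cv, n_cells = n_cells,
         membranes = truth,
         formulation_multipliers = stats::setNames(
           as.list(effects$multiplier), effects$formulation)),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
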