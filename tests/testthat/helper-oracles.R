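# Independent oracles used across the suite. Each re-derives an expected
# value from first principles, by a route different from the package code.

# Receptor mass ledger: given measured concentrations under
# withdraw-and-replace sampling, reconstruct the cumulative transferred
# mass per area by explicit bookkeeping — receptor mass now plus every
# aliquot mass withdrawn so far.
ledger_cumulative_q <- function(conc, vc, vs, a) {
  withdrawn <- 0
  q <- numeric(length(conc))
  for (n in seq_along(conc)) {
    q[n] <- (conc[n] * vc + withdrawn) / a
    withdrawn <- withdrawn + conc[n] * vs
  }
  q
}

# Closed-form two-parameter OLS on (t, q).
ols_line <- function(t, q) {
  slope <- sum((t - mean(t)) * (q - mean(q))) / sum((t - mean(t))^2)
  c(intercept = mean(q) - slope * mean(t), slope = slope)
}

# Kruskal-Wallis H from the rank definition, with midranks and the
# standard tie correction.
brute_force_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  rs <- mapply(function(s, e) sum(r[s:e]), starts, ends)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Explicit finite-difference solution of Fick's second law in the
# membrane (donor face held at K*C0, receptor face a perfect sink),
# integrating the exit flux to the cumulative amount per area.
fd_cumulative_q <- function(d, h, k, c0, t_end, nx = 200) {
  dx <- h / nx
  dt <- 0.2 * dx^2 / d
  nt <- ceiling(t_end / dt)
  dt <- t_end / nt
  conc <- numeric(nx + 1)
  conc[1] <- k * c0
  q <- 0
  flux_prev <- d * (conc[nx] - conc[nx + 1]) / dx
  for (s in seq_len(nt)) {
    lap <- c(0, diff(diff(conc)), 0) / dx^2
    conc <- conc + d * dt * lap
    conc[1] <- k * c0
    conc[nx + 1] <- 0
    flux <- d * (conc[nx] - conc[nx + 1]) / dx
    q <- q + dt * (flux + flux_prev) / 2
    flux_prev <- flux
  }
  q
}

# Build a cumulative_profile directly from (t, q) without going through
# measured concentrations.
make_profile <- function(times_h, q_ug_cm2, cell_id = "test") {
  structure(list(cell_id = cell_id, times_h = times_h,
                 q_ug_cm2 = q_ug_cm2, n_samples = length(times_h),
                 membrane = NA_character_, formulation = NA_character_,
                 analyte = NA_character_),
            class = "cumulative_profile")
}

# Build a true_profile directly from a (t, q) table.
make_true_profile <- function(times_h, q_ug_cm2, label = "manual",
                              c0 = 10000) {
  structure(list(times_h = times_h, q_ug_cm2 = q_ug_cm2,
                 membrane = list(label = label), c0_ug_ml = c0,
                 flux_inf = NA_real_, lag_h = NA_real_),
            class = "true_profile")
}

# Random membrane with a lag time small enough that steady state is
# reached well inside a 4 h window (so the eigenfunction series at the
# default truncation is accurate at the 0.5 h first sample).
random_membrane <- function() {
  lag <- runif(1, 0.01, 0.25)
  h <- runif(1, 0.01, 0.06)
  membrane_model(diffusivity_d = h^2 / (6 * lag), thickness_h = h,
                 partition_k = exp(runif(1, log(0.2), log(2))),
                 label = "random")
}
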