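#' Slab-diffusion kinetics of drug in the stratum corneum
#'
#' The SC is treated as a homogeneous membrane of thickness L and
#' diffusivity D. During *uptake* the outer surface is held at a constant
#' concentration by the applied formulation and the inner face (SC-viable
#' tissue boundary) is a perfect sink; the membrane starts empty. During
#' *clearance* the formulation has been removed, so the outer surface
#' carries zero flux while the inner sink is maintained; the initial
#' condition is the uptake profile at the end of application. Time is
#' expressed in units of the diffusional lag time `t_lag = L^2 / (6 D)`,
#' written `tau = t / t_lag`.
#'
#' `uptake_fraction(tau)` returns the amount of drug in the membrane
#' relative to its steady-state value, `u = Q(t) / Q_ss`, from the
#' eigenfunction series
#' `u = 1 - (8/pi^2) sum_{odd n} n^-2 exp(-n^2 pi^2 tau / 6)`.
#' For `tau < 1e-4` the semi-infinite short-time law
#' `(4/sqrt(pi)) sqrt(tau/6)` is used for numerical stability; series terms
#' are truncated below 1e-12.
#'
#' @param tau Dimensionless time `t / t_lag` (vectorised, >= 0).
#' @return Fraction of the steady-state amount, in `[0, 1)`.
#' @examples
#' uptake_fraction(c(0.1, 0.3, 1, 10))
#' @export
uptake_fraction <- function(tau) {
  stopifnot(all(is.finite(tau)), all(tau >= 0))
  vapply(tau, function(t1) {
    if (t1 == 0) return(0)
    if (t1 < 1e-4) return(4 / sqrt(pi) * sqrt(t1 / 6))
    n <- seq(1, 9999, by = 2)
    terms <- exp(-n^2 * pi^2 * t1 / 6) / n^2
    1 - (8 / pi^2) * sum(terms[terms >= 1e-12 * terms[1]])
  }, numeric(1))
}

# Cosine-eigenmode coefficients of the clearance problem (zero-flux outer
# face, inner sink), projected from the uptake profile at tau_up.
# Returns b_m for eigenvalues a_m = (m + 1/2) pi, m = 0 .. n_modes-1,
# membrane thickness and surface concentration scaled to 1.
.clearance_modes <- function(tau_up, n_modes, n_terms = 10000) {
  a <- (seq_len(n_modes) - 1) + 0.5
  need <- ceiling(sqrt(6 * 28 / (pi^2 * tau_up))) + 5
  n <- seq_len(min(max(need, 50), n_terms))
  en <- exp(-n^2 * pi^2 * tau_up / 6)
  inner <- as.vector(en %*% (1 / outer(n^2, a^2, `-`)))
  2 * (1 / (a^2 * pi^2) - (2 / pi^2) * inner)
}

#' @rdname uptake_fraction
#' @param tau_up Dimensionless duration of uptake, `t_up / t_lag` (> 0).
#' @param tau_cl Dimensionless clearance time, `delta_t / t_lag` (>= 0,
#'   vectorised).
#' @return `clearance_fraction()` returns the retained fraction
#'   `W = Q(t_up + delta_t) / Q(t_up)` in `(0, 1]`; `W = 1` at
#'   `tau_cl = 0`.
#' @examples
#' clearance_fraction(6 / 18.9, 17 / 18.9)
#' @export
clearance_fraction <- function(tau_up, tau_cl) {
  stopifnot(length(tau_up) == 1, is.finite(tau_up), tau_up > 0,
            all(is.finite(tau_cl)), all(tau_cl >= 0))
  pos <- tau_cl[tau_cl > 0]
  out <- rep(1, length(tau_cl))
  if (length(pos) == 0) return(out)
  smin <- min(pos) / 6
  n_modes <- min(max(ceiling(sqrt(28 / (pi^2 * smin))) + 5, 30), 4000)
  m <- seq_len(n_modes) - 1
  a <- m + 0.5
  b <- .clearance_modes(tau_up, n_modes)
  w_m <- b * (-1)^m / (a * pi)       # modal contributions to the amount
  m0 <- sum(w_m)                     # amount at start of clearance
  out[tau_cl > 0] <- vapply(pos, function(tc) {
    sum(w_m * exp(-a^2 * pi^2 * tc / 6)) / m0
  }, numeric(1))
  pmin(out, 1)
}

#' Concentration profiles across the SC
#'
#' Series evaluation of the local concentration (relative to the surface
#' concentration during uptake) as a function of fractional depth `x` in
#' `[0, 1]`, under the boundary conditions described in
#' [uptake_fraction()].
#'
#' @param x Fractional depth from the outer surface (vectorised, in
#'   `[0, 1]`).
#' @inheritParams clearance_fraction
#' @return Relative concentration values.
#' @export
uptake_profile <- function(x, tau) {
  stopifnot(all(x >= 0), all(x <= 1), length(tau) == 1, tau > 0)
  n <- seq_len(min(max(ceiling(sqrt(6 * 28 / (pi^2 * tau))) + 5, 50), 20000))
  en <- exp(-n^2 * pi^2 * tau / 6) / n
  (1 - x) - (2 / pi) * as.vector(sin(pi * outer(x, n)) %*% en)
}

#' @rdname uptake_profile
#' @export
clearance_profile <- function(x, tau_up, tau_cl) {
  stopifnot(all(x >= 0), all(x <= 1), length(tau_up) == 1, tau_up > 0,
            length(tau_cl) == 1, tau_cl >= 0)
  if (tau_cl == 0) return(uptake_profile(x, tau_up))
  n_modes <- min(max(ceiling(sqrt(28 / (pi^2 * tau_cl / 6))) + 5, 30), 4000)
  a <- (seq_len(n_modes) - 1) + 0.5
  b <- .clearance_modes(tau_up, n_modes)
  coef <- b * exp(-a^2 * pi^2 * tau_cl / 6)
  as.vector(cos(pi * outer(x, a)) %*% coef)
}

#' Invert the clearance model for the diffusional lag time
#'
#' Given the two measured areal amounts of a two-time-point tape-stripping
#' protocol, solves `clearance_fraction(t_up/t_lag, delta_t/t_lag) =
#' Q_cl/Q_up` for the lag time by bracketed root-finding, then extrapolates
#' to steady state: `F = 1 / uptake_fraction(t_up/t_lag)` is the factor by
#' which the uptake amount falls short of its steady-state value,
#' `Q_ss = F * Q_up`, and the steady-state flux follows from the slab
#' identity `J_ss = Q_ss / (3 t_lag)`.
#'
#' @param q_up,q_cl Areal amounts, ug/cm^2 (0 < `q_cl` < `q_up` for a fit).
#' @param t_up_h Uptake duration, h.
#' @param delta_t_h Clearance interval, h.
#' @param bracket Lag-time search interval in hours.
#' @return A `diffusion_fit` list: `converged`, `w` (= `q_cl/q_up`),
#'   `t_lag_h`, `tau_up` (= `t_up/t_lag`), `f`, `q_ss_ug_cm2`,
#'   `j_ss_ng_cm2_h`, and `diagnostic` for a failed fit. The identity
#'   `q_ss = 3 * j_ss * t_lag` (with unit factor 1000) holds exactly.
#' @examples
#' fit_lag_time(0.87, 0.69, 6, 17)
#' @export
fit_lag_time <- function(q_up, q_cl, t_up_h = 6, delta_t_h = 17,
                         bracket = c(0.1, 1000)) {
  stopifnot(q_up > 0, q_cl > 0, t_up_h > 0, delta_t_h > 0)
  w <- q_cl / q_up
  if (w >= 1) {
    return(structure(list(
      converged = FALSE, w = w, t_lag_h = NA_real_, tau_up = NA_real_,
      f = NA_real_, q_ss_ug_cm2 = NA_real_, j_ss_ng_cm2_h = NA_real_,
      diagnostic = "clearance did not reduce the amount (Q_cl >= Q_up)"
    ), class = "diffusion_fit"))
  }
  g <- function(tl) clearance_fraction(t_up_h / tl, delta_t_h / tl) - w
  glo <- g(bracket[1])
  ghi <- g(bracket[2])
  if (glo * ghi > 0) {
    stop("lag time not bracketed in [", bracket[1], ", ", bracket[2], "] h")
  }
  root <- stats::uniroot(g, bracket, tol = 1e-6 * bracket[1])
  t_lag <- root$root
  f <- 1 / uptake_fraction(t_up_h / t_lag)
  q_ss <- f * q_up
  structure(list(
    converged = TRUE, w = w, t_lag_h = t_lag, tau_up = t_up_h / t_lag,
    f = f, q_ss_ug_cm2 = q_ss, j_ss_ng_cm2_h = 1000 * q_ss / (3 * t_lag),
    diagnostic = NA_character_
  ), class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  if (!x$converged) {
    cat("slab-diffusion fit failed:", x$diagnostic, "\n")
    return(invisible(x))
  }
  cat("Slab-diffusion lag-time fit\n")
  cat(sprintf("  W = Q_cl/Q_up       %.3f\n", x$w))
  cat(sprintf("  t_lag               %.1f h  (t_up/t_lag = %.2f)\n",
              x$t_lag_h, x$tau_up))
  cat(sprintf("  F = Q_ss/Q_up       %.2f\n", x$f))
  cat(sprintf("  Q_ss                %.2f ug/cm^2\n", x$q_ss_ug_cm2))
  cat(sprintf("  J_ss                %.1f ng/cm^2/h\n", x$j_ss_ng_cm2_h))
  invisible(x)
}

#' Empirical dermal diffusivity correlations
#'
#' Estimates the diffusivity of free drug in the dermis from molecular
#' weight using one of two published empirical correlations (base-10
#' logarithms, D in cm^2/s, MW in Da):
#' `"logMW"`: `log10 D = -4.15 - 0.655 log10(MW)`;
#' `"cube_root"`: `log10 D = -4.38 - 0.207 MW^(1/3)`.
#'
#' @param mw Molecular weight, Da.
#' @param correlation Which correlation to evaluate.
#' @return D in cm^2/s.
#' @examples
#' dermal_diffusivity(225.2, "logMW")
#' @export
dermal_diffusivity <- function(mw, correlation = c("logMW", "cube_root")) {
  stopifnot(all(mw > 0))
  correlation <- match.arg(correlation)
  switch(correlation,
         logMW = 10^(-4.15 - 0.655 * log10(mw)),
         cube_root = 10^(-4.38 - 0.207 * mw^(1 / 3)))
}

#' Dermal clearance permeability coefficient
#'
#' The lumped rate constant describing loss of drug from the viable
#' epidermis into the microcirculation, `P_D = D_D / h_D`, converted to
#' cm/h from a diffusivity in cm^2/s (factor 3600).
#'
#' @param d_d_cm2_s Dermal diffusivity, cm^2/s.
#' @param h_d_cm Diffusion path length to the microcirculation, cm.
#' @return P_D in cm/h.
#' @examples
#' permeability_p_d(mean(dermal_diffusivity(225.2, "logMW"),
#'                       dermal_diffusivity(225.2, "cube_root")), 0.01)
#' @export
permeability_p_d <- function(d_d_cm2_s, h_d_cm) {
  stopifnot(all(d_d_cm2_s > 0))
  if (any(h_d_cm <= 0)) stop("h_d_cm must be positive")
  3600 * d_d_cm2_s / h_d_cm
}

#' Concentration at the cutaneous site of action (C* concept)
#'
#' At steady state the flux into the viable epidermis equals the clearance
#' from the site of action, `J = P_D C*`, so the free concentration there
#' is `C* = J / P_D`. With J in ng cm^-2 h^-1 and P_D in cm/h, C* comes
#' out in ng/cm^3 = ng/mL.
#'
#' @param j_ng_cm2_h Flux into the viable tissue, ng cm^-2 h^-1.
#' @param p_d_cm_h Clearance permeability coefficient, cm/h.
#' @return C* in ng/mL.
#' @examples
#' c_star(10.3, 0.78)
#' @export
c_star <- function(j_ng_cm2_h, p_d_cm_h) {
  if (any(p_d_cm_h <= 0)) stop("p_d_cm_h must be positive")
  j_ng_cm2_h / p_d_cm_h
}

#' Flux implied by a dermal open-flow microperfusion (dOFM) measurement
#'
#' Converts a perfusate concentration to an areal flux: the mass collection
#' rate is the perfusate flow multiplied by its drug concentration, and the
#' collecting area is the planar projection of the probe (length x
#' diameter).
#'
#' @param flow_rate_ul_h Perfusate flow rate, uL/h.
#' @param perfusate_conc_ng_ml Drug concentration in the perfusate, ng/mL.
#' @param probe_length_mm,probe_diameter_mm Probe dimensions, mm.
#' @return A list with `mass_rate_ng_h`, `area_cm2` and `j_ng_cm2_h`.
#' @examples
#' dofm_flux(60, 1)
#' @export
dofm_flux <- function(flow_rate_ul_h, perfusate_conc_ng_ml,
                      probe_length_mm = 15, probe_diameter_mm = 0.5) {
  stopifnot(flow_rate_ul_h > 0, perfusate_conc_ng_ml >= 0,
            probe_length_mm > 0, probe_diameter_mm > 0)
  mass_rate <- flow_rate_ul_h * 1e-3 * perfusate_conc_ng_ml   # ng/h
  area <- (probe_length_mm / 10) * (probe_diameter_mm / 10)   # cm^2
  list(mass_rate_ng_h = mass_rate, area_cm2 = area,
       j_ng_cm2_h = mass_rate / area)
}

#' Finite-difference cross-check of the slab solutions
#'
#' Independent forward-time central-space solver of the same boundary-value
#' problems as [uptake_fraction()] and [clearance_fraction()], used to
#' validate the series solutions. Grid resolution is chosen finer for
#' short times, where the concentration boundary layer is thin.
#'
#' @inheritParams clearance_fraction
#' @param nx Number of spatial intervals; by default 800 for `tau < 0.1`
#'   (uptake) and 300 otherwise.
#' @return The uptake fraction `u(tau)` or retained fraction
#'   `W(tau_up, tau_cl)` computed by finite differences.
#' @export
fd_uptake_fraction <- function(tau, nx = NULL) {
  stopifnot(length(tau) == 1, tau > 0)
  if (is.null(nx)) nx <- if (tau < 0.1) 800 else 300
  st <- .fd_run(rep(0, nx + 1), s_end = tau / 6, nx = nx, phase = "uptake")
  .fd_amount(st, nx) / 0.5
}

#' @rdname fd_uptake_fraction
#' @export
fd_clearance_fraction <- function(tau_up, tau_cl, nx = NULL) {
  stopifnot(length(tau_up) == 1, tau_up > 0, length(tau_cl) == 1, tau_cl >= 0)
  if (is.null(nx)) nx <- if (min(tau_up, max(tau_cl, tau_up)) < 0.1) 600 else 300
  up <- .fd_run(rep(0, nx + 1), s_end = tau_up / 6, nx = nx, phase = "uptake")
  m0 <- .fd_amount(up, nx)
  if (tau_cl == 0) return(1)
  cl <- .fd_run(up, s_end = tau_cl / 6, nx = nx, phase = "clearance")
  .fd_amount(cl, nx) / m0
}

.fd_run <- function(C, s_end, nx, phase) {
  h <- 1 / nx
  r <- 0.35
  dt <- r * h^2
  nstep <- ceiling(s_end / dt)
  dt <- s_end / nstep            # land exactly on s_end
  r <- dt / h^2
  i <- 2:nx
  if (phase == "uptake") C[1] <- 1
  for (step in seq_len(nstep)) {
    interior <- C[i] + r * (C[i - 1] - 2 * C[i] + C[i + 1])
    if (phase == "clearance") C[1] <- C[1] + 2 * r * (C[2] - C[1])
    C[i] <- interior
    C[nx + 1] <- 0
  }
  C
}

.fd_amount <- function(C, nx) {
  (sum(C) - (C[1] + C[nx + 1]) / 2) / nx
}
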