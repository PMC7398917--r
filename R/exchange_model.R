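#' Two-state exchange parameters
#'
#' Parameter set of the two-state Bloch-McConnell model: minor-state
#' population `p_B`, exchange rate `k_ex = k_AB + k_BA`, chemical-shift
#' difference `dw_ppm` between major and minor state, and the exchange-free
#' rate `r2inf` (one intrinsic R2 shared by both states).
#'
#' @param p_B Minor-state population, in (0, 0.5].
#' @param k_ex_s1 Exchange rate in 1/s.
#' @param dw_ppm Absolute 15N shift difference in ppm (>= 0).
#' @param r2inf_s1 Exchange-free transverse rate in 1/s (may be a named vector
#'   per series when used in fits).
#' @return Object of class `two_state_params`, with derived `k_AB = p_B k_ex`
#'   and `k_BA = (1 - p_B) k_ex`.
#' @export
two_state_params <- function(p_B, k_ex_s1, dw_ppm, r2inf_s1) {
  if (!(p_B > 0 && p_B <= 0.5)) stop("p_B must be in (0, 0.5]")
  if (!(k_ex_s1 > 0)) stop("k_ex_s1 must be > 0")
  if (dw_ppm < 0) stop("dw_ppm must be >= 0")
  if (any(r2inf_s1 <= 0)) stop("r2inf_s1 must be > 0")
  structure(list(p_B = p_B, k_ex_s1 = k_ex_s1, dw_ppm = dw_ppm,
                 r2inf_s1 = r2inf_s1,
                 k_AB = p_B * k_ex_s1, k_BA = (1 - p_B) * k_ex_s1),
            class = "two_state_params")
}

#' Admissible CPMG frequencies for a constant-time train
#'
#' For a relaxation-compensated train the pulse count `N = 2 T_relax nu_CPMG`
#' must be an integer divisible by 4, so the admissible frequencies are
#' `N / (2 T_relax)`, `N = 4, 8, 12, ...`.
#'
#' @param t_relax_s Constant relaxation time in seconds.
#' @param n_max Largest pulse count considered (default 400).
#' @return Numeric vector of admissible frequencies (1/s), increasing.
#' @export
admissible_nu <- function(t_relax_s, n_max = 400) {
  n <- seq(4, n_max, by = 4)
  n / (2 * t_relax_s)
}

# snap requested frequencies to exact admissible values (N within `tol` of an
# integer divisible by 4), or fail listing the nearest admissible ones
snap_nu <- function(nu_cpmg_s1, t_relax_s, tol = 0.1) {
  n_real <- 2 * t_relax_s * nu_cpmg_s1
  n <- round(n_real)
  bad <- abs(n_real - n) > tol | n %% 4 != 0 | n < 4
  if (any(bad)) {
    adm <- admissible_nu(t_relax_s)
    nearest <- vapply(nu_cpmg_s1[bad],
                      function(x) adm[which.min(abs(adm - x))], numeric(1))
    stop("inadmissible nu_CPMG ", paste(signif(nu_cpmg_s1[bad], 5), collapse = ", "),
         " for T_relax = ", t_relax_s,
         " s (N = 2*T*nu must be divisible by 4); nearest admissible: ",
         paste(signif(nearest, 5), collapse = ", "))
  }
  n / (2 * t_relax_s)
}

#' Plan a relaxation-compensated CPMG pulse train
#'
#' Lays out the constant-time element `delta/2 - 180 - delta - 180 - ... -
#' delta/2` with `N = 2 T_relax nu_CPMG` ideal 180-degree pulses and
#' inter-pulse spacing `delta = 1 / (2 nu_CPMG)`, totalling exactly
#' `T_relax`. `N` must be divisible by 4 (relaxation compensation); the
#' smallest admissible frequency for `T_relax` = 30 ms is therefore
#' 66.7 1/s.
#'
#' @param t_relax_s Constant relaxation time in seconds.
#' @param nu_cpmg_s1 Requested CPMG frequency (snapped to the exact admissible
#'   value when within tolerance, e.g. the conventionally printed 66.7 to
#'   200/3).
#' @return List with `n_pulses`, `delta_s`, `nu_effective_s1` and an `events`
#'   data frame (`type` in `delay`/`pulse180`, `duration_s`).
#' @export
pulse_train <- function(t_relax_s, nu_cpmg_s1) {
  stopifnot(length(nu_cpmg_s1) == 1)
  nu <- snap_nu(nu_cpmg_s1, t_relax_s)
  n <- as.integer(round(2 * t_relax_s * nu))
  delta <- 1 / (2 * nu)
  type <- c("delay", rep(c("pulse180", "delay"), n))
  dur <- c(delta / 2, rep(c(0, delta), n))
  dur[length(dur)] <- delta / 2
  list(n_pulses = n, delta_s = delta, nu_effective_s1 = nu,
       events = data.frame(type = type, duration_s = dur))
}

dw_rad_per_s <- function(dw_ppm, proton_frequency_MHz) {
  2 * pi * dw_ppm * .rd_const$nuN_over_nuH * proton_frequency_MHz
}

#' Bloch-McConnell R2eff for a two-state system
#'
#' Numerical forward model of the relaxation-compensated CPMG experiment:
#' transverse magnetization of the two exchanging sites evolves under the
#' 2x2 generator (exchange plus the minor-state offset `i dw`), each ideal
#' 180-degree pulse is complex conjugation, and
#' `R2eff = -(1/T_relax) log |m_A(T) + m_B(T)|` starting from equilibrium
#' populations. The shared intrinsic rate `r2inf` is additive and applied
#' after propagating the exchange part. The free-evolution propagators are
#' exact 2x2 matrix exponentials.
#'
#' @param params A [two_state_params] (scalar `r2inf_s1`).
#' @param nu_cpmg_s1 Vector of CPMG frequencies (snapped to admissible).
#' @param context A [spectrometer_context] (supplies the field, which converts
#'   `dw_ppm` to rad/s, and `t_relax_s`).
#' @return Numeric vector of `R2eff` values in 1/s.
#' @export
bm_r2eff <- function(params, nu_cpmg_s1, context) {
  stopifnot(inherits(params, "two_state_params"),
            inherits(context, "spectrometer_context"))
  nu <- snap_nu(nu_cpmg_s1, context$t_relax_s)
  dw <- dw_rad_per_s(params$dw_ppm, context$proton_frequency_MHz)
  rex <- bm_rex_curve_cpp(params$p_B, params$k_ex_s1, dw, nu, context$t_relax_s)
  if (any(!is.finite(rex))) stop("numerical error: non-finite R2eff")
  params$r2inf_s1[1] + rex
}

#' Carver-Richards closed-form R2eff
#'
#' Standard closed-form approximation to the two-state CPMG dispersion curve
#' (auxiliary quantities psi, zeta, D+/-, eta+/-), used as an independent
#' cross-check of [bm_r2eff()]. With equal intrinsic rates in the two states
#' it agrees with the numerical propagator to within about 2% for
#' `p_B <= 0.15`.
#'
#' @inheritParams bm_r2eff
#' @return Numeric vector of `R2eff` values in 1/s.
#' @export
carver_richards_r2eff <- function(params, nu_cpmg_s1, context) {
  stopifnot(inherits(params, "two_state_params"))
  nu <- snap_nu(nu_cpmg_s1, context$t_relax_s)
  pB <- params$p_B; pA <- 1 - pB
  kex <- params$k_ex_s1
  dw <- dw_rad_per_s(params$dw_ppm, context$proton_frequency_MHz)
  r20 <- params$r2inf_s1[1]
  if (dw == 0 || pB == 0) return(rep(r20, length(nu)))
  # equal intrinsic rates: psi = kex^2 - dw^2, zeta = -2 dw kex (pA - pB)
  psi <- kex^2 - dw^2
  zeta <- -2 * dw * kex * (pA - pB)
  root <- sqrt(psi^2 + zeta^2)
  Dp <- 0.5 * ( 1 + (psi + 2 * dw^2) / root)
  Dm <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  tcp <- 1 / (2 * nu)  # delay between successive 180 pulses
  etap <- (tcp / sqrt(2)) * sqrt( psi + root)
  etam <- (tcp / sqrt(2)) * sqrt(-psi + root)
  arg <- Dp * cosh(etap) - Dm * cos(etam)
  r20 + 0.5 * (kex - (1 / tcp) * acosh(arg))
}

#' Simulate a dispersion series from the forward model
#'
#' Noise-free values come from [bm_r2eff()]; when `snr` is given, Gaussian
#' noise with `sigma = 1 / (t_relax * snr)` is added to each point and that
#' sigma is recorded, mirroring the signal-to-noise error model of
#' [compute_r2eff()].
#'
#' @inheritParams bm_r2eff
#' @param nu_grid CPMG frequency grid.
#' @param snr Signal-to-noise ratio, or `NULL` for a noise-free series.
#' @param seed Optional integer seed (local; the global RNG state is
#'   restored).
#' @param residue_id Residue number recorded in the series (default 1).
#' @return A [dispersion_series].
#' @export
simulate_series <- function(params, nu_grid, context, snr = NULL, seed = NULL,
                            residue_id = 1L) {
  nu <- snap_nu(nu_grid, context$t_relax_s)
  r2 <- bm_r2eff(params, nu, context)
  # noise-free series carry unit sigma: weights are uninformative and
  # chi-square equals the sum of squared residuals in (1/s)^2
  sigma <- if (is.null(snr)) rep(1, length(nu))
           else rep(1 / (context$t_relax_s * snr), length(nu))
  if (!is.null(snr)) {
    r2 <- r2 + local_rnorm(length(nu), sd = sigma[1], seed = seed)
  }
  dispersion_series(residue_id, context, nu, r2, sigma)
}

# draw N(0, sd) deviates under an optional local seed, restoring global state
local_rnorm <- function(n, sd, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  rnorm(n, sd = sd)
}
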