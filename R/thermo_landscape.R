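#' Equilibrium thermodynamics of a two-state conformational exchange
#'
#' Parameterises the A = B equilibrium by its enthalpy and entropy;
#' `dG(T) = dH - T dS`, `K(T) = exp(-dG/(R T))`, `p_B(T) = K/(1+K)`.
#'
#' @param dH_kJmol Enthalpy change A -> B in kJ/mol.
#' @param dS_JmolK Entropy change in J/(mol K).
#' @param dH_sigma,dS_sigma Optional 1-sigma uncertainties.
#' @return Object of class `thermo_equilibrium`.
#' @export
thermo_equilibrium <- function(dH_kJmol, dS_JmolK, dH_sigma = NA_real_,
                               dS_sigma = NA_real_) {
  structure(list(dH_kJmol = dH_kJmol, dS_JmolK = dS_JmolK,
                 dH_sigma = dH_sigma, dS_sigma = dS_sigma),
            class = "thermo_equilibrium")
}

#' @rdname thermo_equilibrium
#' @param eq A `thermo_equilibrium`.
#' @param T_K Temperatures in Kelvin.
#' @return `predict_pB()`: minor-state populations `p_B(T)`.
#' @export
predict_pB <- function(eq, T_K) {
  check_kelvin(T_K)
  K <- exp(-(eq$dH_kJmol * 1000 - T_K * eq$dS_JmolK) / (.rd_const$R_gas * T_K))
  K / (1 + K)
}

#' Transition-state thermodynamics (Eyring parameterisation)
#'
#' `k(T) = (k_B T / h) exp(-(dH' - T dS')/(R T))` with transmission
#' coefficient 1.
#'
#' @param dH_act_kJmol Activation enthalpy in kJ/mol.
#' @param dS_act_JmolK Activation entropy in J/(mol K).
#' @param dH_sigma,dS_sigma Optional 1-sigma uncertainties.
#' @return Object of class `thermo_transition`.
#' @export
thermo_transition <- function(dH_act_kJmol, dS_act_JmolK, dH_sigma = NA_real_,
                              dS_sigma = NA_real_) {
  structure(list(dH_act_kJmol = dH_act_kJmol, dS_act_JmolK = dS_act_JmolK,
                 dH_sigma = dH_sigma, dS_sigma = dS_sigma),
            class = "thermo_transition")
}

#' @rdname thermo_transition
#' @param ts A `thermo_transition`.
#' @param T_K Temperatures in Kelvin.
#' @return `predict_k()`: rate constants `k(T)` in 1/s.
#' @export
predict_k <- function(ts, T_K) {
  check_kelvin(T_K)
  cst <- .rd_const
  (cst$k_B * T_K / cst$h) *
    exp(-(ts$dH_act_kJmol * 1000 - T_K * ts$dS_act_JmolK) / (cst$R_gas * T_K))
}

check_kelvin <- function(T_K) {
  if (any(T_K < 250))
    stop("temperature ", T_K[T_K < 250][1],
         " below 250 K; input looks like Celsius")
  invisible(T_K)
}

# weighted straight-line fit y = a + b x; w = 1/sigma_y^2 (or 1 when no
# sigmas); returns coefficients and their covariance.  For exactly-determined
# two-point unweighted fits the parameter sigmas are undefined (flagged
# upstream as "no redundancy").
wls_line <- function(x, y, w = NULL) {
  n <- length(x)
  weighted <- !is.null(w)
  if (!weighted) w <- rep(1, n)
  W <- sum(w); Sx <- sum(w * x); Sy <- sum(w * y)
  Sxx <- sum(w * x^2); Sxy <- sum(w * x * y)
  D <- W * Sxx - Sx^2
  b <- (W * Sxy - Sx * Sy) / D
  a <- (Sy - b * Sx) / W
  cov <- matrix(c(Sxx, -Sx, -Sx, W), 2) / D
  if (!weighted) {
    s2 <- if (n > 2) sum((y - a - b * x)^2) / (n - 2) else NA_real_
    cov <- cov * s2
  }
  list(intercept = a, slope = b,
       sigma_intercept = sqrt(cov[1, 1]), sigma_slope = sqrt(cov[2, 2]))
}

#' van't Hoff fit of p_B(T)
#'
#' Weighted linear regression of `ln K` versus `1/T`, with
#' `K = p_B/(1 - p_B)`: slope `= -dH/R`, intercept `= dS/R`. Uncertainties in
#' `p_B` are propagated to `ln K` by the delta method,
#' `sigma(ln K) = sigma(p_B) / (p_B (1 - p_B))`.
#'
#' @param T_K Temperatures in Kelvin (>= 2, all >= 250 K).
#' @param p_B Minor-state populations in (0, 1).
#' @param sigma Optional 1-sigma uncertainties of `p_B`.
#' @return A [thermo_equilibrium()] with uncertainties; attribute
#'   `"no_redundancy"` is `TRUE` for exactly-determined two-point fits.
#' @export
vant_hoff_fit <- function(T_K, p_B, sigma = NULL) {
  check_kelvin(T_K)
  if (length(T_K) < 2) stop("need >= 2 temperatures")
  if (any(p_B <= 0 | p_B >= 1)) stop("domain error: p_B must lie in (0, 1)")
  K <- p_B / (1 - p_B)
  w <- if (!is.null(sigma)) (p_B * (1 - p_B) / sigma)^2 else NULL
  ft <- wls_line(1 / T_K, log(K), w)
  R <- .rd_const$R_gas
  out <- thermo_equilibrium(dH_kJmol = -ft$slope * R / 1000,
                            dS_JmolK = ft$intercept * R,
                            dH_sigma = ft$sigma_slope * R / 1000,
                            dS_sigma = ft$sigma_intercept * R)
  attr(out, "no_redundancy") <- length(T_K) == 2
  out
}

#' Eyring fit of k(T)
#'
#' Weighted linear regression of `ln(k h / (k_B T))` versus `1/T`: slope
#' `= -dH'/R`, intercept `= dS'/R`. Uncertainties in `k` propagate as
#' `sigma(ln k) = sigma(k)/k`.
#'
#' @param T_K Temperatures in Kelvin.
#' @param k_s1 Rate constants in 1/s (positive).
#' @param sigma Optional 1-sigma uncertainties of `k`.
#' @return A [thermo_transition()] with uncertainties.
#' @export
eyring_fit <- function(T_K, k_s1, sigma = NULL) {
  check_kelvin(T_K)
  if (length(T_K) < 2) stop("need >= 2 temperatures")
  if (any(k_s1 <= 0)) stop("domain error: rates must be positive")
  cst <- .rd_const
  y <- log(k_s1 * cst$h / (cst$k_B * T_K))
  w <- if (!is.null(sigma)) (k_s1 / sigma)^2 else NULL
  ft <- wls_line(1 / T_K, y, w)
  out <- thermo_transition(dH_act_kJmol = -ft$slope * cst$R_gas / 1000,
                           dS_act_JmolK = ft$intercept * cst$R_gas,
                           dH_sigma = ft$sigma_slope * cst$R_gas / 1000,
                           dS_sigma = ft$sigma_intercept * cst$R_gas)
  attr(out, "no_redundancy") <- length(T_K) == 2
  out
}

#' Free-energy-landscape table
#'
#' Assembles, at one temperature, the (dG, dH, -T dS) decomposition of the
#' A -> B equilibrium, the A -> transition-state barrier, and the derived
#' B -> transition-state barrier, which is forced to satisfy
#' `dG'_AB - dG'_BA = dG_AB` (and the corresponding dH and T dS identities).
#' In every row `dG = dH + (-T dS)` holds exactly.
#'
#' @param eq A [thermo_equilibrium()] for A -> B.
#' @param ts A [thermo_transition()] for A -> transition state.
#' @param T_K Temperature in Kelvin.
#' @return Data frame with columns `leg`, `dG_kJmol`, `dH_kJmol`,
#'   `mTdS_kJmol`.
#' @export
landscape_table <- function(eq, ts, T_K) {
  check_kelvin(T_K)
  dG_eq <- eq$dH_kJmol - T_K * eq$dS_JmolK / 1000
  dG_ab <- ts$dH_act_kJmol - T_K * ts$dS_act_JmolK / 1000
  data.frame(
    leg = c("A_to_B", "A_to_TS", "B_to_TS"),
    dG_kJmol = c(dG_eq, dG_ab, dG_ab - dG_eq),
    dH_kJmol = c(eq$dH_kJmol, ts$dH_act_kJmol, ts$dH_act_kJmol - eq$dH_kJmol),
    mTdS_kJmol = c(-T_K * eq$dS_JmolK / 1000,
                   -T_K * ts$dS_act_JmolK / 1000,
                   -T_K * (ts$dS_act_JmolK - eq$dS_JmolK) / 1000))
}
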