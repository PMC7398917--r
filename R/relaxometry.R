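# Rigid-rotor 15N dipolar + CSA relaxation rates, isotropic Lorentzian
# spectral density J(w) = (2/5) tau_c / (1 + (w tau_c)^2), order parameter 1.
# Shared by rigid_r2_over_r1 and gen_rigid_relaxation.
rigid_rates <- function(tau_c_ns, proton_frequency_MHz) {
  cst <- .rd_const
  tau <- tau_c_ns * 1e-9
  wH <- 2 * pi * proton_frequency_MHz * 1e6
  wN <- wH * cst$nuN_over_nuH
  J <- function(w) 0.4 * tau / (1 + (w * tau)^2)
  d <- (cst$mu0 * cst$h * cst$gamma_H * (cst$gamma_H * cst$nuN_over_nuH)) /
       (8 * pi^2 * cst$r_NH^3)
  c2 <- (wN * cst$delta_sigma)^2 / 3
  R1 <- (d^2 / 4) * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- (d^2 / 8) * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                     6 * J(wH + wN)) +
        (c2 / 6) * (4 * J(0) + 3 * J(wN))
  # gamma_N is negative: gamma_H / gamma_N = -1 / |nuN/nuH|
  noe <- 1 + (d^2 / (4 * R1)) * (-1 / cst$nuN_over_nuH) *
         (6 * J(wH + wN) - J(wH - wN))
  list(R1 = R1, R2 = R2, NOE = noe)
}

#' R2/R1 exchange flagging
#'
#' Computes the per-residue `R2/R1` ratio and flags residues lying above the
#' mean plus one standard deviation, the standard indicator of microsecond to
#' millisecond conformational exchange. Mean and SD are taken over residues
#' with `hetNOE > noe_min`, excluding flexible termini from the reference
#' statistics; flagging uses a strict inequality so a zero-SD set flags
#' nothing.
#'
#' @param records Relaxation data frame as returned by
#'   [read_relaxation_table()] or [gen_rigid_relaxation()].
#' @param noe_min Heteronuclear-NOE rigidity cutoff (default 0.65).
#' @param k_sd Number of SDs above the mean required to flag (default 1).
#' @return Data frame with columns `residue_id`, `ratio`, `flagged`;
#'   attributes `mean` and `sd` hold the reference statistics.
#' @export
r2_over_r1_flags <- function(records, noe_min = 0.65, k_sd = 1) {
  if (nrow(records) < 5) stop("need at least 5 residues")
  qual <- records$NOE > noe_min
  if (sum(qual) < 5)
    stop("fewer than 5 residues pass the hetNOE > ", noe_min, " filter")
  ratio <- records$R2 / records$R1
  m <- mean(ratio[qual]); s <- sd(ratio[qual])
  out <- data.frame(residue_id = records$residue_id, ratio = ratio,
                    flagged = ratio > m + k_sd * s)
  attr(out, "mean") <- m
  attr(out, "sd") <- s
  out
}

#' Rigid-rotor R2/R1 ratio
#'
#' Forward curve used to invert the measured `R2/R1` ratio into a rotational
#' correlation time: the ratio of the closed-form dipolar+CSA `R2` and `R1`
#' for an isotropic rigid rotor (order parameter 1). Strictly increasing in
#' `tau_c` beyond about 1 ns; tends to 1 in the extreme narrowing limit.
#'
#' @param tau_c_ns Rotational correlation time in ns (vectorised).
#' @param proton_frequency_MHz 1H frequency in MHz.
#' @return Numeric vector of `R2/R1` ratios.
#' @export
rigid_r2_over_r1 <- function(tau_c_ns, proton_frequency_MHz) {
  if (any(tau_c_ns <= 0)) stop("tau_c_ns must be > 0")
  vapply(tau_c_ns, function(tc) {
    r <- rigid_rates(tc, proton_frequency_MHz)
    r$R2 / r$R1
  }, numeric(1))
}

#' Rotational correlation time from R2/R1
#'
#' Estimates the overall rotational correlation time from the trimmed-mean
#' `R2/R1` ratio of the rigid subset (residues not flagged by
#' [r2_over_r1_flags()] and with `hetNOE > noe_min`), by 1-D root finding of
#' [rigid_r2_over_r1()] on \[0.5, 50\] ns. The closed-form seed
#' `tau_c = sqrt(6 R2/R1 - 7) / (4 pi nu_N)` is reported for reference.
#'
#' @inheritParams r2_over_r1_flags
#' @param proton_frequency_MHz 1H frequency of the field the rates were
#'   measured at.
#' @param trim Fraction trimmed from each tail of the rigid-subset ratios
#'   (default 0.1).
#' @return Object of class `tauc_estimate` with `tau_c_ns`,
#'   `n_residues_used`, `ratio_used`, `seed_ns`.
#' @export
estimate_tc <- function(records, proton_frequency_MHz, noe_min = 0.65,
                        trim = 0.1) {
  fl <- r2_over_r1_flags(records, noe_min = noe_min)
  rigid <- !fl$flagged & records$NOE > noe_min
  if (!any(rigid)) {
    warning("all residues flagged as exchanging; falling back to all residues")
    rigid <- rep(TRUE, nrow(records))
  }
  ratio <- mean(fl$ratio[rigid], trim = trim)
  nuN <- proton_frequency_MHz * 1e6 * .rd_const$nuN_over_nuH
  seed <- if (6 * ratio - 7 > 0) sqrt(6 * ratio - 7) / (4 * pi * nuN) * 1e9 else NA_real_
  f <- function(tc) rigid_r2_over_r1(tc, proton_frequency_MHz) - ratio
  lo <- 0.5; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("no solution: R2/R1 ratio ", signif(ratio, 4),
         " outside the rigid-rotor curve on [0.5, 50] ns")
  root <- uniroot(f, c(lo, hi), tol = 1e-6)
  structure(list(tau_c_ns = root$root, n_residues_used = sum(rigid),
                 ratio_used = ratio, seed_ns = seed),
            class = "tauc_estimate")
}

#' @export
print.tauc_estimate <- function(x, ...) {
  cat(sprintf("tau_c = %.4f ns (from R2/R1 = %.4f over %d rigid residues)\n",
              x$tau_c_ns, x$ratio_used, x$n_residues_used))
  invisible(x)
}
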