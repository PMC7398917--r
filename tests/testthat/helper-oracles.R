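# Independent oracles. These deliberately avoid the package's code paths:
# matrix exponentials come from a scaled Taylor series, rates are recoded
# from scratch, and the CPMG train is propagated in fine time steps.

# n-site brute-force CPMG propagator. pops: site populations; Kmat: kinetic
# generator (column j holds rates out of j; Kmat[i,j] = rate j->i for i != j,
# diagonal = -colSums); omega_rad: site offsets; r2 intrinsic rate (scalar).
# Ideal 180 pulses = complex conjugation between free-evolution segments.
brute_force_r2eff <- function(pops, Kmat, omega_rad, nu, t_relax, r2 = 0,
                              dt = 1e-6) {
  nst <- length(pops)
  L <- Kmat + 1i * diag(omega_rad, nst) - r2 * diag(nst)
  taylor_expm <- function(A) {
    E <- diag(nst) + 0i
    term <- diag(nst) + 0i
    for (k in 1:30) {
      term <- term %*% A / k
      E <- E + term
    }
    E
  }
  vapply(nu, function(v) {
    n <- round(2 * t_relax * v)
    delta <- t_relax / n
    segs <- c(delta / 2, rep(delta, n - 1), delta / 2)
    E <- taylor_expm(L * dt)
    m <- as.complex(pops)
    for (si in seq_along(segs)) {
      nstep <- round(segs[si] / dt)
      for (s in seq_len(nstep)) m <- E %*% m
      if (si < length(segs)) m <- Conj(m)
    }
    -log(Mod(sum(m)) / sum(pops)) / t_relax
  }, numeric(1))
}

two_state_K <- function(p_B, k_ex) {
  k_ab <- p_B * k_ex
  k_ba <- (1 - p_B) * k_ex
  matrix(c(-k_ab, k_ab, k_ba, -k_ba), 2, 2)
}

# linear three-state topology A <-> B and A <-> C with stated populations
three_state_K <- function(pops, kex_ab, kex_ac) {
  pA <- pops[1]; pB <- pops[2]; pC <- pops[3]
  k_ab <- kex_ab * pB / (pA + pB) ; k_ba <- kex_ab * pA / (pA + pB)
  k_ac <- kex_ac * pC / (pA + pC) ; k_ca <- kex_ac * pA / (pA + pC)
  matrix(c(-(k_ab + k_ac), k_ab, k_ac,
           k_ba, -k_ba, 0,
           k_ca, 0, -k_ca), 3, 3)
}

ppm_to_rad <- function(dw_ppm, MHz) 2 * pi * dw_ppm * 0.10136767 * MHz

# rigid-rotor 15N rates, recoded independently (hbar form, explicit numbers)
oracle_rigid_rates <- function(tau_c_ns, MHz) {
  tau <- tau_c_ns * 1e-9
  hbar <- 1.054571817e-34
  mu0 <- 1.25663706212e-6
  gH <- 2.6752218744e8
  gN <- -2.7126e7 # rad/s/T; |gN/gH| = 0.101397 differs from the frequency
  gN <- -gH * 0.10136767 # pin the same frequency ratio the package states
  rNH <- 1.02e-10
  wH <- 2 * pi * MHz * 1e6
  wN <- wH * abs(gN / gH)
  jj <- function(w) 0.4 * tau / (1 + (w * tau)^2)
  dd <- mu0 * hbar * gH * abs(gN) / (4 * pi * rNH^3)
  cc2 <- (wN * 160e-6)^2 / 3
  R1 <- dd^2 / 4 * (jj(wH - wN) + 3 * jj(wN) + 6 * jj(wH + wN)) + cc2 * jj(wN)
  R2 <- dd^2 / 8 * (4 * jj(0) + jj(wH - wN) + 3 * jj(wN) + 6 * jj(wH) +
                    6 * jj(wH + wN)) + cc2 / 6 * (4 * jj(0) + 3 * jj(wN))
  NOE <- 1 + dd^2 / (4 * R1) * (gH / gN) * (6 * jj(wH + wN) - jj(wH - wN))
  list(R1 = R1, R2 = R2, NOE = NOE)
}
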