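# run code under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Synthetic rigid-rotor 15N relaxation table
#'
#' Generates per-residue R1, R2 and heteronuclear NOE for an isotropic rigid
#' rotor (order parameter 1) at the given correlation time and field, using
#' the dipolar + CSA expressions of [rigid_r2_over_r1()] (`r_NH` = 1.02 A,
#' CSA = -160 ppm). Multiplicative Gaussian noise of fraction `noise_frac` is
#' applied; the error columns carry `max(noise_frac, 1e-4) * value` so they
#' stay positive for noise-free tables.
#'
#' @param tau_c_ns Rotational correlation time in ns.
#' @param proton_frequency_MHz 1H frequency in MHz.
#' @param n_residues Number of residues (ids 1..n).
#' @param noise_frac Fractional Gaussian noise (0 = noise-free).
#' @param seed Optional integer seed (local).
#' @return Data frame in the [read_relaxation_table()] schema (plus
#'   `residue_id`).
#' @export
gen_rigid_relaxation <- function(tau_c_ns, proton_frequency_MHz, n_residues,
                                 noise_frac = 0, seed = NULL) {
  if (!(tau_c_ns > 0)) stop("tau_c_ns must be > 0")
  r <- rigid_rates(tau_c_ns, proton_frequency_MHz)
  with_seed(seed, {
    mult <- function() 1 + rnorm(n_residues, sd = noise_frac)
    R1 <- r$R1 * (if (noise_frac > 0) mult() else rep(1, n_residues))
    R2 <- r$R2 * (if (noise_frac > 0) mult() else rep(1, n_residues))
    NOE <- r$NOE * (if (noise_frac > 0) mult() else rep(1, n_residues))
    ef <- max(noise_frac, 1e-4)
    data.frame(residue_id = seq_len(n_residues), residue = seq_len(n_residues),
               R1 = R1, R1_err = ef * abs(R1),
               R2 = R2, R2_err = ef * abs(R2),
               NOE = NOE, NOE_err = ef * pmax(abs(NOE), 0.1))
  })
}

#' Ground-truth record for a synthetic dispersion dataset
#'
#' Bundles the per-residue regime assignment, the exchange parameters of the
#' dispersive residues, the thermodynamic laws generating `p_B(T)` and
#' `k_ex(T)`, the rotational correlation time and the exchange-free baseline
#' model, so that pipeline output can be scored against known truth.
#'
#' @param dispersive Data frame with `residue_id` and `dw_ppm`.
#' @param fast Data frame with `residue_id` and `rex_s1` (flat elevation).
#' @param no_exchange Integer vector of residue ids.
#' @param eq A [thermo_equilibrium()] for `p_B(T)`.
#' @param ts A [thermo_transition()] for `k_AB(T)`.
#' @param tau_c_ns Correlation time used for rigid-rotor rates and baselines.
#' @param visc_E_kJmol Apparent activation energy scaling the baseline with
#'   temperature (water-viscosity-like, default 20 kJ/mol).
#' @param r2inf_jitter_sd SD of the per-residue multiplicative baseline
#'   jitter (default 0.02).
#' @param seed Integer seed fixing the jitter and all downstream noise.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(dispersive, fast, no_exchange, eq, ts,
                            tau_c_ns = 6.5, visc_E_kJmol = 20,
                            r2inf_jitter_sd = 0.02, seed = 1L) {
  ids <- c(dispersive$residue_id, fast$residue_id, no_exchange)
  if (anyDuplicated(ids)) stop("residue assigned to more than one regime")
  jit <- with_seed(seed, setNames(1 + rnorm(length(ids), sd = r2inf_jitter_sd),
                                  ids))
  structure(list(dispersive = dispersive, fast = fast,
                 no_exchange = no_exchange, eq = eq, ts = ts,
                 tau_c_ns = tau_c_ns, visc_E_kJmol = visc_E_kJmol,
                 jitter = jit, seed = seed),
            class = "synthetic_truth")
}

#' @rdname synthetic_truth
#' @details `truth_paperlike()` is the default stated world: five dispersive
#'   residues (ids 124, 125, 134, 136, 138; 15N `dw` 2-4 ppm), five fast
#'   residues (ids 80, 83, 86, 89, 96; flat elevation 5 1/s), ten residues
#'   without exchange, equilibrium thermodynamics `dH` = -30 kJ/mol,
#'   `dS` = -120 J/(mol K), barrier `dH'` = 50 kJ/mol,
#'   `dS'` = -40 J/(mol K), and `tau_c` = 6.5 ns.
#' @export
truth_paperlike <- function(seed = 1L) {
  synthetic_truth(
    dispersive = data.frame(residue_id = c(124L, 125L, 134L, 136L, 138L),
                            dw_ppm = c(2, 2.5, 3, 3.5, 4)),
    fast = data.frame(residue_id = c(80L, 83L, 86L, 89L, 96L),
                      rex_s1 = rep(5, 5)),
    no_exchange = c(5L, 15L, 25L, 35L, 45L, 55L, 65L, 75L, 105L, 150L),
    eq = thermo_equilibrium(-30, -120),
    ts = thermo_transition(50, -40),
    seed = seed)
}

#' Default acquisition contexts and frequency grid
#'
#' The synthetic design mirrors the experimental one: two fields (600.03 and
#' 800.4 MHz), four temperatures (278, 283, 290, 298 K), constant relaxation
#' time 30 ms, and an 11-point CPMG grid spanning 66.7 to 1000 1/s (pulse
#' counts divisible by 4).
#'
#' @param fields_MHz,temperatures_K,t_relax_s Acquisition grid.
#' @param condition Condition label stamped on every context.
#' @return `default_contexts()`: list of [spectrometer_context]s.
#' @export
default_contexts <- function(fields_MHz = c(600.03, 800.4),
                             temperatures_K = c(278, 283, 290, 298),
                             t_relax_s = 0.030, condition = "free") {
  out <- list()
  for (f in fields_MHz) for (tt in temperatures_K)
    out[[length(out) + 1]] <- spectrometer_context(f, tt, t_relax_s,
                                                   condition = condition)
  out
}

#' @rdname default_contexts
#' @return `default_nu_grid()`: the 11-point admissible frequency grid.
#' @export
default_nu_grid <- function(t_relax_s = 0.030) {
  c(4, 8, 12, 16, 20, 24, 32, 40, 48, 56, 60) / (2 * t_relax_s)
}

# exchange-free baseline of one residue in one context: rigid-rotor R2 at the
# truth's tau_c, scaled by a viscosity-like Arrhenius factor and the
# per-residue jitter
truth_r2inf <- function(truth, residue_id, context) {
  base <- rigid_rates(truth$tau_c_ns, context$proton_frequency_MHz)$R2
  fac <- exp(truth$visc_E_kJmol * 1000 / .rd_const$R_gas *
             (1 / context$temperature_K - 1 / 298))
  base * fac * truth$jitter[[as.character(residue_id)]]
}

#' @rdname synthetic_truth
#' @param truth A `synthetic_truth`.
#' @param context A [spectrometer_context].
#' @return `truth_params()`: the [two_state_params()] of one dispersive
#'   residue in one context (its `p_B(T)`, `k_ex(T)` follow the truth's
#'   thermodynamic laws).
#' @export
truth_params <- function(truth, residue_id, context) {
  i <- match(residue_id, truth$dispersive$residue_id)
  if (is.na(i)) stop("residue ", residue_id, " is not dispersive in this truth")
  T_K <- context$temperature_K
  pB <- predict_pB(truth$eq, T_K)
  kAB <- predict_k(truth$ts, T_K)
  two_state_params(p_B = pB, k_ex_s1 = kAB / pB,
                   dw_ppm = truth$dispersive$dw_ppm[i],
                   r2inf_s1 = truth_r2inf(truth, residue_id, context))
}

#' Generate CPMG intensity tables from a synthetic truth
#'
#' For every context, every residue's `R2eff(nu)` is produced from its regime
#' (Bloch-McConnell forward model for dispersive residues with `p_B(T)` and
#' `k_ex(T)` from the truth's van't Hoff/Eyring laws; a flat elevated profile
#' for fast residues; the bare baseline otherwise) and converted to peak
#' intensities `I = I0 exp(-R2eff T_relax)`. Gaussian noise of SD `I0 / snr`
#' is added to the CPMG intensities (the reference is noise-free, matching
#' the error model of [compute_r2eff()]); the `noise` column carries
#' `I0 / snr`. Identical seeds give identical tables.
#'
#' @param truth A [synthetic_truth()].
#' @param contexts List of [spectrometer_context]s (default
#'   [default_contexts()]).
#' @param nu_grid CPMG frequencies (default [default_nu_grid()]).
#' @param snr Signal-to-noise ratio of the reference peak, or `NULL` for
#'   noise-free tables.
#' @param seed Integer seed (local).
#' @param I0 Reference intensity (arbitrary units, default 100).
#' @return List with `tables` (named by context key; data frames in the
#'   [read_intensity_table()] schema), `contexts` and `truth`.
#' @export
gen_dispersion_dataset <- function(truth, contexts = default_contexts(),
                                   nu_grid = default_nu_grid(), snr = NULL,
                                   seed = 1L, I0 = 100) {
  all_ids <- c(truth$dispersive$residue_id, truth$fast$residue_id,
               truth$no_exchange)
  tables <- with_seed(seed, lapply(contexts, function(ctx) {
    nu <- snap_nu(nu_grid, ctx$t_relax_s)
    rows <- lapply(sort(all_ids), function(rid) {
      r2inf <- truth_r2inf(truth, rid, ctx)
      r2 <- if (rid %in% truth$dispersive$residue_id) {
        bm_r2eff(truth_params(truth, rid, ctx), nu, ctx)
      } else if (rid %in% truth$fast$residue_id) {
        rep(r2inf + truth$fast$rex_s1[match(rid, truth$fast$residue_id)],
            length(nu))
      } else rep(r2inf, length(nu))
      I <- I0 * exp(-r2 * ctx$t_relax_s)
      if (!is.null(snr)) I <- I + rnorm(length(I), sd = I0 / snr)
      noise_col <- if (is.null(snr)) I0 * 1e-6 else I0 / snr
      data.frame(residue = rid, nu_cpmg = c(0, nu),
                 intensity = c(I0, I), noise = noise_col)
    })
    do.call(rbind, rows)
  }))
  names(tables) <- vapply(contexts, context_key, character(1))
  structure(list(tables = tables, contexts = contexts, truth = truth),
            snr = snr)
}

#' Dispersion series from a generated dataset
#'
#' Converts the intensity tables of a [gen_dispersion_dataset()] result into
#' [dispersion_series] objects via [build_series()], optionally restricted to
#' some residues. For noise-free datasets (generated with `snr = NULL`) the
#' recorded noise estimate is a placeholder, so the per-point sigmas are
#' replaced by unit weights.
#'
#' @param ds Result of [gen_dispersion_dataset()].
#' @param residues Optional integer vector restricting the residues.
#' @return List of [dispersion_series] (contexts vary fastest by residue).
#' @export
dataset_series <- function(ds, residues = NULL) {
  unit_sigma <- is.null(attr(ds, "snr"))
  out <- list()
  for (k in seq_along(ds$tables)) {
    ctx <- ds$contexts[[k]]
    tab <- ds$tables[[k]]
    ids <- sort(unique(tab$residue))
    if (!is.null(residues)) ids <- intersect(ids, residues)
    for (rid in ids) {
      sub <- tab[tab$residue == rid, ]
      s <- build_series(list(residue_id = rid, context = ctx,
                             data = data.frame(residue_id = rid,
                                               nu_cpmg = sub$nu_cpmg,
                                               intensity = sub$intensity,
                                               noise = sub$noise)))
      if (unit_sigma) s$points$sigma <- rep(1, nrow(s$points))
      out[[length(out) + 1]] <- s
    }
  }
  out
}

#' Synthetic chemical-shift titration dataset
#'
#' Free-state amide shifts are drawn uniformly in plausible ranges
#' (`delta_H` in 7.5-9.5 ppm, `delta_N` in 105-130 ppm). Bound-state shifts
#' add, at each hotspot residue, a perturbation of `effect_ppm` on 1H and
#' `10 * effect_ppm * eps` on 15N with `eps ~ U(0, 1)`, and Gaussian
#' referencing noise of SD `noise_ppm` (1H) and `10 * noise_ppm` (15N)
#' everywhere.
#'
#' @param n_residues Number of residues (ids 1..n).
#' @param hotspots Integer ids of perturbed residues (subset of 1..n).
#' @param effect_ppm 1H perturbation at hotspots.
#' @param noise_ppm SD of the 1H noise (15N noise is 10x).
#' @param seed Integer seed (local).
#' @param temperature_K,proton_frequency_MHz Context metadata.
#' @return List with shift tables `free` and `bound` and a `truth` record.
#' @export
gen_csp_dataset <- function(n_residues, hotspots, effect_ppm = 0.05,
                            noise_ppm = 0.005, seed = 1L,
                            temperature_K = 298,
                            proton_frequency_MHz = 800.4) {
  if (!all(hotspots %in% seq_len(n_residues)))
    stop("hotspot ids must be a subset of 1..n_residues")
  ctx_free <- spectrometer_context(proton_frequency_MHz, temperature_K,
                                   condition = "free")
  ctx_bound <- spectrometer_context(proton_frequency_MHz, temperature_K,
                                    condition = "bound")
  with_seed(seed, {
    free <- data.frame(residue_id = seq_len(n_residues),
                       delta_H = runif(n_residues, 7.5, 9.5),
                       delta_N = runif(n_residues, 105, 130))
    bound <- free
    bound$delta_H <- bound$delta_H + rnorm(n_residues, sd = noise_ppm)
    bound$delta_N <- bound$delta_N + rnorm(n_residues, sd = 10 * noise_ppm)
    eps <- runif(length(hotspots))
    bound$delta_H[hotspots] <- bound$delta_H[hotspots] + effect_ppm
    bound$delta_N[hotspots] <- bound$delta_N[hotspots] + 10 * effect_ppm * eps
    attr(free, "context") <- ctx_free
    attr(bound, "context") <- ctx_bound
    list(free = free, bound = bound,
         truth = list(hotspots = sort(hotspots), effect_ppm = effect_ppm,
                      noise_ppm = noise_ppm, seed = seed))
  })
}

#' Score regime classification against a synthetic truth
#'
#' @param labels Data frame from [classify_all()].
#' @param truth A [synthetic_truth()].
#' @return List with `accuracy` and the merged comparison table.
#' @export
score_regimes <- function(labels, truth) {
  want <- c(setNames(rep("dispersive", nrow(truth$dispersive)),
                     truth$dispersive$residue_id),
            setNames(rep("fast", nrow(truth$fast)), truth$fast$residue_id),
            setNames(rep("no_exchange", length(truth$no_exchange)),
                     truth$no_exchange))
  labels$truth <- want[as.character(labels$residue_id)]
  list(accuracy = mean(labels$label == labels$truth), table = labels)
}
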