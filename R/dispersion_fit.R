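# ---------------------------------------------------------------------------
# Weighted least-squares machinery shared by all fit modes.
#
# A fit mode is defined by a map from a natural-scale nonlinear parameter
# vector `nat` to one (p_B, k_ex, dw_ppm) triple per series. The exchange-free
# rate r2inf of each series enters the model additively, so for any value of
# the nonlinear parameters its weighted-least-squares optimum is available in
# closed form (separable linear parameter); it is profiled out of the search
# and restored afterwards, counted in DF and in the covariance like any other
# free parameter.
# ---------------------------------------------------------------------------

series_label <- function(s) {
  sprintf("r%d_%.6gMHz_%.6gK", s$residue_id, s$context$proton_frequency_MHz,
          s$context$temperature_K)
}

# cache per-series data, concatenated for the C++ objective
prep_series <- function(series_list) {
  per <- lapply(series_list, function(s) {
    list(nu = snap_nu(s$points$nu_cpmg, s$context$t_relax_s),
         obs = s$points$r2eff,
         w = 1 / s$points$sigma^2,
         sigma = s$points$sigma,
         t_relax = s$context$t_relax_s,
         # ppm -> rad/s conversion factor at this series' field
         dw_fac = 2 * pi * .rd_const$nuN_over_nuH * s$context$proton_frequency_MHz,
         residue_id = s$residue_id,
         temperature_K = s$context$temperature_K,
         label = series_label(s))
  })
  len <- vapply(per, function(p) length(p$nu), integer(1))
  list(per = per,
       nu = unlist(lapply(per, `[[`, "nu")),
       obs = unlist(lapply(per, `[[`, "obs")),
       w = unlist(lapply(per, `[[`, "w")),
       sigma = unlist(lapply(per, `[[`, "sigma")),
       t_relax = vapply(per, `[[`, numeric(1), "t_relax"),
       dw_fac = vapply(per, `[[`, numeric(1), "dw_fac"),
       start = c(0L, cumsum(len))[seq_along(len)],
       len = len)
}

# chi^2 profiled over the per-series r2inf; pars is an n_series x 3 matrix
# of (p_B, k_ex, dw_ppm) on the natural scale
profiled_chi2 <- function(prep, pars) {
  profiled_chi2_cpp(pars[, 1], pars[, 2], pars[, 3] * prep$dw_fac,
                    prep$nu, prep$obs, prep$w, prep$t_relax,
                    prep$start, prep$len)
}

# multi-start bounded minimisation on a log10 scale for positive parameters
rd_fit_engine <- function(series_list, map_fun, starts, lower, upper,
                          log_scale, par_names, mode,
                          n_polish = Inf, maxit = 200L, factr = 10) {
  prep <- prep_series(series_list)
  n_points <- sum(prep$len)
  trans <- function(nat) { nat[log_scale] <- log10(nat[log_scale]); nat }
  untrans <- function(th) { th[log_scale] <- 10^th[log_scale]; th }
  obj <- function(th) {
    pars <- map_fun(untrans(th))
    if (is.null(pars)) return(1e12)
    profiled_chi2(prep, pars)$chi2
  }
  lo <- trans(lower); up <- trans(upper)
  th_starts <- lapply(starts, trans)
  # rank starts by their initial objective; run the optimizer from the best
  f0 <- vapply(th_starts, obj, numeric(1))
  ord <- order(f0)
  n_run <- min(length(ord), if (is.finite(n_polish)) n_polish else length(ord))
  best <- NULL
  for (j in ord[seq_len(n_run)]) {
    res <- tryCatch(
      optim(th_starts[[j]], obj, method = "L-BFGS-B", lower = lo, upper = up,
            control = list(maxit = maxit, factr = factr,
                           ndeps = rep(1e-5, length(lo)))),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!is.null(best)) {
    # polish from the winner until the objective stops improving
    for (rep in 1:6) {
      res <- tryCatch(
        optim(best$par, obj, method = "L-BFGS-B", lower = lo, upper = up,
              control = list(maxit = maxit, factr = factr,
                             ndeps = rep(1e-5, length(lo)))),
        error = function(e) NULL)
      if (is.null(res)) break
      improved <- res$value < best$value - 1e-14
      if (res$value <= best$value) best <- res
      if (!improved) break
    }
  }
  if (is.null(best))
    return(structure(list(mode = mode, converged = FALSE, chi2 = NA_real_,
                          df = NA_integer_, n_points = n_points,
                          n_restarts_used = n_run,
                          message = "no start converged"),
                     class = "rd_fit"))
  nat <- untrans(best$par)
  names(nat) <- par_names
  pc <- profiled_chi2(prep, map_fun(nat))
  names(pc$r2inf) <- vapply(prep$per, `[[`, character(1), "label")
  n_free <- length(nat) + length(pc$r2inf)
  df <- n_points - n_free
  # covariance of the full parameter vector (nonlinear params + r2inf) from
  # the weighted-residual Jacobian at the optimum
  phi <- c(nat, pc$r2inf)
  resid_fun <- function(phi) {
    head <- phi[seq_along(nat)]
    pars <- map_fun(head)
    if (is.null(pars)) return(rep(1e6, n_points))
    unlist(lapply(seq_along(prep$per), function(i) {
      p <- prep$per[[i]]
      rex <- bm_rex_curve_cpp(pars[i, 1], pars[i, 2], pars[i, 3] * p$dw_fac,
                              p$nu, p$t_relax)
      (p$obs - phi[length(nat) + i] - rex) / p$sigma
    }))
  }
  J <- numeric_jacobian(resid_fun, phi)
  cov <- tryCatch({
    sv <- svd(J)
    pos <- sv$d > max(sv$d) * 1e-10
    v <- sv$v[, pos, drop = FALSE]
    v %*% diag(1 / sv$d[pos]^2, sum(pos)) %*% t(v)
  }, error = function(e) matrix(NA_real_, length(phi), length(phi)))
  sig <- sqrt(pmax(diag(cov), 0))
  structure(list(
    mode = mode,
    pars = data.frame(name = par_names, value = unname(nat),
                      sigma = sig[seq_along(nat)]),
    r2inf = data.frame(series = names(pc$r2inf), value = unname(pc$r2inf),
                       sigma = sig[-seq_along(nat)]),
    chi2 = pc$chi2, df = df, n_points = n_points,
    # code 52 (line-search failure) occurs on degenerate, flat objectives
    # (e.g. dw at its bound for exchange-free data) after the minimum has
    # effectively been reached; the polish loop has verified no further
    # improvement is available
    converged = best$convergence %in% c(0L, 52L) && is.finite(pc$chi2),
    n_restarts_used = n_run,
    cov = cov,
    warnings = character(0)),
    class = "rd_fit")
}

numeric_jacobian <- function(f, x, rel_h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    h <- max(abs(x[k]) * rel_h, 1e-9)
    xp <- x; xp[k] <- x[k] + h
    xm <- x; xm[k] <- x[k] - h
    J[, k] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' @export
print.rd_fit <- function(x, ...) {
  cat(sprintf("two-state fit [%s]: chi2 = %.4g, DF = %d, converged = %s\n",
              x$mode, x$chi2, x$df, x$converged))
  if (!is.null(x$pars)) print(x$pars, row.names = FALSE)
  invisible(x)
}

default_start_grid <- function() {
  expand.grid(p_B = c(0.01, 0.05, 0.1), k_ex = c(200, 1000, 3000),
              dw = c(1, 3, 6))
}

#' Per-residue two-state fit
#'
#' Fits one residue's dispersion series (ideally at two fields, shared
#' temperature) with the numerical Bloch-McConnell model. Free parameters:
#' `p_B`, `k_ex` and the 15N `dw` (shared across fields, converted to rad/s
#' per field), plus one `r2inf` per series. The weighted chi-square
#' `sum(((obs - model)/sigma)^2)` is minimised from a fixed multi-start grid
#' (`p_B` in \{0.01, 0.05, 0.1\}, `k_ex` in \{200, 1000, 3000\} 1/s, `dw` in
#' \{1, 3, 6\} ppm) within bounds `p_B` in \[1e-4, 0.5\], `k_ex` in
#' \[10, 1e5\] 1/s, `dw` in \[0.05, 15\] ppm; the best chi-square is kept.
#' Uncertainties are 1-sigma, from the Jacobian-based covariance.
#'
#' @param series_list List of [dispersion_series] for one residue at one
#'   temperature (typically two fields).
#' @param start_grid Data frame of start values (columns `p_B`, `k_ex`, `dw`).
#' @param n_polish Number of top-ranked starts actually optimised (all by
#'   default; ranking is by the objective at the start point).
#' @return Object of class `rd_fit`: parameter table, per-series `r2inf`
#'   table, `chi2`, `df`, `converged`, `n_restarts_used`.
#' @export
fit_individual <- function(series_list, start_grid = default_start_grid(),
                           n_polish = Inf) {
  if (inherits(series_list, "dispersion_series")) series_list <- list(series_list)
  res_ids <- unique(vapply(series_list, function(s) s$residue_id, integer(1)))
  if (length(res_ids) != 1) stop("fit_individual expects a single residue")
  fields <- unique(vapply(series_list, function(s) s$context$proton_frequency_MHz,
                          numeric(1)))
  if (length(fields) < 2)
    warning("only one field supplied; p_B and dw are poorly separable")
  n_points <- sum(vapply(series_list, function(s) nrow(s$points), integer(1)))
  if (n_points <= 5) stop("need more than 5 points in total")
  k <- length(series_list)
  map_fun <- function(nat) {
    cbind(rep(nat[1], k), rep(nat[2], k), rep(nat[3], k))
  }
  starts <- lapply(seq_len(nrow(start_grid)),
                   function(i) as.numeric(start_grid[i, c("p_B", "k_ex", "dw")]))
  fit <- rd_fit_engine(series_list, map_fun, starts,
                       lower = c(1e-4, 10, 0.05), upper = c(0.5, 1e5, 15),
                       log_scale = c(TRUE, TRUE, TRUE),
                       par_names = c("p_B", "k_ex", "dw_ppm"),
                       mode = "individual", n_polish = n_polish)
  if (!is.null(fit$pars)) {
    dw_hat <- fit$pars$value[3]
    amp <- max(vapply(seq_along(series_list), function(i) {
      p <- prep_series(series_list[i])$per[[1]]
      rex <- bm_rex_curve_cpp(fit$pars$value[1], fit$pars$value[2],
                              dw_hat * p$dw_fac, range(p$nu), p$t_relax)
      rex[1] - rex[2]
    }, numeric(1)))
    mean_sigma <- mean(unlist(lapply(series_list, function(s) s$points$sigma)))
    if (dw_hat <= 0.06 || amp < mean_sigma) {
      fit$warnings <- c(fit$warnings,
                        "non-identifiable: no resolvable dispersion (dw at lower bound or amplitude below noise)")
      warning(fit$warnings[length(fit$warnings)])
    }
  }
  fit$residue_id <- res_ids
  fit
}

#' Global two-state fit at one temperature
#'
#' All dispersive residues at one temperature share `p_B` and `k_ex`; each
#' residue keeps its own `dw`, each (residue, field) series its own `r2inf`.
#' Bounds and start grid as in [fit_individual()] (each start uses one common
#' `dw` start for every residue).
#'
#' @param series_list List of [dispersion_series] at one temperature
#'   (several residues, one or two fields each).
#' @inheritParams fit_individual
#' @return An `rd_fit`; parameter names are `p_B`, `k_ex`, `dw_ppm_r<id>`.
#' @export
fit_global_temperature <- function(series_list,
                                   start_grid = default_start_grid(),
                                   n_polish = 8, factr = 10) {
  temps <- unique(vapply(series_list, function(s) s$context$temperature_K,
                         numeric(1)))
  if (length(temps) != 1) stop("fit_global_temperature expects one temperature")
  res_ids <- sort(unique(vapply(series_list, function(s) s$residue_id, integer(1))))
  res_idx <- match(vapply(series_list, function(s) s$residue_id, integer(1)),
                   res_ids)
  k <- length(res_ids)
  map_fun <- function(nat) {
    cbind(rep(nat[1], length(res_idx)), rep(nat[2], length(res_idx)),
          nat[2 + res_idx])
  }
  starts <- lapply(seq_len(nrow(start_grid)), function(i)
    c(start_grid$p_B[i], start_grid$k_ex[i], rep(start_grid$dw[i], k)))
  rd_fit_engine(series_list, map_fun, starts,
                lower = c(1e-4, 10, rep(0.05, k)),
                upper = c(0.5, 1e5, rep(15, k)),
                log_scale = rep(TRUE, 2 + k),
                par_names = c("p_B", "k_ex", paste0("dw_ppm_r", res_ids)),
                mode = "global_T", n_polish = n_polish, factr = factr)
}

#' Global two-state fit across all temperatures
#'
#' Joint fit of every residue at every temperature and field. `dw` is shared
#' across temperatures per residue. Unconstrained mode frees one
#' (`p_B`, `k_ex`) pair per temperature. Constrained mode generates
#' `p_B(T)` and `k_ex(T)` from four thermodynamic parameters via the
#' van't Hoff law `K(T) = p_B/(1-p_B) = exp(-(dH - T dS)/(R T))` and the
#' Eyring law `k_AB(T) = (k_B T / h) exp(-(dH' - T dS')/(R T))`,
#' `k_ex = k_AB / p_B` (transmission coefficient 1). Starting values are
#' staged from per-temperature global fits (and, in constrained mode, from
#' van't Hoff/Eyring regression of those per-temperature estimates), with
#' perturbed replicas guarding against a poor stage-one solution.
#'
#' @param series_list List of [dispersion_series] spanning >= 2 temperatures.
#' @param constrained Logical; impose the van't Hoff/Eyring temperature laws.
#' @param stage1 Optional list of per-temperature `rd_fit` objects (in
#'   increasing temperature order) to skip the internal stage-one fits.
#' @return An `rd_fit`. Unconstrained parameter names: `p_B_<T>K`,
#'   `k_ex_<T>K`, `dw_ppm_r<id>`; constrained: `dH_kJmol`, `dS_JmolK`,
#'   `dHact_kJmol`, `dSact_JmolK`, `dw_ppm_r<id>`.
#' @export
fit_global_all <- function(series_list, constrained = FALSE, stage1 = NULL) {
  temps <- sort(unique(vapply(series_list, function(s) s$context$temperature_K,
                              numeric(1))))
  if (length(temps) < 2) stop("need series at >= 2 temperatures")
  res_ids <- sort(unique(vapply(series_list, function(s) s$residue_id, integer(1))))
  k <- length(res_ids)
  nT <- length(temps)
  t_idx <- match(vapply(series_list, function(s) s$context$temperature_K,
                        numeric(1)), temps)
  r_idx <- match(vapply(series_list, function(s) s$residue_id, integer(1)),
                 res_ids)
  if (is.null(stage1)) {
    # stage-1 fits only seed the joint fit; run them loose and from fewer
    # starts
    stage1 <- lapply(temps, function(tt) {
      sel <- series_list[vapply(series_list, function(s)
        s$context$temperature_K == tt, logical(1))]
      fit_global_temperature(sel, n_polish = 4, factr = 1e7)
    })
  }
  pB_T <- vapply(stage1, function(f) f$pars$value[f$pars$name == "p_B"], numeric(1))
  kex_T <- vapply(stage1, function(f) f$pars$value[f$pars$name == "k_ex"], numeric(1))
  dw_start <- vapply(res_ids, function(r) {
    v <- vapply(stage1, function(f) {
      i <- match(paste0("dw_ppm_r", r), f$pars$name)
      if (is.na(i)) NA_real_ else f$pars$value[i]
    }, numeric(1))
    exp(mean(log(v), na.rm = TRUE))
  }, numeric(1))
  dw_start <- pmin(pmax(dw_start, 0.06), 14)

  if (!constrained) {
    map_fun <- function(nat) {
      cbind(nat[t_idx], nat[nT + t_idx], nat[2 * nT + r_idx])
    }
    base <- c(pmin(pmax(pB_T, 2e-4), 0.45), pmin(pmax(kex_T, 11), 9e4), dw_start)
    starts <- list(base,
                   c(base[seq_len(nT)] * 0.7, base[nT + seq_len(nT)] * 1.5,
                     dw_start),
                   c(rep(0.05, nT), rep(1000, nT), rep(3, k)))
    rd_fit_engine(series_list, map_fun, starts,
                  lower = c(rep(1e-4, nT), rep(10, nT), rep(0.05, k)),
                  upper = c(rep(0.5, nT), rep(1e5, nT), rep(15, k)),
                  log_scale = rep(TRUE, 2 * nT + k),
                  par_names = c(sprintf("p_B_%gK", temps),
                                sprintf("k_ex_%gK", temps),
                                paste0("dw_ppm_r", res_ids)),
                  mode = "global_all", n_polish = 3)
  } else {
    cst <- .rd_const
    # internal parameterisation (dG(T0), dH) instead of (dH, dS): over a
    # narrow 1/T range dH and dS are nearly collinear and the raw
    # parameterisation makes the optimizer crawl along the valley; anchoring
    # the free energy at the central temperature decorrelates the pair.
    T0 <- mean(temps)
    to_dS <- function(dH_kJ, dG0_kJ) (dH_kJ - dG0_kJ) * 1000 / T0
    map_fun <- function(nat) {
      dH <- nat[2] * 1000; dS <- to_dS(nat[2], nat[1])
      dHa <- nat[4] * 1000; dSa <- to_dS(nat[4], nat[3])
      K <- exp(-(dH - temps * dS) / (cst$R_gas * temps))
      pB <- K / (1 + K)
      if (any(pB <= 1e-6) || any(pB > 0.5)) return(NULL)
      kAB <- (cst$k_B * temps / cst$h) *
        exp(-(dHa - temps * dSa) / (cst$R_gas * temps))
      kex <- kAB / pB
      if (any(!is.finite(kex)) || any(kex <= 0) || any(kex > 1e7)) return(NULL)
      cbind(pB[t_idx], kex[t_idx], nat[4 + r_idx])
    }
    vh <- tryCatch(vant_hoff_fit(temps, pmin(pmax(pB_T, 1e-4), 0.499)),
                   error = function(e) NULL)
    ey <- tryCatch(eyring_fit(temps, pmax(pB_T * kex_T, 1e-6)),
                   error = function(e) NULL)
    eqs <- if (!is.null(vh)) c(vh$dH_kJmol, vh$dS_JmolK) else c(-30, -120)
    tss <- if (!is.null(ey)) c(ey$dH_act_kJmol, ey$dS_act_JmolK) else c(50, -40)
    s0 <- c(eqs[1] - T0 * eqs[2] / 1000, eqs[1],
            tss[1] - T0 * tss[2] / 1000, tss[1])
    starts <- list(c(s0, dw_start),
                   c(s0 + c(1, -5, 1, 5), dw_start),
                   c(s0 + c(-1, 5, -1, -5), dw_start))
    fit <- rd_fit_engine(series_list, map_fun, starts,
                  lower = c(-40, -200, 25, -100, rep(0.05, k)),
                  upper = c(40, 200, 120, 400, rep(15, k)),
                  log_scale = c(FALSE, FALSE, FALSE, FALSE, rep(TRUE, k)),
                  par_names = c("dG_T0_kJmol", "dH_kJmol", "dGact_T0_kJmol",
                                "dHact_kJmol", paste0("dw_ppm_r", res_ids)),
                  mode = "constrained", n_polish = 3)
    if (!is.null(fit$pars)) {
      # report (dH, dS) pairs; sigma(dS) by the delta method from the
      # (dG(T0), dH) covariance
      v <- fit$pars$value; sg <- fit$pars$sigma
      a <- 1000 / T0
      sd_dS <- function(i_g, i_h) {
        if (all(is.finite(fit$cov[c(i_g, i_h), c(i_g, i_h)])))
          a * sqrt(max(fit$cov[i_h, i_h] + fit$cov[i_g, i_g] -
                       2 * fit$cov[i_g, i_h], 0))
        else NA_real_
      }
      fit$pars <- data.frame(
        name = c("dH_kJmol", "dS_JmolK", "dHact_kJmol", "dSact_JmolK",
                 fit$pars$name[-(1:4)]),
        value = c(v[2], to_dS(v[2], v[1]), v[4], to_dS(v[4], v[3]),
                  v[-(1:4)]),
        sigma = c(sg[2], sd_dS(1, 2), sg[4], sd_dS(3, 4), sg[-(1:4)]))
    }
    fit
  }
}

#' Chi-square vs degrees-of-freedom model selection
#'
#' Tabulates chi-square and DF for the individual fits and each global fit on
#' the same data, applying the criterion that a fit level is acceptable when
#' `chi2 < DF`. The overall verdict is "two-state consistent" when every
#' global fit satisfies `chi2 < DF` and the summed individual fits satisfy
#' `sum(chi2) < sum(DF)`.
#'
#' @param individual_results List of per-residue `rd_fit` objects.
#' @param global_results One `rd_fit` or a list of them (per-temperature
#'   and/or all-temperature fits).
#' @return List of class `rd_model_selection` with a `table` data frame and a
#'   logical `consistent`.
#' @export
model_select <- function(individual_results, global_results) {
  if (inherits(global_results, "rd_fit")) global_results <- list(global_results)
  ind_chi2 <- sum(vapply(individual_results, `[[`, numeric(1), "chi2"))
  ind_df <- sum(vapply(individual_results, `[[`, numeric(1), "df"))
  ind_pts <- sum(vapply(individual_results, `[[`, numeric(1), "n_points"))
  glob_pts <- vapply(global_results, `[[`, numeric(1), "n_points")
  if (any(glob_pts != ind_pts))
    stop("mismatched datasets: global fit covers ", glob_pts[1],
         " points, individual fits cover ", ind_pts)
  tab <- data.frame(
    level = c("individual_sum",
              vapply(global_results, `[[`, character(1), "mode")),
    chi2 = c(ind_chi2, vapply(global_results, `[[`, numeric(1), "chi2")),
    DF = c(ind_df, vapply(global_results, `[[`, numeric(1), "df")))
  tab$ok <- tab$chi2 < tab$DF
  structure(list(table = tab, consistent = all(tab$ok)),
            class = "rd_model_selection")
}

#' @export
print.rd_model_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(if (x$consistent) "verdict: two-state consistent\n"
      else "verdict: inconsistent with a single two-state process\n")
  invisible(x)
}

#' Compare two dispersion series point by point
#'
#' Computes the per-point chi-square
#' `chi2/N = mean((r2eff_a - r2eff_b)^2 / (sigma_a^2 + sigma_b^2))` for two
#' series of the same residue on the same frequency grid (no interpolation),
#' declaring a significant change when `chi2/N` exceeds `threshold`. Used for
#' the concentration-dependence control (dilution) and for quench/gain
#' comparisons between free and peptide-bound samples.
#'
#' @param a,b [dispersion_series] objects, same residue and grid.
#' @param threshold Change threshold on `chi2/N` (default 2).
#' @return List with `chi2_per_point` and logical `changed`.
#' @export
compare_series <- function(a, b, threshold = 2) {
  if (a$residue_id != b$residue_id)
    stop("series belong to different residues")
  if (nrow(a$points) != nrow(b$points) ||
      any(abs(a$points$nu_cpmg - b$points$nu_cpmg) > 1e-6))
    stop("frequency grids differ; no interpolation is performed")
  d2 <- (a$points$r2eff - b$points$r2eff)^2
  v <- a$points$sigma^2 + b$points$sigma^2
  chi2n <- mean(d2 / v)
  list(chi2_per_point = chi2n, changed = chi2n > threshold)
}
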