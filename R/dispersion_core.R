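#' Effective transverse relaxation rate from peak intensities
#'
#' Converts a CPMG peak intensity `I` and the reference intensity `I0`
#' (recorded with a zero-length relaxation element) into
#' `R2eff = -(1/T_relax) * log(I / I0)`, with the first-order error
#' `sigma = (1 / T_relax) / (I / noise)`, i.e. `1 / (T_relax * SNR)`.
#' Reference-spectrum noise is deliberately not propagated.
#'
#' @param I Peak intensity at the CPMG frequency (vectorised).
#' @param I0 Reference peak intensity.
#' @param t_relax_s Constant relaxation time in seconds.
#' @param noise Spectral noise estimate in the same units as `I`.
#' @return Data frame with columns `r2eff` and `sigma` (both 1/s). `r2eff` can
#'   be negative when noise pushes `I` above `I0`.
#' @export
compute_r2eff <- function(I, I0, t_relax_s, noise) {
  if (!(t_relax_s > 0)) stop("t_relax_s must be > 0")
  if (any(noise <= 0)) stop("noise must be > 0")
  if (any(I <= 0) || any(I0 <= 0))
    stop("domain error: non-positive intensity (peak vanished); drop the point")
  data.frame(r2eff = -log(I / I0) / t_relax_s,
             sigma = (noise / I) / t_relax_s)
}

#' Dispersion series container
#'
#' One residue's `R2eff(nu_CPMG)` profile with per-point errors at one
#' field/temperature/condition.
#'
#' @param residue_id Integer residue number.
#' @param context A [spectrometer_context].
#' @param nu_cpmg,r2eff,sigma Equal-length numeric vectors; `nu_cpmg` must be
#'   strictly increasing and `sigma` positive.
#' @return Object of class `dispersion_series` with a `points` data frame.
#' @export
dispersion_series <- function(residue_id, context, nu_cpmg, r2eff, sigma) {
  stopifnot(inherits(context, "spectrometer_context"),
            length(nu_cpmg) == length(r2eff),
            length(sigma) == length(r2eff))
  if (is.unsorted(nu_cpmg, strictly = TRUE))
    stop("nu_cpmg must be strictly increasing")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  structure(list(residue_id = as.integer(residue_id), context = context,
                 points = data.frame(nu_cpmg = nu_cpmg, r2eff = r2eff,
                                     sigma = sigma)),
            class = "dispersion_series")
}

#' @export
print.dispersion_series <- function(x, ...) {
  cat(sprintf("dispersion_series residue %d, %s, %d points\n",
              x$residue_id, format(x$context), nrow(x$points)))
  invisible(x)
}

#' Build a dispersion series from one residue's intensity group
#'
#' Identifies the reference record (`nu_cpmg == 0`), averages duplicate
#' frequencies (noise combined in quadrature, with a warning), converts each
#' remaining point with [compute_r2eff()] and drops (with a warning) points
#' whose intensity is non-positive.
#'
#' @param group One element of the list returned by [read_intensity_table()].
#' @return A [dispersion_series].
#' @export
build_series <- function(group) {
  d <- group$data
  ctx <- group$context
  ref <- d[d$nu_cpmg == 0, , drop = FALSE]
  if (nrow(ref) != 1) stop("group must contain exactly one reference record")
  if (ref$intensity <= 0)
    stop("domain error: non-positive reference intensity for residue ",
         group$residue_id)
  cp <- d[d$nu_cpmg > 0, , drop = FALSE]
  if (nrow(cp) == 0) stop("group has no CPMG records")
  if (anyDuplicated(cp$nu_cpmg)) {
    warning("duplicate nu_cpmg rows for residue ", group$residue_id,
            "; averaging intensities, combining noise in quadrature")
    agg_i <- tapply(cp$intensity, cp$nu_cpmg, mean)
    agg_n <- tapply(cp$noise, cp$nu_cpmg,
                    function(n) sqrt(sum(n^2)) / length(n))
    cp <- data.frame(nu_cpmg = as.numeric(names(agg_i)),
                     intensity = as.numeric(agg_i),
                     noise = as.numeric(agg_n))
  }
  keep <- cp$intensity > 0
  if (!all(keep)) {
    warning(sum(!keep), " point(s) with non-positive intensity dropped for ",
            "residue ", group$residue_id)
    cp <- cp[keep, , drop = FALSE]
  }
  if (nrow(cp) == 0) stop("domain error: all CPMG points non-positive")
  rr <- compute_r2eff(cp$intensity, ref$intensity, ctx$t_relax_s, cp$noise)
  dispersion_series(group$residue_id, ctx, cp$nu_cpmg, rr$r2eff, rr$sigma)
}

#' Exchange-free baseline from a set of dispersion series
#'
#' Estimates the expected `R2eff` of residues without exchange contribution
#' (the dotted line under flat dispersion profiles) by an iterative robust
#' location: the per-residue mean `R2eff` over the frequency grid is computed,
#' the baseline is the median of those means, residues whose mean exceeds
#' `median + k_flag * 1.4826 * MAD` are excluded, and the estimate is repeated
#' until stable (at most `max_iter` rounds). The spread is the MAD-scaled
#' robust SD of the surviving residues.
#'
#' @param series_list List of [dispersion_series] sharing one context.
#' @param k_flag Exclusion threshold in robust-SD units (default 2).
#' @param max_iter Maximum refinement rounds (default 10).
#' @return Object of class `baseline_estimate` with fields `r2inf`, `spread`,
#'   `n_supporting_residues`, `excluded_residues`.
#' @export
estimate_baseline <- function(series_list, k_flag = 2, max_iter = 10) {
  if (length(series_list) < 5)
    stop("need at least 5 series to estimate a baseline")
  means <- vapply(series_list, function(s) mean(s$points$r2eff), numeric(1))
  ids <- vapply(series_list, function(s) s$residue_id, integer(1))
  keep <- rep(TRUE, length(means))
  for (it in seq_len(max_iter)) {
    if (!any(keep)) stop("baseline did not converge: all residues excluded")
    ctr <- median(means[keep])
    scl <- mad(means[keep], center = ctr) # 1.4826 * MAD
    new_keep <- means <= ctr + k_flag * max(scl, .Machine$double.eps)
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  if (!any(keep)) stop("baseline did not converge: all residues excluded")
  r2inf <- median(means[keep])
  if (!(r2inf > 0)) stop("baseline estimate is non-positive")
  structure(list(context = series_list[[1]]$context,
                 r2inf = r2inf,
                 spread = mad(means[keep], center = r2inf),
                 n_supporting_residues = sum(keep),
                 excluded_residues = ids[!keep]),
            class = "baseline_estimate")
}

#' Classify a dispersion profile into an exchange regime
#'
#' Uses two statistics: the dispersion amplitude
#' `A = r2eff(nu_min) - r2eff(nu_max)` and the elevation above the
#' exchange-free baseline `E = mean(r2eff) - r2inf`. The label is
#' `"dispersive"` when `A > k_sigma * sigma_A` (errors of the two endpoints in
#' quadrature), else `"fast"` when `E > k_sigma * max(spread, mean sigma)`
#' (a flat profile sitting above the baseline), else `"no_exchange"`.
#'
#' @param series A [dispersion_series].
#' @param baseline A `baseline_estimate` for the same context.
#' @param k_sigma Decision threshold in sigma units (default 3).
#' @return Object of class `regime_label` with fields `residue_id`, `label`
#'   and `evidence` (elevation, amplitude, z-scores).
#' @export
classify_regime <- function(series, baseline, k_sigma = 3) {
  p <- series$points
  n <- nrow(p)
  amplitude <- p$r2eff[1] - p$r2eff[n]
  sigma_a <- sqrt(p$sigma[1]^2 + p$sigma[n]^2)
  elevation <- mean(p$r2eff) - baseline$r2inf
  sigma_e <- max(baseline$spread, mean(p$sigma))
  z_a <- amplitude / sigma_a
  z_e <- elevation / sigma_e
  label <- if (z_a > k_sigma) "dispersive"
           else if (z_e > k_sigma) "fast"
           else "no_exchange"
  structure(list(residue_id = series$residue_id, context = series$context,
                 label = label,
                 evidence = list(mean_elevation = elevation,
                                 amplitude = amplitude,
                                 z_amplitude = z_a, z_elevation = z_e)),
            class = "regime_label")
}

#' Classify every series of one context
#'
#' Convenience wrapper: estimates the baseline from all series and labels each.
#'
#' @inheritParams estimate_baseline
#' @inheritParams classify_regime
#' @return Data frame with columns `residue_id`, `label`, `elevation`,
#'   `amplitude`; the baseline as attribute `"baseline"`.
#' @export
classify_all <- function(series_list, k_flag = 2, k_sigma = 3) {
  bl <- estimate_baseline(series_list, k_flag = k_flag)
  labs <- lapply(series_list, classify_regime, baseline = bl, k_sigma = k_sigma)
  out <- data.frame(
    residue_id = vapply(labs, function(x) x$residue_id, integer(1)),
    label = vapply(labs, function(x) x$label, character(1)),
    elevation = vapply(labs, function(x) x$evidence$mean_elevation, numeric(1)),
    amplitude = vapply(labs, function(x) x$evidence$amplitude, numeric(1)))
  attr(out, "baseline") <- bl
  out
}
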