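#' Chemical shift perturbation between two conditions
#'
#' Combined 1H/15N perturbation per residue,
#' `CSP = sqrt(0.5 (dH)^2 + 0.5 (dN/10)^2)` with `d = bound - free`.
#'
#' @param free,bound Shift tables (data frames with `residue_id`, `delta_H`,
#'   `delta_N`) as returned by [read_shift_table()] or
#'   [gen_csp_dataset()]. Residue sets must match.
#' @return Data frame with columns `residue_id`, `dH_ppm`, `dN_ppm`,
#'   `csp_ppm`.
#' @export
compute_csp <- function(free, bound) {
  if (!setequal(free$residue_id, bound$residue_id))
    stop("residue mismatch between conditions: e.g. residue ",
         setdiff(union(free$residue_id, bound$residue_id),
                 intersect(free$residue_id, bound$residue_id))[1])
  bound <- bound[match(free$residue_id, bound$residue_id), ]
  dH <- bound$delta_H - free$delta_H
  dN <- bound$delta_N - free$delta_N
  data.frame(residue_id = free$residue_id, dH_ppm = dH, dN_ppm = dN,
             csp_ppm = sqrt(0.5 * dH^2 + 0.5 * (dN / 10)^2))
}

#' Flag significant chemical shift perturbations
#'
#' A residue is significant when its CSP exceeds the mean plus `k_sd`
#' standard deviations of all CSPs (strict inequality, so an all-equal set
#' flags nothing).
#'
#' @param csps Data frame from [compute_csp()].
#' @param k_sd SD multiplier (default 2).
#' @return `csps` with a logical `significant` column; attributes `mean`,
#'   `sd`, `threshold`.
#' @export
label_significant <- function(csps, k_sd = 2) {
  if (nrow(csps) < 5) stop("need >= 5 residues")
  m <- mean(csps$csp_ppm); s <- sd(csps$csp_ppm)
  thr <- m + k_sd * s
  csps$significant <- csps$csp_ppm > thr
  attr(csps, "mean") <- m; attr(csps, "sd") <- s; attr(csps, "threshold") <- thr
  csps
}

#' Amide-proton chemical-shift temperature coefficient
#'
#' Ordinary least-squares line of the amide 1H shift versus temperature; the
#' slope is reported in ppb/K. A zero-variance (perfectly constant) series
#' has slope 0 and, by convention, `r_squared = 1`.
#'
#' @param T_K Temperatures in Kelvin (>= 2, no duplicates).
#' @param delta_ppm Amide 1H shifts in ppm.
#' @return List of class `temp_coefficient`: `slope_ppb_per_K`,
#'   `intercept_ppm`, `r_squared`.
#' @export
temp_coefficient <- function(T_K, delta_ppm) {
  if (length(T_K) < 2) stop("need >= 2 temperatures")
  if (anyDuplicated(T_K)) stop("duplicate temperatures")
  ft <- wls_line(T_K, delta_ppm)
  pred <- ft$intercept + ft$slope * T_K
  ss_tot <- sum((delta_ppm - mean(delta_ppm))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum((delta_ppm - pred)^2) / ss_tot
  structure(list(slope_ppb_per_K = ft$slope * 1000,
                 intercept_ppm = ft$intercept, r_squared = r2),
            class = "temp_coefficient")
}

#' Temperature coefficients for a set of shift tables
#'
#' Applies [temp_coefficient()] residue by residue to shift tables acquired
#' at several temperatures.
#'
#' @param tables List of shift tables (each with a context attribute carrying
#'   `temperature_K`, e.g. from [read_shift_table()]).
#' @return Data frame with `residue_id`, `slope_ppb_per_K`, `intercept_ppm`,
#'   `r_squared`.
#' @export
temp_coefficient_table <- function(tables) {
  T_K <- vapply(tables, function(t) attr(t, "context")$temperature_K, numeric(1))
  ids <- sort(Reduce(intersect, lapply(tables, `[[`, "residue_id")))
  rows <- lapply(ids, function(r) {
    dh <- vapply(tables, function(t) t$delta_H[t$residue_id == r], numeric(1))
    tc <- temp_coefficient(T_K, dh)
    data.frame(residue_id = r, slope_ppb_per_K = tc$slope_ppb_per_K,
               intercept_ppm = tc$intercept_ppm, r_squared = tc$r_squared)
  })
  do.call(rbind, rows)
}
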