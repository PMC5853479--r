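# Whole-cell analysis: ramp-slope conductance extraction, Boltzmann fitting,
# reversal-potential estimation, group comparison.

#' Membrane conductance from a conductance-testing ramp
#'
#' Ordinary least-squares slope of current against (corrected) voltage over
#' the trimmed ramp. Because the ramp is brief relative to the gating
#' kinetics, the number of open channels is constant during it and the I-V
#' relation is linear; the slope is the whole-cell conductance set by the
#' preceding pulse.
#'
#' @param time_ms,voltage_mV,current_pA Ramp samples (voltage already
#'   LJP-corrected; units mV and pA).
#' @param trim_ms Discard this much from each end of the ramp (settling),
#'   default 2 ms.
#' @return A list with `g_nS` (slope, nS), `intercept_pA`, `r2` and `n`.
#'   A perfectly constant trace fits exactly with zero slope (`r2` = 1).
#' @export
ramp_conductance <- function(time_ms, voltage_mV, current_pA, trim_ms = 2) {
  stopifnot(length(time_ms) == length(voltage_mV),
            length(time_ms) == length(current_pA))
  keep <- time_ms > min(time_ms) + trim_ms & time_ms < max(time_ms) - trim_ms
  v <- voltage_mV[keep]; i <- current_pA[keep]
  if (length(v) < 5) stop("fewer than 5 ramp samples after trimming")
  fit <- stats::lm.fit(cbind(1, v), i)
  res <- fit$residuals
  ss_res <- sum(res^2)
  ss_tot <- sum((i - mean(i))^2)
  r2 <- if (ss_tot < .Machine$double.eps * max(1, sum(i^2))) 1
        else 1 - ss_res / ss_tot
  list(g_nS = unname(fit$coefficients[2]),
       intercept_pA = unname(fit$coefficients[1]),
       r2 = r2, n = length(v))
}

#' Specific conductance from whole-cell conductance
#'
#' G' = G / area, converting nS to mS (factor 1e-6), giving mS cm^-2.
#'
#' @param g_nS Whole-cell conductance, nS.
#' @param area_cm2 Membrane surface area, cm^2 (> 0).
#' @return Specific conductance, mS cm^-2.
#' @export
specific_conductance <- function(g_nS, area_cm2) {
  stopifnot(is.numeric(g_nS), is.numeric(area_cm2))
  if (any(area_cm2 <= 0)) stop("area must be positive")
  g_nS * 1e-6 / area_cm2
}

.ramp_rows <- function(rec) {
  rec$data$time_ms > rec$meta$protocol$pulse_ms
}

#' Extract the conductance-voltage (G'-E_M) curve from a recording
#'
#' For every sweep, fits the trimmed conductance-testing ramp by OLS
#' ([ramp_conductance()]), converts the slope to specific conductance using
#' the protoplast surface area, and keys the point by the LJP-corrected
#' potential of the preceding pulse. Points whose ramp linearity falls below
#' `r2_gate` are flagged and excluded from subsequent fitting.
#'
#' @param rec A `current_recording`.
#' @param trim_ms Ramp trimming, ms (each end).
#' @param r2_gate Minimum ramp R^2 for an unflagged point (default 0.99).
#' @return An object of class `gv_curve`: a data.frame with columns
#'   `sweep`, `e_m` (corrected pulse potential, mV), `g_nS`, `g_specific`
#'   (mS cm^-2), `r2`, `flagged`; attributes `area_cm2`, `cell_id`,
#'   `cell_type`.
#' @export
extract_gv_curve <- function(rec, trim_ms = 2, r2_gate = 0.99) {
  stopifnot(inherits(rec, "current_recording"))
  prot <- rec$meta$protocol
  area <- surface_area(rec$meta$diameter_um)
  ramp <- rec$data[.ramp_rows(rec), ]
  rows <- lapply(sort(unique(ramp$sweep_index)), function(s) {
    sw <- ramp[ramp$sweep_index == s, ]
    rc <- ramp_conductance(sw$time_ms,
                           correct_ljp(sw$command_mV_nominal, rec$meta$ljp_mV),
                           sw$current_pA, trim_ms = trim_ms)
    data.frame(sweep = s,
               e_m = correct_ljp(prot$pulse_levels_mV[s], rec$meta$ljp_mV),
               g_nS = rc$g_nS,
               g_specific = specific_conductance(rc$g_nS, area),
               r2 = rc$r2,
               flagged = rc$r2 < r2_gate)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("gv_curve", "data.frame"),
            area_cm2 = area, cell_id = rec$meta$cell_id,
            cell_type = rec$meta$cell_type)
}

#' Fit the Boltzmann equation to a G'-E_M curve
#'
#' Bounded Levenberg-Marquardt nonlinear least squares
#' (via \pkg{minpack.lm}) of
#' `g = g_b + g_max_net / (1 + exp(z (e - e_half) / V_T))`, parameterized in
#' (G'_b, G'_max_net, E_1/2, z) with box bounds G'_b >= 0, G'_max_net >= 0,
#' 0 < z <= 5, so G'_max = G'_b + G'_max_net >= G'_b structurally.
#' Initial values: G'_b = min(G'), G'_max_net = range, E_1/2 = voltage of the
#' point nearest mid-conductance, z = 1. Flagged points are excluded.
#' Degenerate or non-convergent inputs yield `converged = FALSE`, never an
#' error or silent NaN.
#'
#' @param curve A `gv_curve` (or data.frame with `e_m`, `g_specific`, and
#'   optionally `flagged`).
#' @param temperature Kelvin.
#' @return An object of class `boltzmann_fit`: list with `g_b`, `g_max`,
#'   `e_half`, `z`, `g_max_net` (= g_max - g_b exactly), `converged`,
#'   `resid_norm`, `n_points`, `temperature`, `cell_id`, `cell_type`.
#' @export
fit_boltzmann <- function(curve, temperature = 295.15) {
  df <- as.data.frame(curve)
  if (!is.null(df$flagged)) df <- df[!df$flagged, ]
  e <- df$e_m; g <- df$g_specific
  fail <- function(msg) {
    structure(list(g_b = NA_real_, g_max = NA_real_, e_half = NA_real_,
                   z = NA_real_, g_max_net = NA_real_, converged = FALSE,
                   message = msg, resid_norm = NA_real_, n_points = length(e),
                   temperature = temperature,
                   cell_id = attr(curve, "cell_id"),
                   cell_type = attr(curve, "cell_type")),
              class = "boltzmann_fit")
  }
  if (length(e) < 6) return(fail("fewer than 6 unflagged points"))
  rng <- max(g) - min(g)
  if (rng <= 1e-9 * max(abs(g), 1)) return(fail("degenerate: constant conductance"))
  vt <- thermal_voltage(temperature)
  start <- c(g_b = max(min(g), 0),
             g_net = rng,
             e_half = e[which.min(abs(g - (min(g) + rng / 2)))],
             z = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ g_b + g_net / (1 + exp(z * (e - e_half) / vt)),
      data = data.frame(e = e, g = g),
      start = as.list(start),
      lower = c(0, 0, min(e) - 200, 1e-3),
      upper = c(Inf, Inf, max(e) + 200, 5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(cnd) NULL)
  if (is.null(fit)) return(fail("nonlinear least squares did not converge"))
  cf <- stats::coef(fit)
  g_b_hat <- unname(cf["g_b"])
  g_max_hat <- unname(cf["g_b"] + cf["g_net"])
  structure(list(g_b = g_b_hat,
                 g_max = g_max_hat,
                 e_half = unname(cf["e_half"]),
                 z = unname(cf["z"]),
                 g_max_net = g_max_hat - g_b_hat,
                 converged = TRUE,
                 message = "ok",
                 resid_norm = sqrt(sum(stats::resid(fit)^2)),
                 n_points = length(e),
                 temperature = temperature,
                 cell_id = attr(curve, "cell_id"),
                 cell_type = attr(curve, "cell_type")),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<boltzmann_fit> NOT converged:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<boltzmann_fit> G'_b %.3f  G'_max %.3f  G'_max_net %.3f mS cm^-2  E_1/2 %.1f mV  z %.2f  (n = %d)\n",
    x$g_b, x$g_max, x$g_max_net, x$e_half, x$z, x$n_points))
  invisible(x)
}

#' Estimate the reversal potential from ramp crossovers
#'
#' Each sweep's conductance-testing ramp is fit with a line in the
#' current-voltage plane. Because the pre-pulses set different numbers of
#' open channels while the open-channel current reverses at the same
#' potential, the ramp lines intersect at (E_rev, 0). The estimator fits a
#' line per ramp, forms all pairwise intersection voltages among ramps whose
#' slopes differ by more than `slope_floor_frac` of the largest absolute
#' slope (near-parallel pairs give unstable intersections), and reports the
#' median intersection with its dispersion.
#'
#' @param rec A `current_recording`.
#' @param trim_ms Ramp trimming, ms.
#' @param slope_floor_frac Minimum pairwise slope difference, as a fraction
#'   of the maximum absolute slope (default 0.05).
#' @return An object of class `reversal_estimate`: list with `e_rev` (mV,
#'   corrected), `intersections`, `dispersion` (SD of intersections, 0 when
#'   only one), `n_pairs`, `in_ramp_span` (logical), and per-ramp `slopes`
#'   and `intercepts`.
#' @export
estimate_reversal <- function(rec, trim_ms = 2, slope_floor_frac = 0.05) {
  stopifnot(inherits(rec, "current_recording"))
  ramp <- rec$data[.ramp_rows(rec), ]
  sweeps <- sort(unique(ramp$sweep_index))
  if (length(sweeps) < 3) stop("need at least 3 ramps")
  fits <- lapply(sweeps, function(s) {
    sw <- ramp[ramp$sweep_index == s, ]
    ramp_conductance(sw$time_ms,
                     correct_ljp(sw$command_mV_nominal, rec$meta$ljp_mV),
                     sw$current_pA, trim_ms = trim_ms)
  })
  m <- vapply(fits, `[[`, numeric(1), "g_nS")
  b <- vapply(fits, `[[`, numeric(1), "intercept_pA")
  floor_nS <- slope_floor_frac * max(abs(m))
  xs <- c()
  for (i in seq_along(m)) for (j in seq_len(i - 1)) {
    if (abs(m[i] - m[j]) > floor_nS) {
      xs <- c(xs, (b[j] - b[i]) / (m[i] - m[j]))
    }
  }
  if (length(xs) == 0) stop("no ramp pairs with distinct slopes: no crossover")
  e_rev <- stats::median(xs)
  span <- sort(correct_ljp(c(rec$meta$protocol$ramp_from_mV,
                             rec$meta$protocol$ramp_to_mV), rec$meta$ljp_mV))
  structure(list(e_rev = e_rev,
                 intersections = xs,
                 dispersion = if (length(xs) > 1) stats::sd(xs) else 0,
                 n_pairs = length(xs),
                 in_ramp_span = e_rev >= span[1] && e_rev <= span[2],
                 slopes = m, intercepts = b),
            class = "reversal_estimate")
}

#' @export
print.reversal_estimate <- function(x, ...) {
  cat(sprintf("<reversal_estimate> E_rev = %.1f mV (SD of %d intersections: %.2f)\n",
              x$e_rev, x$n_pairs, x$dispersion))
  invisible(x)
}

#' Analyze one recording end to end
#'
#' Convenience wrapper: [extract_gv_curve()] then [fit_boltzmann()].
#'
#' @inheritParams extract_gv_curve
#' @inheritParams fit_boltzmann
#' @return A `boltzmann_fit`.
#' @export
analyze_recording <- function(rec, trim_ms = 2, r2_gate = 0.99,
                              temperature = 295.15) {
  fit_boltzmann(extract_gv_curve(rec, trim_ms = trim_ms, r2_gate = r2_gate),
                temperature = temperature)
}

#' Compare fitted gating parameters between cell-type groups
#'
#' Per-cell best-fit parameters are averaged within each group
#' (fit-then-average) and compared with a two-sided Welch t-test per
#' parameter. Non-convergent fits are dropped with a message.
#'
#' @param fits List of `boltzmann_fit` objects.
#' @param group Character/factor vector of group labels, one per fit
#'   (defaults to the fits' `cell_type`).
#' @return An object of class `group_comparison`: a data.frame with one row
#'   per parameter (`g_b`, `g_max`, `g_max_net`, `e_half`, `z`) holding each
#'   group's mean, SE (SD/sqrt(n)) and n, plus the Welch `p_value`. The
#'   difference of group mean E_1/2 is stored in attribute
#'   `e_half_difference` (first group minus second).
#' @export
compare_groups <- function(fits, group = NULL) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, logical(1), "boltzmann_fit")))
  if (is.null(group)) {
    group <- vapply(fits, function(f) as.character(f$cell_type), character(1))
  }
  stopifnot(length(group) == length(fits))
  ok <- vapply(fits, `[[`, logical(1), "converged")
  if (any(!ok)) {
    message(sum(!ok), " non-convergent fit(s) dropped from group averaging")
  }
  fits <- fits[ok]; group <- factor(group[ok])
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (any(table(group) < 2)) stop("need >= 2 converged fits per group")
  params <- c("g_b", "g_max", "g_max_net", "e_half", "z")
  g1 <- levels(group)[1]; g2 <- levels(group)[2]
  rows <- lapply(params, function(p) {
    x <- vapply(fits[group == g1], `[[`, numeric(1), p)
    y <- vapply(fits[group == g2], `[[`, numeric(1), p)
    pv <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
    out <- data.frame(parameter = p,
                      mean1 = mean(x), se1 = stats::sd(x) / sqrt(length(x)),
                      n1 = length(x),
                      mean2 = mean(y), se2 = stats::sd(y) / sqrt(length(y)),
                      n2 = length(y),
                      p_value = pv)
    names(out) <- c("parameter",
                    paste0(c("mean_", "se_", "n_"), g1),
                    paste0(c("mean_", "se_", "n_"), g2), "p_value")
    out
  })
  out <- do.call(rbind, rows)
  ehd <- out[out$parameter == "e_half", 2] - out[out$parameter == "e_half", 5]
  structure(out, class = c("group_comparison", "data.frame"),
            groups = c(g1, g2), e_half_difference = ehd)
}
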