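# Synthetic whole-cell voltage-clamp recordings: a single first-order
# Boltzmann-gated K+ conductance under a pulse + G-V-testing-ramp protocol.

#' Channel model parameters for a simulated protoplast
#'
#' Ground-truth parameters on the LJP-corrected voltage scale.
#'
#' @param g_b Basal specific conductance, mS cm^-2 (>= 0).
#' @param g_max Maximal specific conductance, mS cm^-2 (>= g_b).
#' @param e_half Half-activation voltage, mV.
#' @param z Effective gating charge (> 0).
#' @param e_rev Reversal potential of the current, mV (corrected).
#' @param tau_ms Activation/deactivation time constant of the single
#'   first-order gate, ms (> 0). A voltage-independent default of 100 ms is
#'   used; only the assumption that the 30 ms ramp is too brief to re-gate
#'   the channels matters downstream.
#' @param noise_sd_pA SD of additive Gaussian current noise, pA (>= 0).
#' @param diameter_um Protoplast diameter, um (> 0).
#' @return An object of class `channel_params`.
#' @export
channel_params <- function(g_b, g_max, e_half, z, e_rev,
                           tau_ms = 100, noise_sd_pA = 5, diameter_um = 30) {
  stopifnot(is.numeric(g_b), is.numeric(g_max), is.numeric(e_half),
            is.numeric(z), is.numeric(e_rev))
  if (g_b < 0 || g_max < g_b) stop("need g_max >= g_b >= 0")
  if (z <= 0) stop("gating charge z must be positive")
  if (tau_ms <= 0) stop("time constant must be positive")
  if (noise_sd_pA < 0) stop("noise SD must be non-negative")
  if (diameter_um <= 0) stop("diameter must be positive")
  structure(list(g_b = g_b, g_max = g_max, e_half = e_half, z = z,
                 e_rev = e_rev, tau_ms = tau_ms, noise_sd_pA = noise_sd_pA,
                 diameter_um = diameter_um),
            class = "channel_params")
}

#' Group-mean channel parameters for the two leaf cell types
#'
#' Convenience constructors carrying the group-mean Boltzmann parameters of
#' the inward-rectifying K+ conductance of bundle-sheath cells (BSC:
#' G'_b 0.8, G'_max 1.75 mS cm^-2, E_1/2 14.5 mV, z 1.46, diameter 27.4 um)
#' and mesophyll cells (MC: 0.43, 1.15, -6.5 mV, 1.03, 43.5 um), with a
#' reversal potential of -31 mV in the low-K bath.
#'
#' @param ... Overrides passed to [channel_params()].
#' @return A `channel_params` object.
#' @name cell_type_params
NULL

#' @rdname cell_type_params
#' @export
bsc_params <- function(...) {
  defaults <- list(g_b = 0.8, g_max = 1.75, e_half = 14.5, z = 1.46,
                   e_rev = -31, diameter_um = 27.4)
  do.call(channel_params, utils::modifyList(defaults, list(...)))
}

#' @rdname cell_type_params
#' @export
mc_params <- function(...) {
  defaults <- list(g_b = 0.43, g_max = 1.15, e_half = -6.5, z = 1.03,
                   e_rev = -31, diameter_um = 43.5)
  do.call(channel_params, utils::modifyList(defaults, list(...)))
}

#' Voltage-clamp pulse + ramp protocol
#'
#' The default is the standard sweep family: 1 s square pulses stepping from
#' +120 mV down to -160 mV in -20 mV increments (nominal), each followed by a
#' 30 ms conductance-testing ramp from +70 to -70 mV, sampled at 2 kHz, with
#' a nominal holding potential of 0 mV and an LJP of -23 mV (low-K bath).
#' All protocol voltages are nominal; corrections are applied downstream.
#'
#' @param holding_mV Nominal holding potential, mV.
#' @param pulse_levels_mV Strictly decreasing nominal pulse levels, mV.
#' @param pulse_ms Pulse duration, ms.
#' @param ramp_from_mV,ramp_to_mV Nominal ramp endpoints, mV.
#' @param ramp_ms Ramp duration, ms.
#' @param sampling_hz Sampling rate, Hz (> 0).
#' @param ljp_mV LJP of the bath this protocol is run in, mV.
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(holding_mV = 0,
                           pulse_levels_mV = seq(120, -160, by = -20),
                           pulse_ms = 1000,
                           ramp_from_mV = 70, ramp_to_mV = -70,
                           ramp_ms = 30,
                           sampling_hz = 2000,
                           ljp_mV = -23) {
  if (any(diff(pulse_levels_mV) >= 0)) {
    stop("pulse levels must be strictly decreasing")
  }
  if (sampling_hz <= 0) stop("sampling rate must be positive")
  if (pulse_ms <= 0 || ramp_ms <= 0) stop("durations must be positive")
  structure(list(holding_mV = holding_mV, pulse_levels_mV = pulse_levels_mV,
                 pulse_ms = pulse_ms, ramp_from_mV = ramp_from_mV,
                 ramp_to_mV = ramp_to_mV, ramp_ms = ramp_ms,
                 sampling_hz = sampling_hz, ljp_mV = ljp_mV),
            class = "pulse_protocol")
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a whole-cell recording
#'
#' Generates per-sweep current traces for one protoplast under a pulse + ramp
#' protocol. The open fraction p relaxes first-order (time constant
#' `params$tau_ms`) from its steady state at the corrected holding potential
#' toward the Boltzmann steady state at the corrected pulse potential, and is
#' frozen at its pulse-end value for the duration of the brief ramp. Total
#' current is
#' `area * (g_b + (g_max - g_b) p) * (E - e_rev)` plus Gaussian noise, with E
#' the corrected potential; the emitted command voltages are nominal (LJP
#' correction is an analysis-side step). The gate is assumed to re-equilibrate
#' at holding between sweeps, so sweeps are independent.
#'
#' @param params A `channel_params` object (ground truth).
#' @param protocol A `pulse_protocol` object.
#' @param seed RNG seed (required; the caller's RNG state is untouched).
#' @param cell_id Identifier stored in the metadata.
#' @param cell_type Optional label ("BSC"/"MC"/...).
#' @param temperature Kelvin (stored; used for the gate's Boltzmann curve).
#' @return An object of class `current_recording`: a list with `meta`
#'   (protoplast id, cell type, diameter, LJP, sampling rate, protocol),
#'   `data` (data.frame with `time_ms` within sweep, `command_mV_nominal`,
#'   `current_pA`, `sweep_index`), and `truth` (the generating parameters).
#'   If the ramp is not brief relative to the gating time constant the
#'   frozen-gate assumption is violated and `meta$frozen_gate_warning` is set
#'   (with an R warning).
#' @export
simulate_recording <- function(params, protocol = pulse_protocol(), seed,
                               cell_id = "cell_1", cell_type = NA_character_,
                               temperature = 295.15) {
  stopifnot(inherits(params, "channel_params"),
            inherits(protocol, "pulse_protocol"))
  if (missing(seed)) stop("a seed must be supplied")

  frozen_warn <- protocol$ramp_ms >= params$tau_ms
  if (frozen_warn) {
    warning("ramp duration >= gating time constant: frozen-gate assumption violated")
  }

  dt <- 1000 / protocol$sampling_hz
  n_pulse <- round(protocol$pulse_ms / dt)
  n_ramp <- round(protocol$ramp_ms / dt)
  t_pulse <- seq_len(n_pulse) * dt
  t_ramp <- seq_len(n_ramp) * dt
  area <- surface_area(params$diameter_um)
  ljp <- protocol$ljp_mV

  p_inf <- function(e_corr) {
    open_fraction(e_corr, e_half = params$e_half, z = params$z,
                  temperature = temperature)
  }
  p_hold <- p_inf(correct_ljp(protocol$holding_mV, ljp))

  # nS * mV = pA; g' [mS cm^-2] * area [cm^2] * 1e6 = G [nS]
  current_pA <- function(p, e_corr) {
    g_nS <- (params$g_b + (params$g_max - params$g_b) * p) * area * 1e6
    g_nS * (e_corr - params$e_rev)
  }

  sweeps <- .with_seed(seed, {
    lapply(seq_along(protocol$pulse_levels_mV), function(i) {
      v_pulse <- protocol$pulse_levels_mV[i]
      e_pulse <- correct_ljp(v_pulse, ljp)
      p_ss <- p_inf(e_pulse)
      p_t <- p_ss + (p_hold - p_ss) * exp(-t_pulse / params$tau_ms)
      p_end <- p_t[n_pulse]

      v_ramp <- protocol$ramp_from_mV +
        (protocol$ramp_to_mV - protocol$ramp_from_mV) * t_ramp / protocol$ramp_ms
      e_ramp <- correct_ljp(v_ramp, ljp)

      i_trace <- c(current_pA(p_t, e_pulse), current_pA(p_end, e_ramp))
      if (params$noise_sd_pA > 0) {
        i_trace <- i_trace + stats::rnorm(length(i_trace), 0, params$noise_sd_pA)
      }
      data.frame(time_ms = c(t_pulse, protocol$pulse_ms + t_ramp),
                 command_mV_nominal = c(rep(v_pulse, n_pulse), v_ramp),
                 current_pA = i_trace,
                 sweep_index = i)
    })
  })

  structure(list(
    meta = list(cell_id = cell_id, cell_type = cell_type,
                diameter_um = params$diameter_um, ljp_mV = ljp,
                sampling_hz = protocol$sampling_hz,
                temperature_K = temperature,
                protocol = unclass(protocol),
                frozen_gate_warning = frozen_warn),
    data = do.call(rbind, sweeps),
    truth = params
  ), class = "current_recording")
}

#' @export
print.current_recording <- function(x, ...) {
  cat("<current_recording>", x$meta$cell_id,
      sprintf("(%s, d = %.1f um)\n", x$meta$cell_type, x$meta$diameter_um))
  cat(sprintf("  %d sweeps, %d samples, LJP %g mV, %g Hz\n",
              max(x$data$sweep_index), nrow(x$data), x$meta$ljp_mV,
              x$meta$sampling_hz))
  invisible(x)
}

#' Write / read a recording in the plain-text dialect
#'
#' A recording is stored as two files under `dir`: `<cell_id>.meta.yaml`
#' (protoplast id, cell type, diameter, LJP, sampling rate, protocol) and
#' `<cell_id>.tsv` with columns `time_ms`, `command_mV_nominal`,
#' `current_pA`, `sweep_index`.
#'
#' @param rec A `current_recording`.
#' @param dir Directory (created if needed).
#' @return `write_recording` returns the metadata path invisibly;
#'   `read_recording` returns a `current_recording` (without ground truth).
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "current_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, rec$meta$cell_id)
  meta <- rec$meta
  yaml::write_yaml(meta, paste0(base, ".meta.yaml"))
  utils::write.table(rec$data, paste0(base, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paste0(base, ".meta.yaml"))
}

#' @rdname write_recording
#' @param cell_id Basename of the recording to read.
#' @export
read_recording <- function(dir, cell_id) {
  base <- file.path(dir, cell_id)
  meta <- yaml::read_yaml(paste0(base, ".meta.yaml"))
  dat <- utils::read.table(paste0(base, ".tsv"), sep = "\t", header = TRUE)
  structure(list(meta = meta, data = dat, truth = NULL),
            class = "current_recording")
}
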