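# Shared fixture builders. All synthetic, constructed in code at test time.

# A minimal current_recording containing only ramp segments, one per entry
# of `slopes_nS`, each an exact line current = slope * (E - e_rev) + offset
# in the I-V plane (corrected voltages; ljp = 0 by default so nominal ==
# corrected). Used to test ramp fitting and the crossover estimator against
# hand-constructed geometry.
make_ramp_recording <- function(slopes_nS, e_rev = -20, offsets_pA = 0,
                                ljp = 0, n_samples = 60,
                                ramp_from = 70, ramp_to = -70, ramp_ms = 30) {
  offsets_pA <- rep_len(offsets_pA, length(slopes_nS))
  dt <- ramp_ms / n_samples
  t_ramp <- seq_len(n_samples) * dt
  v_nom <- ramp_from + (ramp_to - ramp_from) * t_ramp / ramp_ms
  sweeps <- lapply(seq_along(slopes_nS), function(i) {
    e <- v_nom + ljp
    data.frame(time_ms = t_ramp, # pulse_ms = 0, so every sample is "ramp"
               command_mV_nominal = v_nom,
               current_pA = slopes_nS[i] * (e - e_rev) + offsets_pA[i],
               sweep_index = i)
  })
  structure(list(
    meta = list(cell_id = "fixture", cell_type = NA, diameter_um = 30,
                ljp_mV = ljp, sampling_hz = 1000 * n_samples / ramp_ms,
                protocol = list(pulse_ms = 0,
                                pulse_levels_mV = seq_along(slopes_nS),
                                ramp_from_mV = ramp_from,
                                ramp_to_mV = ramp_to, ramp_ms = ramp_ms)),
    data = do.call(rbind, sweeps), truth = NULL),
    class = "current_recording")
}

# expression_set built directly from a log2 matrix (columns BSC_* then MC_*)
make_expression_set <- function(log2_matrix, transporter = NULL,
                                category = NULL) {
  if (is.null(rownames(log2_matrix))) {
    rownames(log2_matrix) <- sprintf("g%03d", seq_len(nrow(log2_matrix)))
  }
  ct <- sub("_[0-9]+$", "", colnames(log2_matrix))
  ann <- data.frame(gene_id = rownames(log2_matrix),
                    category = if (is.null(category)) "other" else category,
                    transporter = if (is.null(transporter)) FALSE else transporter)
  structure(list(log2 = log2_matrix,
                 samples = data.frame(sample_id = colnames(log2_matrix),
                                      cell_type = ct),
                 annotation = ann, truth = NULL),
            class = "expression_set")
}

# exhaustive-enumeration oracle for hypergeometric over-representation:
# fraction of all n-subsets of the background with >= k category members
enum_overrep_p <- function(n_bg, k_bg, n_de, k_overlap) {
  bg <- seq_len(n_bg)
  in_cat <- bg <= k_bg
  subsets <- utils::combn(n_bg, n_de)
  hits <- colSums(matrix(in_cat[subsets], nrow = n_de)) >= k_overlap
  mean(hits)
}

# noiseless G'-E_M curve straight from the Boltzmann relation
make_gv_curve <- function(g_b, g_max, e_half, z, e_m = seq(-180, 100, by = 20),
                          temperature = 295.15) {
  g <- boltzmann_conductance(e_m, g_b, g_max, e_half, z,
                             temperature = temperature)
  structure(data.frame(sweep = seq_along(e_m), e_m = e_m, g_nS = NA,
                       g_specific = g, r2 = 1, flagged = FALSE),
            class = c("gv_curve", "data.frame"),
            area_cm2 = surface_area(30), cell_id = "synthetic",
            cell_type = NA)
}
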