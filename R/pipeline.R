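# Orchestration: one config drives simulate -> analyze -> report for the
# three assays, with reproducible seeds and a machine-readable manifest.

#' Pipeline run configuration
#'
#' Aggregates the seeds, physical constants and analysis thresholds used by
#' [run_pipeline()]. Every bath referenced by a stage must have an LJP
#' entry; all thresholds must be positive.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param temperature_K Kelvin.
#' @param ljp_mV Named vector of per-bath LJPs, mV.
#' @param expression_threshold Mean log2 cutoff for "expressed".
#' @param high_expression_threshold Mean log2 cutoff for "highly expressed"
#'   transporters.
#' @param fc_cutoff Absolute linear fold-change cutoff.
#' @param alpha Significance level shared by the DE, enrichment and group
#'   tests.
#' @param ramp_trim_ms Ramp trimming, ms.
#' @param r2_gate Ramp linearity gate.
#' @param n_bsc,n_mc Simulated cells per type in the ephys stage.
#' @param n_rev_per_bath Simulated cells per bath for the reversal-shift
#'   stage.
#' @param stages Character subset of c("ephys", "expression", "imaging").
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       temperature_K = 295.15,
                       ljp_mV = c("low-K" = -23, "30-K" = -14),
                       expression_threshold = 2,
                       high_expression_threshold = 3.5,
                       fc_cutoff = 1.5,
                       alpha = 0.05,
                       ramp_trim_ms = 2,
                       r2_gate = 0.99,
                       n_bsc = 8, n_mc = 4,
                       n_rev_per_bath = 3,
                       stages = c("ephys", "expression", "imaging")) {
  thr <- c(expression_threshold, high_expression_threshold, fc_cutoff,
           alpha, ramp_trim_ms, r2_gate)
  if (any(!is.finite(thr)) || any(thr <= 0)) {
    stop("all thresholds must be positive")
  }
  if (is.null(names(ljp_mV)) || !all(c("low-K", "30-K") %in% names(ljp_mV))) {
    stop("ljp_mV must name an LJP for every bath ('low-K', '30-K')")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(seed = seed, temperature_K = temperature_K,
                 ljp_mV = ljp_mV,
                 expression_threshold = expression_threshold,
                 high_expression_threshold = high_expression_threshold,
                 fc_cutoff = fc_cutoff, alpha = alpha,
                 ramp_trim_ms = ramp_trim_ms, r2_gate = r2_gate,
                 n_bsc = n_bsc, n_mc = n_mc,
                 n_rev_per_bath = n_rev_per_bath, stages = stages),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys map onto [run_config()] arguments; `ljp_mV` is a mapping
#' of bath name to LJP. Validation happens before any compute.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$ljp_mV)) y$ljp_mV <- unlist(y$ljp_mV)
  if (!is.null(y$stages)) y$stages <- unlist(y$stages)
  do.call(run_config, y)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full simulate -> analyze -> report pipeline
#'
#' Executes the requested stages on synthetic data generated under the
#' config's seed and writes tabular results plus a combined summary and a
#' run manifest under `out_dir`:
#' \itemize{
#'   \item ephys: simulates BSC- and MC-parameterized cells, extracts G'-E_M
#'     curves, fits each cell's Boltzmann, compares groups
#'     (`ephys_fits.tsv`, `ephys_group_comparison.tsv`), and estimates the
#'     reversal potential per bath including the bath-K shift
#'     (`ephys_reversal.tsv`).
#'   \item expression: simulates a spiked two-type matrix, runs the DE
#'     filter, expressed-gene Venn, transporter classification and category
#'     enrichment (`de_table.tsv`, `venn.tsv`, `transporters.tsv`,
#'     `enrichment.tsv`).
#'   \item imaging: simulates a two-population field and an equal-potential
#'     (depolarized) control field, measures per-protoplast ratios and
#'     compares the groups (`ratios.tsv`).
#' }
#' `summary.json` collects the headline quantities (group E_1/2 difference,
#' open fractions at the holding potential, E_rev per bath and shift,
#' DE/Venn/classification counts, ratio comparison); `manifest.json` records
#' the config, seeds and package version so any table can be reproduced.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`ephys`,
#'   `expression`, `imaging`, `summary`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  summary <- list()
  temp <- config$temperature_K

  if ("ephys" %in% config$stages) {
    prot_low <- pulse_protocol(ljp_mV = config$ljp_mV[["low-K"]])
    sims <- c(
      lapply(seq_len(config$n_bsc), function(i) {
        simulate_recording(bsc_params(), prot_low, seed = config$seed * 100 + i,
                           cell_id = sprintf("BSC_%02d", i),
                           cell_type = "BSC", temperature = temp)
      }),
      lapply(seq_len(config$n_mc), function(i) {
        simulate_recording(mc_params(), prot_low,
                           seed = config$seed * 100 + 50 + i,
                           cell_id = sprintf("MC_%02d", i),
                           cell_type = "MC", temperature = temp)
      }))
    fits <- lapply(sims, analyze_recording, trim_ms = config$ramp_trim_ms,
                   r2_gate = config$r2_gate, temperature = temp)
    fit_tab <- do.call(rbind, lapply(fits, function(f) {
      data.frame(cell_id = f$cell_id, cell_type = f$cell_type,
                 g_b = f$g_b, g_max = f$g_max, g_max_net = f$g_max_net,
                 e_half = f$e_half, z = f$z, converged = f$converged)
    }))
    cmp <- compare_groups(fits)
    .write_tsv(fit_tab, file.path(out_dir, "ephys_fits.tsv"))
    .write_tsv(as.data.frame(cmp),
               file.path(out_dir, "ephys_group_comparison.tsv"))

    # reversal per bath: low-K cells reverse near -31 mV, raising bath K+
    # to 30 mM moves the K+ equilibrium and the observed reversal to -17 mV
    rev_tab <- do.call(rbind, lapply(seq_len(config$n_rev_per_bath), function(i) {
      r_low <- estimate_reversal(simulate_recording(
        bsc_params(), prot_low, seed = config$seed * 100 + 80 + i,
        cell_id = sprintf("rev_low_%d", i), cell_type = "BSC",
        temperature = temp), trim_ms = config$ramp_trim_ms)
      r_hi <- estimate_reversal(simulate_recording(
        bsc_params(e_rev = -17),
        pulse_protocol(ljp_mV = config$ljp_mV[["30-K"]]),
        seed = config$seed * 100 + 90 + i,
        cell_id = sprintf("rev_30_%d", i), cell_type = "BSC",
        temperature = temp), trim_ms = config$ramp_trim_ms)
      data.frame(cell = i, e_rev_low_k = r_low$e_rev, e_rev_30_k = r_hi$e_rev)
    }))
    .write_tsv(rev_tab, file.path(out_dir, "ephys_reversal.tsv"))

    hold_corr <- correct_ljp(0, config$ljp_mV[["low-K"]])
    mean_of <- function(type, p) {
      mean(fit_tab[[p]][fit_tab$cell_type == type & fit_tab$converged])
    }
    po_at_hold <- function(type) {
      open_fraction(hold_corr, e_half = mean_of(type, "e_half"),
                    z = mean_of(type, "z"), temperature = temp)
    }
    summary$ephys <- list(
      e_half_difference_mV = unname(attr(cmp, "e_half_difference")),
      e_half_p_value = cmp$p_value[cmp$parameter == "e_half"],
      open_fraction_at_holding = list(BSC = po_at_hold("BSC"),
                                      MC = po_at_hold("MC")),
      e_rev_mV = list(low_k = mean(rev_tab$e_rev_low_k),
                      k30 = mean(rev_tab$e_rev_30_k)),
      e_rev_shift_mV = mean(rev_tab$e_rev_30_k) - mean(rev_tab$e_rev_low_k))
    res$ephys <- list(fits = fits, comparison = cmp, reversal = rev_tab)
  }

  if ("expression" %in% config$stages) {
    es <- simulate_expression_matrix(expression_sim_spec(),
                                     seed = config$seed * 100 + 7)
    de <- differential_expression(es, fc_cutoff = config$fc_cutoff,
                                  alpha = config$alpha)
    expressed_bsc <- expressed_genes(es, "BSC", config$expression_threshold)
    expressed_mc <- expressed_genes(es, "MC", config$expression_threshold)
    venn <- venn_summary(expressed_bsc, expressed_mc)
    cls <- classify_transporters(es, de,
                                 high_threshold = config$high_expression_threshold)
    enr <- enrichment(de$gene_id[de$passed_de], es$annotation,
                      rownames(es$log2), alpha = config$alpha, de = de)
    .write_tsv(as.data.frame(de), file.path(out_dir, "de_table.tsv"))
    .write_tsv(venn, file.path(out_dir, "venn.tsv"))
    .write_tsv(as.data.frame(cls), file.path(out_dir, "transporters.tsv"))
    .write_tsv(as.data.frame(enr), file.path(out_dir, "enrichment.tsv"))
    summary$expression <- list(
      n_genes = nrow(es$log2),
      n_expressed = list(BSC = length(expressed_bsc),
                         MC = length(expressed_mc)),
      percent_common = venn$percent_common,
      n_de = sum(de$passed_de),
      transporter_groups = as.list(attr(cls, "counts")),
      n_enriched = sum(enr$enriched))
    res$expression <- list(es = es, de = de, venn = venn,
                           classification = cls, enrichment = enr)
  }

  if ("imaging" %in% config$stages) {
    pair <- simulate_ratio_images(
      default_ratio_image_spec(seed = config$seed * 100 + 11),
      seed = config$seed * 100 + 12)
    tab <- analyze_ratio_images(pair)
    grp <- pair$truth$group[vapply(seq_len(nrow(tab)), function(i) {
      which.min((pair$truth$x - tab$x[i])^2 + (pair$truth$y - tab$y[i])^2)
    }, integer(1))]
    tab$group <- grp
    cmpr <- compare_ratio_groups(tab$ratio, tab$group)
    # depolarizing control: both populations assigned the same potential
    ctrl_pair <- simulate_ratio_images(
      default_ratio_image_spec(seed = config$seed * 100 + 13,
                               potential_bsc = -60, potential_mc = -60),
      seed = config$seed * 100 + 14)
    ctrl <- analyze_ratio_images(ctrl_pair)
    ctrl$group <- ctrl_pair$truth$group[vapply(seq_len(nrow(ctrl)), function(i) {
      which.min((ctrl_pair$truth$x - ctrl$x[i])^2 +
                  (ctrl_pair$truth$y - ctrl$y[i])^2)
    }, integer(1))]
    cmpr_ctrl <- compare_ratio_groups(ctrl$ratio, ctrl$group)
    tab$condition <- "standard"; ctrl$condition <- "depolarized_control"
    .write_tsv(rbind(tab, ctrl), file.path(out_dir, "ratios.tsv"))
    summary$imaging <- list(
      ordering = cmpr$ordering, p_value = cmpr$p_value,
      smaller_group = as.character(cmpr$smaller_group),
      control_p_value = cmpr_ctrl$p_value)
    res$imaging <- list(ratios = tab, comparison = cmpr,
                        control = ctrl, control_comparison = cmpr_ctrl)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(config = unclass(config),
         package = "protophys",
         package_version = as.character(utils::packageVersion("protophys")),
         r_version = R.version.string),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$summary <- summary
  invisible(res)
}
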