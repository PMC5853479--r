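# Synthetic two-cell-type log2 expression matrices with a spiked DE fraction.

#' Specification for a synthetic expression matrix
#'
#' Describes a two-cell-type (BSC/MC), replicated log2 expression matrix with
#' a known differentially expressed (DE) subset. Per-gene baselines are drawn
#' from N(`baseline_mean`, `baseline_sd`); replicate values add
#' N(0, `noise_sd`) noise; DE genes are shifted by their true log2
#' fold-change in the BSC group (positive = higher in BSC). The default
#' design mirrors a 3-replicates-per-type microarray comparison whose log2
#' expression levels have a median near 2.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per cell type (>= 2).
#' @param baseline_mean,baseline_sd Mean and SD of per-gene baseline log2
#'   expression across genes.
#' @param noise_sd Replicate (within-gene) SD of log2 expression.
#' @param n_de Number of spiked DE genes (default 5% of the genes; ignored
#'   when `de_gene_indices` given).
#' @param de_lfc True absolute log2 fold-change of spiked genes; recycled and
#'   alternated in sign unless `true_lfc` is given in full.
#' @param de_gene_indices Optional explicit indices of DE genes (unique, in
#'   range).
#' @param true_lfc Optional explicit signed log2 fold-changes, one per DE
#'   gene.
#' @param categories Category labels to sample per gene.
#' @param category_prob Sampling probabilities for `categories`.
#' @param transporter_frac Fraction of genes flagged as transporters.
#' @return An object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 1000, n_replicates = 3,
                                baseline_mean = 2, baseline_sd = 1.5,
                                noise_sd = 0.2,
                                n_de = round(0.05 * n_genes), de_lfc = 1.5,
                                de_gene_indices = NULL, true_lfc = NULL,
                                categories = c("membrane", "chloroplast",
                                               "transport", "kinase", "other"),
                                category_prob = c(0.20, 0.25, 0.10, 0.05, 0.40),
                                transporter_frac = 0.10) {
  if (n_replicates < 2) stop("need at least 2 replicates per cell type")
  if (!is.null(de_gene_indices)) {
    if (anyDuplicated(de_gene_indices)) stop("DE gene indices must be unique")
    if (any(de_gene_indices < 1 | de_gene_indices > n_genes)) {
      stop("DE gene indices out of range")
    }
    n_de <- length(de_gene_indices)
  }
  if (n_de > n_genes) stop("more DE genes than genes")
  if (!is.null(true_lfc) && length(true_lfc) != n_de) {
    stop("true_lfc must have one entry per DE gene")
  }
  if (noise_sd < 0 || baseline_sd < 0) stop("SDs must be non-negative")
  stopifnot(length(categories) == length(category_prob))
  structure(list(n_genes = n_genes, n_replicates = n_replicates,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, n_de = n_de, de_lfc = de_lfc,
                 de_gene_indices = de_gene_indices, true_lfc = true_lfc,
                 categories = categories, category_prob = category_prob,
                 transporter_frac = transporter_frac),
            class = "expression_sim_spec")
}

#' Simulate a genes x samples log2 expression matrix with ground truth
#'
#' @param spec An `expression_sim_spec`.
#' @param seed RNG seed (required; caller's RNG untouched).
#' @return An object of class `expression_set`: list with
#'   `log2` (genes x samples matrix, rownames = gene ids, colnames = sample
#'   ids), `samples` (data.frame `sample_id`, `cell_type`),
#'   `annotation` (data.frame `gene_id`, `category`, `transporter`), and
#'   `truth` (data.frame `gene_id`, `is_de`, `true_lfc`).
#' @export
simulate_expression_matrix <- function(spec = expression_sim_spec(), seed) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  if (missing(seed)) stop("a seed must be supplied")
  .with_seed(seed, {
    ng <- spec$n_genes; nr <- spec$n_replicates
    gene_id <- sprintf("gene_%04d", seq_len(ng))
    samples <- data.frame(
      sample_id = c(paste0("BSC_", seq_len(nr)), paste0("MC_", seq_len(nr))),
      cell_type = rep(c("BSC", "MC"), each = nr))
    de_idx <- spec$de_gene_indices
    if (is.null(de_idx) && spec$n_de > 0) de_idx <- sample.int(ng, spec$n_de)
    lfc <- rep(0, ng)
    if (length(de_idx)) {
      tl <- spec$true_lfc
      if (is.null(tl)) {
        tl <- rep_len(spec$de_lfc, length(de_idx)) *
          rep_len(c(1, -1), length(de_idx))
      }
      lfc[de_idx] <- tl
    }
    baseline <- stats::rnorm(ng, spec$baseline_mean, spec$baseline_sd)
    mu <- outer(baseline, rep(1, 2 * nr))
    mu[, samples$cell_type == "BSC"] <- mu[, samples$cell_type == "BSC"] + lfc
    vals <- mu + matrix(stats::rnorm(ng * 2 * nr, 0, spec$noise_sd), ng)
    dimnames(vals) <- list(gene_id, samples$sample_id)
    annotation <- data.frame(
      gene_id = gene_id,
      category = sample(spec$categories, ng, replace = TRUE,
                        prob = spec$category_prob),
      transporter = stats::runif(ng) < spec$transporter_frac)
    structure(list(log2 = vals, samples = samples, annotation = annotation,
                   truth = data.frame(gene_id = gene_id,
                                      is_de = lfc != 0, true_lfc = lfc)),
              class = "expression_set")
  })
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d genes x %d samples (%s)\n",
              nrow(x$log2), ncol(x$log2),
              paste(table(x$samples$cell_type), collapse = " + ")))
  invisible(x)
}

#' Write / read an expression set as tab-delimited text
#'
#' The matrix file has genes as rows and a header of sample ids of the form
#' `<cell_type>_<replicate>`; the annotation file has columns `gene_id`,
#' `category`, `transporter`.
#'
#' @param es An `expression_set`.
#' @param matrix_file,annotation_file Paths.
#' @return `read_expression_set` returns an `expression_set` (no truth).
#' @export
write_expression_set <- function(es, matrix_file, annotation_file = NULL) {
  stopifnot(inherits(es, "expression_set"))
  df <- data.frame(gene_id = rownames(es$log2), es$log2, check.names = FALSE)
  utils::write.table(df, matrix_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(annotation_file)) {
    utils::write.table(es$annotation, annotation_file, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(matrix_file)
}

#' @rdname write_expression_set
#' @export
read_expression_set <- function(matrix_file, annotation_file = NULL) {
  df <- utils::read.table(matrix_file, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  cell_type <- sub("_[0-9]+$", "", colnames(m))
  ann <- if (!is.null(annotation_file)) {
    utils::read.table(annotation_file, sep = "\t", header = TRUE)
  } else NULL
  structure(list(log2 = m,
                 samples = data.frame(sample_id = colnames(m),
                                      cell_type = cell_type),
                 annotation = ann, truth = NULL),
            class = "expression_set")
}
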