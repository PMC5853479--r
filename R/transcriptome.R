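# Expression-threshold, differential-expression, Venn, transporter
# classification and category-enrichment logic on a log2 expression matrix.

.type_means <- function(es, cell_type) {
  sel <- es$samples$cell_type == cell_type
  if (!any(sel)) stop("unknown cell type: ", cell_type)
  rowMeans(es$log2[, sel, drop = FALSE])
}

#' Genes expressed in a cell type
#'
#' A gene counts as expressed in a cell type when its mean log2 expression
#' over that type's replicates is at or above `threshold` (default
#' log2 level 2, a median-level cutoff well above array background).
#'
#' @param es An `expression_set`.
#' @param cell_type Cell-type label present in `es$samples`.
#' @param threshold Mean log2 expression cutoff (inclusive).
#' @return Character vector of gene ids.
#' @export
expressed_genes <- function(es, cell_type, threshold = 2) {
  m <- .type_means(es, cell_type)
  names(m)[m >= threshold]
}

#' Two-set Venn summary
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @return A one-row data.frame with `a_only`, `b_only`, `common`, `union`
#'   and `percent_common` (100 * |A n B| / |A u B|, rounded to integer; 0
#'   for two empty sets).
#' @export
venn_summary <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  common <- length(intersect(a, b))
  un <- length(union(a, b))
  data.frame(a_only = length(setdiff(a, b)),
             b_only = length(setdiff(b, a)),
             common = common, union = un,
             percent_common = if (un == 0) 0 else round(100 * common / un))
}

#' Two-group differential expression on a log2 matrix
#'
#' Per-gene two-sample comparison of log2 expression between the two cell
#' types (pooled-variance t-test, identical to a two-group one-way ANOVA),
#' with the linear fold change computed from the anti-logged difference of
#' group means and reported signed: FC = ratio when ratio >= 1, else
#' -1/ratio, where ratio = 2^(mean_BSC - mean_MC). Raw P-values are used
#' throughout (no multiple-testing correction); an optional
#' Benjamini-Hochberg column can be added for exploration but plays no part
#' in the pass flags. The fold-change gate is evaluated on the log2 scale
#' (|delta| >= log2(fc_cutoff), mathematically identical to |FC| >=
#' fc_cutoff and exact at the boundary). Genes with zero pooled variance get
#' a fallback P (1 when the means are equal, 0 otherwise) and are flagged
#' `zero_variance`.
#'
#' @param es An `expression_set` with >= 2 replicates per type.
#' @param fc_cutoff Absolute linear fold-change cutoff (inclusive),
#'   default 1.5.
#' @param alpha P-value cutoff: the DE flag uses P < alpha (strict), the
#'   P-only flag uses P <= alpha.
#' @param group_a,group_b Cell-type labels; fold changes are `group_a`
#'   relative to `group_b`.
#' @param add_bh Add a `p_adj_bh` column (off by default; not used by flags).
#' @return An object of class `differential_result`: data.frame with columns
#'   `gene_id`, `mean_a`, `mean_b`, `delta_log2`, `fold_change` (signed),
#'   `p_value`, `passed_de` (|FC| >= fc_cutoff and P < alpha),
#'   `passed_p_only` (P <= alpha), `zero_variance`.
#' @export
differential_expression <- function(es, fc_cutoff = 1.5, alpha = 0.05,
                                    group_a = "BSC", group_b = "MC",
                                    add_bh = FALSE) {
  stopifnot(inherits(es, "expression_set"))
  sel_a <- es$samples$cell_type == group_a
  sel_b <- es$samples$cell_type == group_b
  n1 <- sum(sel_a); n2 <- sum(sel_b)
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per cell type")
  xa <- es$log2[, sel_a, drop = FALSE]
  xb <- es$log2[, sel_b, drop = FALSE]
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  v1 <- apply(xa, 1, stats::var); v2 <- apply(xb, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  dm <- m1 - m2
  tt <- dm / se
  p <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
  zero_var <- se == 0
  p[zero_var] <- ifelse(dm[zero_var] == 0, 1, 0)
  ratio <- 2^dm
  fc <- ifelse(ratio >= 1, ratio, -1 / ratio)
  # inclusive FC gate on the log2 scale, with an epsilon so a gene sitting
  # exactly on the boundary is not lost to floating-point rounding
  passed_fc <- abs(dm) >= log2(fc_cutoff) - 1e-9
  passed_de <- passed_fc & p < alpha
  out <- data.frame(gene_id = rownames(es$log2),
                    mean_a = m1, mean_b = m2,
                    delta_log2 = dm, fold_change = fc, p_value = p,
                    passed_de = passed_de, passed_p_only = p <= alpha,
                    zero_variance = zero_var, row.names = NULL)
  names(out)[2:3] <- paste0("mean_", c(group_a, group_b))
  if (add_bh) out$p_adj_bh <- stats::p.adjust(p, method = "BH")
  structure(out, class = c("differential_result", "data.frame"),
            groups = c(group_a, group_b),
            fc_cutoff = fc_cutoff, alpha = alpha)
}

#' Classify transporter genes by expression level and differential status
#'
#' Transporter genes are split by whether they are highly expressed
#' (mean log2 >= `high_threshold`, default 3.5) in each cell type, then
#' intersected with the differentially expressed transporter set (the
#' P <= alpha rule with no fold-change restriction): group A is high in MC
#' only, group B high in BSC only, group C high in both; all three are
#' subsets of the differential transporter set and mutually disjoint.
#'
#' @param es An `expression_set` whose `annotation` has a logical
#'   `transporter` column (or supply `transporter_genes`).
#' @param de A `differential_result` for the same matrix.
#' @param high_threshold Mean log2 cutoff for "highly expressed".
#' @param transporter_genes Optional explicit character vector of transporter
#'   gene ids.
#' @return An object of class `transporter_classification`: data.frame with
#'   one row per transporter gene (`gene_id`, `high_bsc`, `high_mc`,
#'   `differential`, `group` in {"A","B","C",NA}); attribute `counts` holds
#'   the per-group totals.
#' @export
classify_transporters <- function(es, de, high_threshold = 3.5,
                                  transporter_genes = NULL) {
  stopifnot(inherits(es, "expression_set"),
            inherits(de, "differential_result"))
  if (is.null(transporter_genes)) {
    if (is.null(es$annotation$transporter)) {
      stop("transporter flags not provided")
    }
    transporter_genes <- es$annotation$gene_id[es$annotation$transporter]
  }
  tg <- intersect(rownames(es$log2), transporter_genes)
  mb <- .type_means(es, "BSC")[tg]
  mm <- .type_means(es, "MC")[tg]
  diff_set <- de$gene_id[de$passed_p_only]
  high_bsc <- mb >= high_threshold
  high_mc <- mm >= high_threshold
  differential <- tg %in% diff_set
  group <- rep(NA_character_, length(tg))
  group[differential & high_mc & !high_bsc] <- "A"
  group[differential & high_bsc & !high_mc] <- "B"
  group[differential & high_bsc & high_mc] <- "C"
  out <- data.frame(gene_id = tg, high_bsc = unname(high_bsc),
                    high_mc = unname(high_mc), differential = differential,
                    group = group)
  structure(out, class = c("transporter_classification", "data.frame"),
            counts = c(A = sum(group == "A", na.rm = TRUE),
                       B = sum(group == "B", na.rm = TRUE),
                       C = sum(group == "C", na.rm = TRUE)),
            high_threshold = high_threshold)
}

#' Category over-representation in a DE gene set
#'
#' One-tailed hypergeometric over-representation test per category against a
#' background gene universe, a stand-in for web-tool enrichment engines
#' (modified-Fisher/EASE scores): P = P(X >= k) for k category members among
#' the n DE genes drawn from a background of N genes containing K category
#' members. Categories with P < alpha are flagged enriched. If a
#' `differential_result` is supplied, each category row also reports how
#' many of its DE genes are higher versus lower in BSC.
#'
#' @param de_genes Character vector of DE gene ids (must be a subset of
#'   `background`).
#' @param categories Named character vector mapping gene id -> category
#'   label, or a data.frame with `gene_id` and `category` columns.
#' @param background Character vector: the gene universe.
#' @param alpha Enrichment cutoff (P < alpha).
#' @param de Optional `differential_result` for the direction split.
#' @return An object of class `enrichment_result`: data.frame with columns
#'   `category`, `n_de_in_cat`, `n_bg_in_cat`, `n_de`, `n_bg`, `p_value`,
#'   `enriched`, and (when `de` given) `n_higher_bsc`, `n_lower_bsc`.
#' @export
enrichment <- function(de_genes, categories, background, alpha = 0.05,
                       de = NULL) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% background)) {
    stop("DE set must be a subset of the background")
  }
  if (is.data.frame(categories)) {
    categories <- stats::setNames(as.character(categories$category),
                                  categories$gene_id)
  }
  cat_map <- categories[background]
  n_bg <- length(background); n_de <- length(de_genes)
  cats <- sort(unique(stats::na.omit(unname(cat_map))))
  rows <- lapply(cats, function(cc) {
    in_cat <- background[!is.na(cat_map) & cat_map == cc]
    k_bg <- length(in_cat)
    k_de <- length(intersect(de_genes, in_cat))
    p <- stats::phyper(k_de - 1, k_bg, n_bg - k_bg, n_de, lower.tail = FALSE)
    row <- data.frame(category = cc, n_de_in_cat = k_de, n_bg_in_cat = k_bg,
                      n_de = n_de, n_bg = n_bg, p_value = p,
                      enriched = p < alpha)
    if (!is.null(de)) {
      sub <- de[de$gene_id %in% intersect(de_genes, in_cat), ]
      row$n_higher_bsc <- sum(sub$delta_log2 > 0)
      row$n_lower_bsc <- sum(sub$delta_log2 < 0)
    }
    row
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(), n_de_in_cat = integer(),
               n_bg_in_cat = integer(), n_de = integer(), n_bg = integer(),
               p_value = numeric(), enriched = logical())
  structure(out, class = c("enrichment_result", "data.frame"), alpha = alpha)
}
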