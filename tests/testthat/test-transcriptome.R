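test_that("expressed-gene sets use the per-type mean with an inclusive cutoff", {
  m <- cbind(BSC_1 = c(1, 2.5, 3, 1.9), BSC_2 = c(1, 1.5, 3, 2.1),
             MC_1 = c(1, 4, 0, 1), MC_2 = c(1, 4, 0, 1))
  rownames(m) <- c("a", "b", "c", "d")
  es <- make_expression_set(m)
  expect_setequal(expressed_genes(es, "BSC"), c("b", "c", "d")) # means 2,3,2
  expect_setequal(expressed_genes(es, "MC"), "b")
  expect_equal(expressed_genes(es, "BSC", threshold = 5), character(0))
  expect_setequal(expressed_genes(es, "BSC", threshold = -Inf),
                  c("a", "b", "c", "d"))
  expect_error(expressed_genes(es, "guard_cell"), "unknown cell type")
})

test_that("Venn summaries: edge cases, constructed 78% fixture, conservation", {
  expect_equal(venn_summary(letters, letters)$percent_common, 100)
  expect_equal(venn_summary(letters[1:5], letters[6:9])$percent_common, 0)
  a <- paste0("g", 1:89)  # |A u B| = 100, |A n B| = 78
  b <- paste0("g", 12:100)
  v <- venn_summary(a, b)
  expect_equal(v$common, 78)
  expect_equal(v$union, 100)
  expect_equal(v$percent_common, 78)
  # counts conserve for arbitrary sets
  set.seed(42)
  for (i in 1:10) {
    x <- sample(letters, sample(0:20, 1))
    y <- sample(letters, sample(0:20, 1))
    vv <- venn_summary(x, y)
    expect_equal(vv$a_only + vv$b_only + vv$common, vv$union)
  }
})

test_that("differential expression matches the classical pooled test and FC rules", {
  es <- simulate_expression_matrix(expression_sim_spec(n_genes = 40, n_de = 5),
                                   seed = 9)
  de <- differential_expression(es)
  # independent oracle: stats::t.test with pooled variance, gene by gene
  for (i in c(1, 7, 20, 40)) {
    tt <- t.test(es$log2[i, 1:3], es$log2[i, 4:6], var.equal = TRUE)
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$delta_log2[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
  # signed FC convention: |FC| >= 1, sign follows the mean difference
  expect_true(all(abs(de$fold_change) >= 1))
  expect_true(all(de$fold_change[de$delta_log2 > 0] >= 1))
  expect_true(all(de$fold_change[de$delta_log2 < 0] <= -1))
  expect_equal(abs(de$fold_change), pmax(2^de$delta_log2, 2^-de$delta_log2))
})

test_that("identical group means give |FC| = 1 and the boundary FC passes inclusively", {
  m <- rbind(flat = rep(2, 6),
             edge = c(rep(2 + log2(1.5), 3), rep(2, 3)),
             below = c(rep(2 + log2(1.49), 3), rep(2, 3)))
  colnames(m) <- c(paste0("BSC_", 1:3), paste0("MC_", 1:3))
  es <- make_expression_set(m)
  de <- differential_expression(es)
  expect_equal(abs(de$fold_change[1]), 1)
  expect_equal(de$fold_change[2], 1.5) # exactly on the cutoff
  # zero-variance fallback: flagged, P = 1 when equal, P = 0 when shifted
  expect_true(all(de$zero_variance))
  expect_equal(de$p_value, c(1, 0, 0))
  expect_true(de$passed_de[2])   # >= 1.5 is inclusive
  expect_false(de$passed_de[3])  # 1.49 fails the fold-change gate
  expect_false(de$passed_de[1])
})

test_that("DE flag is monotone in the mean shift at fixed variance", {
  set.seed(7)
  noise <- matrix(rnorm(6, 0, 0.2), 1)
  shifts <- seq(0, 2, by = 0.1)
  passed <- vapply(shifts, function(s) {
    m <- matrix(4 + noise + c(rep(s, 3), rep(0, 3)), 1)
    colnames(m) <- c(paste0("BSC_", 1:3), paste0("MC_", 1:3))
    differential_expression(make_expression_set(m))$passed_de
  }, logical(1))
  expect_true(all(diff(passed) >= 0)) # once on, never off as the shift grows
})

test_that("spiked genes are recovered from the synthetic matrix", {
  es <- simulate_expression_matrix(expression_sim_spec(), seed = 123)
  de <- differential_expression(es)
  truth <- es$truth$is_de
  sens <- sum(de$passed_de & truth) / sum(truth)
  spec <- 1 - sum(de$passed_de & !truth) / sum(!truth)
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.98)
})

test_that("under the null, the P <= alpha rate matches alpha", {
  es <- simulate_expression_matrix(
    expression_sim_spec(n_genes = 4000, n_de = 0), seed = 55)
  de <- differential_expression(es)
  rate <- mean(de$passed_p_only)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("transporter classification reproduces a constructed A/B/C fixture", {
  # 1 gene high in MC only, 5 high in BSC only, 2 high in both -- all
  # differential; plus one high-both non-differential and one high-neither
  n <- 10
  base_bsc <- c(1, rep(5, 5), 5, 5, 5, 1)
  base_mc <- c(5, rep(1, 5), 5, 5, 5, 1)
  diffp <- c(TRUE, rep(TRUE, 5), TRUE, TRUE, FALSE, TRUE)
  m <- matrix(0, n, 6,
              dimnames = list(sprintf("tg%02d", 1:n),
                              c(paste0("BSC_", 1:3), paste0("MC_", 1:3))))
  set.seed(11)
  for (i in 1:n) {
    shift <- if (diffp[i]) base_bsc[i] - base_mc[i] + 0.5 else 0
    m[i, ] <- c(base_mc[i] + shift + rnorm(3, 0, 0.05),
                base_mc[i] + rnorm(3, 0, 0.05))
  }
  es <- make_expression_set(m, transporter = rep(TRUE, n))
  de <- differential_expression(es)
  cls <- classify_transporters(es, de)
  counts <- attr(cls, "counts")
  expect_equal(unname(counts["A"]), 1)
  expect_equal(unname(counts["B"]), 5)
  expect_equal(unname(counts["C"]), 2)
  # groups are disjoint subsets of the differential transporter set
  expect_false(any(duplicated(cls$gene_id[!is.na(cls$group)])))
  expect_true(all(cls$differential[!is.na(cls$group)]))
  expect_true(is.na(cls$group[cls$gene_id == "tg10"])) # high in neither
  expect_true(is.na(cls$group[cls$gene_id == "tg09"])) # not differential
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  # constructed case: background 20, category 5, DE 4, overlap 3
  bg <- sprintf("g%02d", 1:20)
  cats <- setNames(ifelse(seq_along(bg) <= 5, "cat", "rest"), bg)
  de_set <- c("g01", "g02", "g03", "g10")
  enr <- enrichment(de_set, cats, bg)
  p_enum <- enum_overrep_p(n_bg = 20, k_bg = 5, n_de = 4, k_overlap = 3)
  expect_equal(enr$p_value[enr$category == "cat"], p_enum, tolerance = 1e-12)
  # random small instances, background <= 25
  set.seed(99)
  for (i in 1:8) {
    n_bg <- sample(8:25, 1); k_bg <- sample(1:(n_bg - 1), 1)
    n_de <- sample(2:4, 1)
    bg <- sprintf("x%02d", seq_len(n_bg))
    cats <- setNames(ifelse(seq_len(n_bg) <= k_bg, "cat", "rest"), bg)
    de_set <- sample(bg, n_de)
    k <- sum(de_set %in% bg[seq_len(k_bg)])
    enr <- enrichment(de_set, cats, bg)
    expect_equal(enr$p_value[enr$category == "cat"],
                 enum_overrep_p(n_bg, k_bg, n_de, k),
                 tolerance = 1e-12)
  }
})

test_that("enrichment edge cases and direction split", {
  bg <- sprintf("g%02d", 1:20)
  cats <- setNames(rep("all", 20), bg)
  # category spanning the whole background can never be over-represented
  expect_equal(enrichment(c("g01", "g05"), cats, bg)$p_value, 1)
  # empty DE set: nothing enriched
  enr0 <- enrichment(character(0), cats, bg)
  expect_false(any(enr0$enriched))
  expect_error(enrichment("not_in_bg", cats, bg), "subset")
  expect_error(enrichment("g01", cats, character(0)), "empty background")
  # direction split follows the DE signs
  es <- simulate_expression_matrix(expression_sim_spec(n_genes = 200), seed = 2)
  de <- differential_expression(es)
  enr <- enrichment(de$gene_id[de$passed_de], es$annotation,
                    rownames(es$log2), de = de)
  expect_true(all(enr$n_higher_bsc + enr$n_lower_bsc <= enr$n_de_in_cat))
  up <- de$gene_id[de$passed_de & de$delta_log2 > 0]
  ann <- setNames(es$annotation$category, es$annotation$gene_id)
  for (cc in enr$category) {
    expect_equal(enr$n_higher_bsc[enr$category == cc],
                 sum(ann[up] == cc))
  }
})

test_that("expression set round-trips through tab-delimited files", {
  dir <- withr::local_tempdir()
  es <- simulate_expression_matrix(expression_sim_spec(n_genes = 30), seed = 8)
  write_expression_set(es, file.path(dir, "m.tsv"), file.path(dir, "a.tsv"))
  back <- read_expression_set(file.path(dir, "m.tsv"), file.path(dir, "a.tsv"))
  expect_equal(back$log2, es$log2, tolerance = 1e-8)
  expect_equal(back$samples$cell_type, es$samples$cell_type)
  expect_equal(back$annotation$transporter, es$annotation$transporter)
})
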