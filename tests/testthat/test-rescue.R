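toy_deg <- function(genes, lfc, p) {
  d <- data.frame(gene_id = genes, log2fc = lfc, p = p, fdr = bh_adjust(p),
                  mean_log_expression = 5, degenerate = FALSE)
  class(d) <- c("deg_table", "data.frame")
  d
}

test_that("directional_overlap matches a hand tally and reports zero FCs", {
  genes <- paste0("g", 1:12)
  # hand assignment: g1-2 up/up, g3-5 up/down, g6 down/up, g7-8 down/down,
  # g9 zero FC in B, g10-12 not significant in both
  a <- toy_deg(genes,
               lfc = c(1, 2, 1, 1, 2, -1, -2, -1, 1, 1, -1, 2),
               p = c(rep(0.01, 9), 0.5, 0.01, 0.5))
  b <- toy_deg(genes,
               lfc = c(2, 1, -1, -2, -1, 1, -1, -2, 0, 1, 1, 1),
               p = c(rep(0.01, 9), 0.01, 0.5, 0.01))
  ov <- directional_overlap(a, b, alpha = 0.05)
  expect_equal(ov$counts,
               c(up_up = 2, up_down = 3, down_up = 1, down_down = 2))
  expect_equal(ov$n_total_overlap, 8)
  expect_equal(ov$n_zero_excluded, 1)
  expect_setequal(ov$genes$up_down, c("g3", "g4", "g5"))
  expect_error(directional_overlap(a, b, alpha = 1.5), "alpha")
})

test_that("overlap cells always sum to the total (partition property)", {
  set.seed(31)
  for (i in 1:10) {
    n <- 80
    genes <- paste0("g", 1:n)
    a <- toy_deg(genes, rnorm(n), runif(n))
    b <- toy_deg(genes, rnorm(n), runif(n))
    for (mode in c("nominal_p", "fdr")) {
      ov <- directional_overlap(a, b, threshold_mode = mode)
      expect_equal(sum(ov$counts), ov$n_total_overlap)
      expect_equal(sum(lengths(ov$genes)), ov$n_total_overlap)
    }
  }
})

test_that("overlap_fisher reduces to the hypergeometric oracle", {
  genes <- paste0("g", 1:10)
  a <- toy_deg(genes, rep(1, 10), c(rep(0.01, 3), rep(0.5, 7)))
  b <- toy_deg(genes, rep(1, 10), c(0.01, 0.01, 0.5, 0.01, rep(0.5, 6)))
  # K = 3 (g1-3), n = 3 (g1, g2, g4), k = 2, N = 10
  fr <- overlap_fisher(a, b, direction = "any")
  expect_equal(fr$p_one_sided, 22 / 120)
  # zero overlap -> p = 1
  b2 <- toy_deg(genes, rep(1, 10), c(rep(0.5, 7), rep(0.01, 3)))
  expect_equal(overlap_fisher(a, b2)$p_one_sided,
               hyper_upper_oracle(0, 3, 3, 10))
  # identical tables: saturated overlap, minimal p for the margins
  expect_equal(overlap_fisher(a, a)$overlap_k, 3)
  expect_equal(overlap_fisher(a, a)$p_one_sided,
               hyper_upper_oracle(3, 3, 3, 10))
  # directional restriction
  a3 <- toy_deg(genes, c(1, -1, 1, rep(1, 7)), c(rep(0.01, 3), rep(0.5, 7)))
  fr_up <- overlap_fisher(a3, b, direction = "up_up")
  expect_equal(fr_up$query_size_K, 2)
})

test_that("rescue_classify applies the endpoint rule and partitions exactly", {
  # 4 genotype groups x 3 samples; expression constructed by hand
  meta <- data.frame(
    sample_id = sprintf("s%02d", 1:12),
    htt_genotype = rep(c("WT", "Q111", "WT", "Q111"), each = 3),
    hdac_genotype = rep(c("WT", "WT", "KO", "KO"), each = 3))
  grp <- genotype_group(meta)
  mk_expr <- function(vals) {
    # vals: named list group -> mean; small jitter for nonzero variance
    v <- numeric(12)
    for (g in names(vals)) v[grp == g] <- vals[[g]] + c(-0.01, 0, 0.01)
    v
  }
  expr <- rbind(
    resc = mk_expr(list(WT_WT = 5, Q111_WT = 7, WT_KO = 5, Q111_KO = 5)),
    stuck = mk_expr(list(WT_WT = 5, Q111_WT = 7, WT_KO = 5, Q111_KO = 9)),
    samedir = mk_expr(list(WT_WT = 5, Q111_WT = 7, WT_KO = 6, Q111_KO = 5)))
  colnames(expr) <- meta$sample_id
  ov <- structure(list(
    counts = c(up_up = 1, up_down = 2, down_up = 0, down_down = 0),
    n_total_overlap = 3, n_zero_excluded = 0,
    genes = list(up_up = "samedir", up_down = c("resc", "stuck"),
                 down_up = character(0), down_down = character(0)),
    alpha = 0.05, threshold_mode = "nominal_p"),
    class = "directional_overlap")
  rc <- rescue_classify(expr, meta, ov)
  expect_equal(rc$rescued_opposite_up, "resc")
  expect_equal(length(rc$rescued_opposite_down), 0)
  # same-direction gene has equal endpoints but is never "rescued"
  expect_gt(rc$endpoint_p[["samedir"]], 0.05)
  expect_setequal(rc$not_normalized, c("stuck", "samedir"))
  # exact partition
  expect_setequal(c(rc$rescued_opposite_up, rc$rescued_opposite_down,
                    rc$not_normalized), unlist(ov$genes))
  expect_equal(rc$n_rescued, 1)
})

test_that("relative_impact_permutation matches exhaustive enumeration", {
  set.seed(32)
  genes <- paste0("g", 1:10)
  for (i in 1:5) {
    lfc_wt <- stats::setNames(rnorm(10), genes)
    lfc_ko <- stats::setNames(rnorm(10), genes)
    set_genes <- sample(genes, 3)
    pr <- relative_impact_permutation(lfc_wt, lfc_ko, set_genes,
                                      n_perm = 4000, seed = 100 + i)
    reduced <- abs(lfc_ko) < abs(lfc_wt)
    p_exact <- perm_exhaustive_oracle(reduced, match(set_genes, genes))
    expect_lt(abs(pr$p_empirical - p_exact), 0.05)
    expect_equal(pr$observed_stat, sum(reduced[set_genes]))
  }
})

test_that("permutation is deterministic, bounded, and treats ties strictly", {
  lfc_wt <- stats::setNames(c(rep(2, 5), rep(0.5, 15)), paste0("g", 1:20))
  lfc_ko <- stats::setNames(c(rep(1, 5), rep(0.5, 15)), paste0("g", 1:20))
  set_genes <- paste0("g", 1:5)
  p1 <- relative_impact_permutation(lfc_wt, lfc_ko, set_genes,
                                    n_perm = 500, seed = 9)
  p2 <- relative_impact_permutation(lfc_wt, lfc_ko, set_genes,
                                    n_perm = 500, seed = 9)
  expect_identical(p1$p_empirical, p2$p_empirical)
  expect_gte(p1$p_empirical, 1 / 501)
  expect_lte(p1$p_empirical, 1)
  # ties (|ko| == |wt|) count as NOT reduced
  expect_equal(p1$observed_stat, 5)
  tied <- relative_impact_permutation(lfc_wt, lfc_wt, set_genes,
                                      n_perm = 100, seed = 9)
  expect_equal(tied$observed_stat, 0)
  expect_equal(tied$p_empirical, 1)

  expect_error(relative_impact_permutation(lfc_wt, lfc_ko, "nope",
                                           n_perm = 10, seed = 1),
               "not contained")
  expect_error(relative_impact_permutation(lfc_wt, lfc_ko, names(lfc_wt),
                                           n_perm = 10, seed = 1),
               "universe")
  expect_error(relative_impact_permutation(lfc_wt, lfc_ko, set_genes,
                                           n_perm = 0, seed = 1), "n_perm")
})

test_that("cross_study_concordance splits by direction agreement", {
  genes <- paste0("g", 1:8)
  a <- toy_deg(genes, c(1, 1, -1, -1, -1, 1, 1, -1),
               c(rep(0.01, 6), 0.5, 0.5))
  b <- toy_deg(genes, c(1, 1, -1, -1, -1, -1, 1, -1),
               c(rep(0.01, 6), 0.5, 0.5))
  cc <- cross_study_concordance(a, b)
  expect_equal(cc$n_both_up, 2)
  expect_equal(cc$n_both_down, 3)
  expect_equal(cc$n_opposite, 1)
  expect_equal(cc$n_common, 6)
  expect_equal(cc$n_both_up + cc$n_both_down + cc$n_opposite, cc$n_common)

  same <- cross_study_concordance(a, a)
  expect_equal(same$n_opposite, 0)
  expect_equal(same$n_common, 6)
})

test_that("geneset_enrichment tests overlap against the background", {
  bg <- paste0("g", 1:20)
  query <- bg[1:10]
  sets <- list(half = bg[1:10], disjoint = bg[11:20],
               empty_after = c("x1", "x2"))
  expect_warning(res <- geneset_enrichment(query, bg, sets), "skipped")
  expect_equal(nrow(res), 2)
  half <- res[res$set == "half", ]
  expect_equal(half$overlap, 10)
  expect_equal(half$p, hyper_upper_oracle(10, 10, 10, 20))
  expect_equal(res$p[res$set == "disjoint"], 1)
  expect_true(all(res$fdr >= res$p))
  expect_error(geneset_enrichment(c(query, "zz"), bg, sets), "absent")
})

test_that("read_gmt parses the tab-delimited set format", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tother desc\tg2\tg4"), f)
  sets <- read_gmt(f)
  expect_named(sets, c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("setA\tdesc_only", bad)
  expect_error(read_gmt(bad), "malformed")
})
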