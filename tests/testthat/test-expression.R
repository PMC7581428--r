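toy_meta <- function(n_per = 3) {
  grid <- expand.grid(htt_genotype = c("WT", "Q111"),
                      hdac_genotype = c("WT", "KO"),
                      stringsAsFactors = FALSE)
  meta <- grid[rep(seq_len(4), each = n_per), ]
  meta$sample_id <- sprintf("s%02d", seq_len(nrow(meta)))
  meta$sex <- rep_len(c("M", "F"), nrow(meta))
  meta
}

test_that("filter_genes keeps genes detected in every sample of one group", {
  meta <- toy_meta(3)
  set.seed(21)
  counts <- matrix(rpois(20 * 12, 3), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20), meta$sample_id))
  grp <- genotype_group(meta)
  # hand-label: plant pass via the WT_KO group for genes 1-4, fail elsewhere
  counts[] <- pmin(counts, 5)                     # nothing passes initially
  counts[1:4, grp == "WT_KO"] <- 6
  counts[5, grp == "Q111_KO"] <- c(6, 6, 5)       # one sample below -> fail
  manual_keep <- sprintf("g%02d", 1:4)
  filt <- filter_genes(counts, meta)
  expect_setequal(rownames(filt), manual_keep)

  # order invariance
  perm_s <- sample(ncol(counts)); perm_g <- sample(nrow(counts))
  filt2 <- filter_genes(counts[perm_g, perm_s], meta)
  expect_setequal(rownames(filt2), manual_keep)

  # annotation filters
  ann <- data.frame(gene_id = rownames(counts),
                    length_nt = c(100, rep(300, 19)),
                    biotype = c("protein_coding", "rRNA",
                                rep("protein_coding", 18)))
  filt3 <- filter_genes(counts, meta, annotation = ann)
  expect_setequal(rownames(filt3), c("g03", "g04"))
  expect_error(filter_genes(counts, meta, annotation = ann[, 1:2]),
               "annotation needs")
  expect_error(filter_genes(counts[, 1:3], meta[1:2, ]), "metadata")
})

test_that("normalize_log_cpm matches hand arithmetic", {
  # sample s1 has library size exactly 1e6 with 100 counts on gene a
  m <- matrix(c(100, 1e6 - 100, 50, 50), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  lc <- normalize_log_cpm(m)
  expect_equal(lc["a", "s1"], log2(101), tolerance = 1e-10)  # count 100 / 1e6
  expect_equal(normalize_log_cpm(matrix(c(0, 10), 2, 1))[1, 1], 0)
  expect_error(normalize_log_cpm(matrix(0, 2, 2)), "empty library")
})

test_that("pca_samples separates planted clusters and orders variance", {
  set.seed(22)
  base <- matrix(rnorm(50 * 10, 5, 0.1), nrow = 50)
  base[1:10, 6:10] <- base[1:10, 6:10] + 5     # block separating two groups
  dimnames(base) <- list(paste0("g", 1:50), paste0("s", 1:10))
  p <- pca_samples(base)
  expect_false(p$degenerate)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_lte(sum(p$variance_fraction), 1 + 1e-8)
  # PC1 separates the two sample blocks
  expect_true(max(p$scores[1:5, 1]) < min(p$scores[6:10, 1]) ||
                min(p$scores[1:5, 1]) > max(p$scores[6:10, 1]))

  # rank-1 limit: one informative gene dominates PC1
  r1 <- matrix(5, nrow = 20, ncol = 6,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  r1[1, ] <- c(1, 2, 3, 4, 5, 6)
  expect_gt(pca_samples(r1)$variance_fraction[1], 0.999)

  cst <- matrix(3, 5, 5, dimnames = list(paste0("g", 1:5), paste0("s", 1:5)))
  expect_true(pca_samples(cst)$degenerate)
})

test_that("de_test flags degenerate genes and flips sign with the contrast", {
  sim <- make_sim(23, n_genes = 300)
  counts <- sim$counts
  counts["gene00001", ] <- 7                     # identical everywhere
  deg <- de_test(counts, sim$meta, 3)
  i <- match("gene00001", deg$gene_id)
  expect_true(deg$degenerate[i])
  expect_equal(deg$log2fc[i], 0)
  expect_equal(deg$p[i], 1)
  expect_equal(deg$fdr, bh_adjust(deg$p))
  expect_true(all(deg$fdr >= deg$p, na.rm = TRUE))

  fwd <- contrast_spec(3)
  rev <- list(id = 3L, group_a = fwd$group_b, group_b = fwd$group_a)
  deg_r <- de_test(counts, sim$meta, rev)
  expect_equal(deg_r$log2fc, -deg$log2fc)
  expect_equal(deg_r$p, deg$p)
})

test_that("de_test detects planted effects and respects covariates", {
  sim <- make_sim(24, n_genes = 500, dispersion = 0.05,
                  fractions = c(q111_up = 0.05, q111_down = 0.05), delta = 2)
  filt <- filter_genes(sim$counts, sim$meta)
  deg <- de_test(filt, sim$meta, 3)
  cls <- sim$truth$class[match(deg$gene_id, sim$truth$gene_id)]
  planted <- cls %in% c("q111_up", "q111_down")
  expect_gte(mean(deg$p[planted] < 1e-3), 0.95)
  # direction recovered
  expect_true(all(deg$log2fc[cls == "q111_up"] > 0))
  expect_true(all(deg$log2fc[cls == "q111_down"] < 0))

  # covariate GLM path runs and finds the same planted genes
  degc <- de_test(filt, sim$meta, 3, covariates = "sex")
  expect_gte(mean(degc$p[planted] < 1e-3, na.rm = TRUE), 0.9)
  # collinear covariate is named
  meta_bad <- sim$meta
  meta_bad$badcov <- meta_bad$htt_genotype
  expect_error(de_test(filt, meta_bad, 3, covariates = "badcov"),
               "collinear")
  expect_error(de_test(filt, sim$meta, 3, covariates = "nope"),
               "not in metadata")
})

test_that("logcpm-lm method is a calibrated alternative", {
  sim <- make_sim(25, n_genes = 400, fractions = c(q111_up = 0))
  filt <- filter_genes(sim$counts, sim$meta)
  deg <- de_test(filt, sim$meta, 3, method = "logcpm-lm")
  p <- deg$p[!deg$degenerate & !is.na(deg$p)]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("contrast_spec defines the five comparisons", {
  expect_equal(contrast_spec(3)$group_a, "Q111_WT")
  expect_equal(contrast_spec(3)$group_b, "WT_WT")
  expect_equal(contrast_spec(5)$group_a, "Q111_KO")
  expect_equal(contrast_spec(5)$group_b, "WT_WT")
  expect_error(contrast_spec(6), "1\\.\\.5")
})

test_that("deg tables round-trip through TSV", {
  sim <- make_sim(26, n_genes = 50)
  deg <- de_test(filter_genes(sim$counts, sim$meta), sim$meta, 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_deg_table(deg, f)
  back <- read_deg_table(f)
  expect_equal(back$gene_id, deg$gene_id)
  expect_equal(back$log2fc, deg$log2fc, tolerance = 1e-12)
  expect_equal(back$p, deg$p, tolerance = 1e-12)
})
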