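#' Derive the four Htt x Hdac genotype groups from sample metadata
#'
#' @param meta Data frame with columns `sample_id`, `htt_genotype`
#'   (`"Q111"`/`"WT"`) and `hdac_genotype` (`"KO"`/`"WT"`), optionally
#'   `sex` and `batch`.
#' @return Factor of group labels `WT_WT`, `Q111_WT`, `WT_KO`, `Q111_KO`
#'   (Htt genotype first), named by sample.
#' @export
genotype_group <- function(meta) {
  req <- c("sample_id", "htt_genotype", "hdac_genotype")
  if (!all(req %in% names(meta))) {
    stop("genotype_group: metadata needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (!all(meta$htt_genotype %in% c("Q111", "WT")) ||
      !all(meta$hdac_genotype %in% c("KO", "WT"))) {
    stop("genotype_group: htt_genotype must be Q111/WT and hdac_genotype KO/WT",
         call. = FALSE)
  }
  g <- factor(paste(meta$htt_genotype, meta$hdac_genotype, sep = "_"),
              levels = c("WT_WT", "Q111_WT", "WT_KO", "Q111_KO"))
  names(g) <- meta$sample_id
  g
}

#' The five pairwise genotype-group contrasts
#'
#' Contrast definitions (group A vs group B, B is the baseline):
#' 1 = WT_KO vs WT_WT (Hdac knockout effect in wild-type Htt),
#' 2 = Q111_KO vs Q111_WT (knockout effect in the disease background),
#' 3 = Q111_WT vs WT_WT (disease-allele effect, Hdac wild-type),
#' 4 = Q111_KO vs WT_KO (disease-allele effect in the knockout),
#' 5 = Q111_KO vs WT_WT (double mutant vs wild-type).
#'
#' @param id Integer 1-5.
#' @return List with `id`, `group_a`, `group_b`.
#' @export
contrast_spec <- function(id) {
  id <- as.integer(id)
  defs <- list(
    `1` = c("WT_KO", "WT_WT"),
    `2` = c("Q111_KO", "Q111_WT"),
    `3` = c("Q111_WT", "WT_WT"),
    `4` = c("Q111_KO", "WT_KO"),
    `5` = c("Q111_KO", "WT_WT"))
  if (is.na(id) || !as.character(id) %in% names(defs)) {
    stop("contrast_spec: id must be 1..5", call. = FALSE)
  }
  d <- defs[[as.character(id)]]
  list(id = id, group_a = d[1], group_b = d[2])
}

check_counts_meta <- function(counts, meta) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("gene and sample identifiers must be unique", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing)) {
    stop("samples without metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
}

#' Detection filter on a count matrix
#'
#' Keeps genes having at least `min_count` counts in every sample of at
#' least one genotype group (the spike-in derived detection rule), and
#' optionally removes short genes and unwanted biotypes when an annotation
#' table is supplied.
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param meta Sample metadata (see [genotype_group]).
#' @param min_count Detection threshold, default 6 reads.
#' @param annotation Optional data frame with columns `gene_id`,
#'   `length_nt`, `biotype`.
#' @param min_gene_length_nt Genes shorter than this are dropped when
#'   annotation is given (default 250).
#' @param excluded_biotypes Biotypes dropped when annotation is given
#'   (default tRNA and rRNA).
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, meta, min_count = 6, annotation = NULL,
                         min_gene_length_nt = 250,
                         excluded_biotypes = c("tRNA", "rRNA")) {
  meta <- check_counts_meta(counts, meta)
  stopifnot(min_count >= 0)
  grp <- genotype_group(meta)
  keep <- rep(FALSE, nrow(counts))
  for (g in levels(grp)) {
    cols <- which(grp == g)
    if (length(cols) == 0L) next
    keep <- keep |
      (matrixStats_rowMins(counts[, cols, drop = FALSE]) >= min_count)
  }
  out <- counts[keep, , drop = FALSE]
  if (!is.null(annotation)) {
    req <- c("gene_id", "length_nt", "biotype")
    if (!all(req %in% names(annotation))) {
      stop("filter_genes: annotation needs columns ",
           paste(req, collapse = ", "), call. = FALSE)
    }
    ann <- annotation[match(rownames(out), annotation$gene_id), ]
    ok <- !is.na(ann$gene_id) &
      ann$length_nt >= min_gene_length_nt &
      !(ann$biotype %in% excluded_biotypes)
    out <- out[ok, , drop = FALSE]
  }
  out
}

# row minima without extra dependencies
matrixStats_rowMins <- function(m) {
  if (ncol(m) == 1L) return(as.numeric(m[, 1]))
  do.call(pmin, as.data.frame(m))
}

#' Log2 counts-per-million transform
#'
#' `log2(1e6 * count / library_size + 1)` per entry, where library size is
#' the column sum.  The +1 keeps zeros at zero and the transform monotone.
#'
#' @param counts Count matrix, genes x samples.
#' @return Real matrix of the same shape.
#' @export
normalize_log_cpm <- function(counts) {
  libs <- colSums(counts)
  if (any(libs <= 0)) stop("normalize_log_cpm: empty library", call. = FALSE)
  log2(sweep(counts, 2, libs, "/") * 1e6 + 1)
}

#' PCA of samples from a log-expression matrix
#'
#' Gene-centered singular value decomposition; samples are observations.
#'
#' @param log_matrix Genes x samples real matrix.
#' @return List with `scores` (samples x components), `variance_fraction`
#'   (nonincreasing, sums to <= 1), and `degenerate` (TRUE when the matrix
#'   is constant and components are undefined).
#' @export
pca_samples <- function(log_matrix) {
  if (ncol(log_matrix) < 3L) {
    stop("pca_samples: need at least 3 samples", call. = FALSE)
  }
  x <- t(log_matrix)                      # samples x genes
  x <- sweep(x, 2, colMeans(x), "-")      # center each gene
  if (all(abs(x) < 1e-12)) {
    return(list(scores = matrix(0, nrow(x), 0), variance_fraction = numeric(0),
                degenerate = TRUE))
  }
  sv <- svd(x)
  ncomp <- sum(sv$d > 1e-10)
  scores <- x %*% sv$v[, seq_len(ncomp), drop = FALSE]
  rownames(scores) <- colnames(log_matrix)
  colnames(scores) <- paste0("PC", seq_len(ncomp))
  varfrac <- sv$d[seq_len(ncomp)]^2 / sum(sv$d^2)
  list(scores = scores, variance_fraction = varfrac, degenerate = FALSE)
}

# ---------------------------------------------------------------------------
# Negative-binomial machinery for de_test
# ---------------------------------------------------------------------------

# Gene-wise method-of-moments dispersion on group-mean-corrected counts,
# shrunk 50/50 toward a fitted mean-dispersion trend phi(mu) = b0 + b1/mu,
# floored at 1e-4.  `y` genes x samples, `s` library sizes, `grp` factor.
estimate_dispersion <- function(y, s, grp, floor = 1e-4, cap = 25) {
  sbar <- mean(s)
  z <- sweep(y, 2, s / sbar, "/")   # counts rescaled to the mean library
  mu <- rowMeans(z)
  n <- ncol(y)
  ngrp <- nlevels(droplevels(grp))
  # pooled within-group unbiased variance
  ssq <- rep(0, nrow(y))
  for (g in levels(droplevels(grp))) {
    cols <- which(grp == g)
    zg <- z[, cols, drop = FALSE]
    ssq <- ssq + rowSums((zg - rowMeans(zg))^2)
  }
  v <- ssq / (n - ngrp)
  phi_raw <- (v - mu) / mu^2
  phi_raw[!is.finite(phi_raw)] <- NA_real_
  phi_clamped <- pmin(pmax(phi_raw, floor), cap)
  # trend: least squares of clamped phi on 1/mu over informative genes
  ok <- is.finite(phi_clamped) & mu > 0
  if (sum(ok) >= 10) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[ok]), phi_clamped[ok])
    phi_trend <- pmin(pmax(fit$coefficients[1] + fit$coefficients[2] / mu,
                           floor), cap)
  } else {
    phi_trend <- rep(stats::median(phi_clamped, na.rm = TRUE), nrow(y))
    phi_trend[!is.finite(phi_trend)] <- floor
  }
  phi <- 0.5 * ifelse(is.finite(phi_clamped), phi_clamped, phi_trend) +
    0.5 * phi_trend
  pmin(pmax(phi, floor), cap)
}

# Vectorized NB mean fit: for each gene solve for m in mu_j = m * s_j
# by Newton on eta = log m.  y genes x samples, s sample sizes (relative),
# phi per-gene dispersion.  Returns the per-gene fitted m.
nb_fit_mean <- function(y, s, phi, n_iter = 30) {
  m <- pmax(as.numeric(rowSums(y)) / sum(s), 1e-10)
  for (it in seq_len(n_iter)) {
    mu <- outer(m, s)                      # genes x samples
    w <- 1 + phi * mu
    score <- rowSums((y - mu) / w)
    info <- rowSums(mu / w)
    step <- score / pmax(info, 1e-12)
    step <- pmax(pmin(step, 3), -3)        # damp
    m <- m * exp(step)
    m <- pmax(m, 1e-12)
    if (max(abs(step)) < 1e-10) break
  }
  m
}

nb_loglik <- function(y, mu, phi) {
  size <- 1 / phi
  rowSums(stats::dnbinom(y, size = size, mu = pmax(mu, 1e-12), log = TRUE))
}

#' Per-gene differential expression test between two genotype groups
#'
#' Default method `nb-lrt`: a per-gene negative-binomial log-linear model
#' with a genotype-group factor (plus optional known covariates such as sex
#' or batch) and log library-size offset.  Gene-wise dispersions are
#' method-of-moments estimates on group-mean-corrected counts, shrunk 50/50
#' toward the fitted mean-dispersion trend and floored at 1e-4; the group
#' effect is tested by a likelihood-ratio chi-square with 1 df.  Method
#' `logcpm-lm` instead fits an ordinary linear model on log2-CPM and uses
#' the t-test on the group coefficient.
#'
#' Fold changes are reported as log2 of group A over group B (`group_b` is
#' the baseline), so reversing the contrast flips the sign and leaves the
#' p-value unchanged.  Genes with identical counts in all samples are
#' flagged degenerate (`log2fc = 0`, `p = 1`); genes whose fit fails get
#' `p = NA` and are excluded from the BH adjustment.
#'
#' @param counts Filtered count matrix, genes x samples.
#' @param meta Sample metadata (see [genotype_group]).
#' @param contrast A [contrast_spec] (or integer id 1-5).
#' @param covariates Optional character vector of metadata columns to
#'   adjust for (e.g. `"sex"`, `"batch"`).
#' @param method `"nb-lrt"` (default) or `"logcpm-lm"`.
#' @return A `deg_table` data.frame: `gene_id`, `log2fc`, `p`, `fdr`,
#'   `mean_log_expression` (mean log2-CPM), `degenerate`.
#' @export
de_test <- function(counts, meta, contrast, covariates = NULL,
                    method = c("nb-lrt", "logcpm-lm")) {
  method <- match.arg(method)
  if (is.numeric(contrast)) contrast <- contrast_spec(contrast)
  meta <- check_counts_meta(counts, meta)
  grp_all <- genotype_group(meta)
  sel <- grp_all %in% c(contrast$group_a, contrast$group_b)
  if (sum(grp_all == contrast$group_a) < 2L ||
      sum(grp_all == contrast$group_b) < 2L) {
    stop("de_test: need >= 2 samples in each contrasted group", call. = FALSE)
  }
  y <- as.matrix(counts[, sel, drop = FALSE])
  storage.mode(y) <- "double"
  meta_s <- meta[sel, , drop = FALSE]
  # baseline = group_b so the group coefficient is log-FC of A over B
  grp <- factor(as.character(grp_all[sel]),
                levels = c(contrast$group_b, contrast$group_a))
  libs <- colSums(y)
  if (any(libs <= 0)) stop("de_test: empty library", call. = FALSE)
  s <- libs / mean(libs)

  mean_log_expr <- rowMeans(normalize_log_cpm(y))
  degenerate <- apply(y, 1, function(r) all(r == r[1]))

  if (method == "logcpm-lm") {
    res <- de_logcpm_lm(y, s, grp, meta_s, covariates)
  } else if (is.null(covariates)) {
    res <- de_nb_fast(y, s, grp)
  } else {
    res <- de_nb_glm(y, s, grp, meta_s, covariates)
  }
  res$log2fc[degenerate] <- 0
  res$p[degenerate] <- 1

  out <- data.frame(gene_id = rownames(counts),
                    log2fc = res$log2fc,
                    p = res$p,
                    fdr = bh_adjust(res$p),
                    mean_log_expression = mean_log_expr,
                    degenerate = degenerate,
                    row.names = NULL)
  class(out) <- c("deg_table", "data.frame")
  attr(out, "contrast") <- contrast
  attr(out, "method") <- method
  out
}

# fast two-group NB LRT (no covariates): closed-ish MLE group means via
# vectorized Newton, plug-in shrunk dispersion, chi-square df = 1
de_nb_fast <- function(y, s, grp) {
  phi <- estimate_dispersion(y, s * mean(colSums(y)), grp)
  a_cols <- which(grp == levels(grp)[2])
  b_cols <- which(grp == levels(grp)[1])
  m_a <- nb_fit_mean(y[, a_cols, drop = FALSE], s[a_cols], phi)
  m_b <- nb_fit_mean(y[, b_cols, drop = FALSE], s[b_cols], phi)
  m_0 <- nb_fit_mean(y, s, phi)
  ll_full <- nb_loglik(y[, a_cols, drop = FALSE], outer(m_a, s[a_cols]), phi) +
    nb_loglik(y[, b_cols, drop = FALSE], outer(m_b, s[b_cols]), phi)
  ll_null <- nb_loglik(y, outer(m_0, s), phi)
  lrt <- pmax(2 * (ll_full - ll_null), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  eps <- 0.5 / mean(colSums(y))            # half-count pseudo for zero groups
  log2fc <- log2((m_a + eps) / (m_b + eps))
  list(log2fc = log2fc, p = p)
}

build_design <- function(grp, meta_s, covariates) {
  df <- data.frame(.group = grp)
  for (cv in covariates) {
    if (!cv %in% names(meta_s)) {
      stop("de_test: covariate '", cv, "' not in metadata", call. = FALSE)
    }
    v <- meta_s[[cv]]
    df[[cv]] <- if (is.numeric(v)) v else factor(v)
  }
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("de_test: design is collinear; aliased columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

# NB LRT with covariates via per-gene GLM fits at fixed shrunk dispersion
de_nb_glm <- function(y, s, grp, meta_s, covariates) {
  phi <- estimate_dispersion(y, s * mean(colSums(y)), grp)
  X <- build_design(grp, meta_s, covariates)
  gcol <- grep("^\\.group", colnames(X))
  X0 <- X[, -gcol, drop = FALSE]
  off <- log(s)
  n <- nrow(y)
  log2fc <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    yi <- y[i, ]
    fam <- MASS::negative.binomial(theta = 1 / phi[i], link = "log")
    fit1 <- try(suppressWarnings(
      stats::glm.fit(X, yi, family = fam, offset = off)), silent = TRUE)
    fit0 <- try(suppressWarnings(
      stats::glm.fit(X0, yi, family = fam, offset = off)), silent = TRUE)
    if (inherits(fit1, "try-error") || inherits(fit0, "try-error") ||
        !fit1$converged || !fit0$converged) next
    lrt <- max(fit0$deviance - fit1$deviance, 0)
    p[i] <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    log2fc[i] <- fit1$coefficients[gcol] / log(2)
  }
  list(log2fc = log2fc, p = p)
}

# ordinary linear model on log2-CPM, vectorized across genes
de_logcpm_lm <- function(y, s, grp, meta_s, covariates) {
  lcpm <- normalize_log_cpm(y)
  X <- if (is.null(covariates)) {
    stats::model.matrix(~ .group, data = data.frame(.group = grp))
  } else {
    build_design(grp, meta_s, covariates)
  }
  gcol <- grep("^\\.group", colnames(X))
  fit <- stats::lm.fit(X, t(lcpm))
  df_res <- nrow(X) - ncol(X)
  res <- fit$residuals                 # samples x genes
  sigma2 <- colSums(res^2) / df_res
  xtxinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * xtxinv[gcol, gcol])
  beta <- fit$coefficients[gcol, ]
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = df_res, lower.tail = FALSE)
  p[!is.finite(tstat)] <- NA_real_
  list(log2fc = unname(beta), p = unname(p))
}

#' Write a DEG table as TSV
#' @param deg A `deg_table` from [de_test].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(deg, path) {
  data.table::fwrite(as.data.frame(deg), path, sep = "\t")
  invisible(path)
}

#' Read a DEG table written by [write_deg_table]
#' @param path TSV path with columns `gene_id`, `log2fc`, `p`, `fdr`.
#' @return A `deg_table` data.frame.
#' @export
read_deg_table <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  req <- c("gene_id", "log2fc", "p", "fdr")
  if (!all(req %in% names(d))) {
    stop("read_deg_table: missing columns: ",
         paste(setdiff(req, names(d)), collapse = ", "), call. = FALSE)
  }
  class(d) <- c("deg_table", "data.frame")
  d
}
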