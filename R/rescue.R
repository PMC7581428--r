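sig_genes <- function(deg, alpha, threshold_mode) {
  col <- if (threshold_mode == "fdr") "fdr" else "p"
  ok <- !is.na(deg[[col]]) & deg[[col]] < alpha
  deg[ok, , drop = FALSE]
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
}

#' Directional overlap of two DEG tables
#'
#' Genes significant in both tables (nominal p or FDR below `alpha`) are
#' cross-classified by the signs of their log2 fold-changes into four cells:
#' up in A & up in B, up/down, down/up, down/down.  Genes with a zero
#' fold-change in either table cannot be signed; they are excluded from the
#' cells and reported in `n_zero_excluded`.
#'
#' With A = the disease-allele contrast and B = the knockout contrast in the
#' disease background, the two opposite-sign cells (`up_down`, `down_up`)
#' are the candidate rescue pool and the two same-sign cells the
#' exacerbation pool.
#'
#' @param deg_a,deg_b `deg_table` data frames sharing a gene namespace.
#' @param alpha Significance threshold (default 0.05).
#' @param threshold_mode `"nominal_p"` (default) or `"fdr"`.
#' @return An object of class `directional_overlap`: list with `counts`
#'   (named vector `up_up`, `up_down`, `down_up`, `down_down`),
#'   `n_total_overlap`, `n_zero_excluded`, `genes` (list of gene-id vectors
#'   per cell), `alpha`, `threshold_mode`.
#' @export
directional_overlap <- function(deg_a, deg_b, alpha = 0.05,
                                threshold_mode = c("nominal_p", "fdr")) {
  threshold_mode <- match.arg(threshold_mode)
  check_alpha(alpha)
  sa <- sig_genes(deg_a, alpha, threshold_mode)
  sb <- sig_genes(deg_b, alpha, threshold_mode)
  common <- intersect(sa$gene_id, sb$gene_id)
  la <- sa$log2fc[match(common, sa$gene_id)]
  lb <- sb$log2fc[match(common, sb$gene_id)]
  nonzero <- la != 0 & lb != 0
  n_zero <- sum(!nonzero)
  common <- common[nonzero]
  la <- la[nonzero]; lb <- lb[nonzero]
  cell <- paste(ifelse(la > 0, "up", "down"), ifelse(lb > 0, "up", "down"),
                sep = "_")
  cells <- c("up_up", "up_down", "down_up", "down_down")
  genes <- lapply(cells, function(cl) common[cell == cl])
  names(genes) <- cells
  counts <- vapply(genes, length, integer(1))
  structure(list(counts = counts, n_total_overlap = sum(counts),
                 n_zero_excluded = n_zero, genes = genes,
                 alpha = alpha, threshold_mode = threshold_mode),
            class = "directional_overlap")
}

#' @export
print.directional_overlap <- function(x, ...) {
  cat(sprintf(
    "Directional overlap (%s < %g): total %d\n  up/up %d  up/down %d  down/up %d  down/down %d  (zero-FC excluded: %d)\n",
    x$threshold_mode, x$alpha, x$n_total_overlap,
    x$counts["up_up"], x$counts["up_down"], x$counts["down_up"],
    x$counts["down_down"], x$n_zero_excluded))
  invisible(x)
}

#' One-sided Fisher test of DEG-list overlap
#'
#' Tests over-representation of the overlap between the significant genes of
#' two DEG tables against their shared analyzed-gene universe.  For
#' directional variants the margins are restricted to the corresponding
#' sign(s): `up_up` tests up-in-A against up-in-B; `same` and `opposite`
#' keep the full significant lists as margins and count only same- or
#' opposite-direction overlap.
#'
#' @param deg_a,deg_b `deg_table` data frames.
#' @param direction One of `"any"`, `"same"`, `"up_up"`, `"down_down"`,
#'   `"opposite"`.
#' @param alpha Significance threshold.
#' @param threshold_mode `"nominal_p"` or `"fdr"`.
#' @return A `fisher_result` (see [fisher_one_sided]).
#' @export
overlap_fisher <- function(deg_a, deg_b,
                           direction = c("any", "same", "up_up",
                                         "down_down", "opposite"),
                           alpha = 0.05,
                           threshold_mode = c("nominal_p", "fdr")) {
  direction <- match.arg(direction)
  threshold_mode <- match.arg(threshold_mode)
  check_alpha(alpha)
  universe <- intersect(deg_a$gene_id, deg_b$gene_id)
  if (length(universe) == 0L) {
    stop("overlap_fisher: empty shared gene universe", call. = FALSE)
  }
  sa <- sig_genes(deg_a, alpha, threshold_mode)
  sb <- sig_genes(deg_b, alpha, threshold_mode)
  sa <- sa[sa$gene_id %in% universe, ]
  sb <- sb[sb$gene_id %in% universe, ]
  if (direction %in% c("up_up", "down_down")) {
    want <- if (direction == "up_up") 1 else -1
    sa <- sa[sign(sa$log2fc) == want, ]
    sb <- sb[sb$gene_id %in% universe & sign(sb$log2fc) == want, ]
  }
  common <- intersect(sa$gene_id, sb$gene_id)
  if (direction %in% c("same", "opposite")) {
    la <- sa$log2fc[match(common, sa$gene_id)]
    lb <- sb$log2fc[match(common, sb$gene_id)]
    agree <- sign(la) * sign(lb)
    common <- common[if (direction == "same") agree > 0 else agree < 0]
  }
  fisher_one_sided(length(common), nrow(sa), nrow(sb), length(universe))
}

#' Classify overlap genes as rescued or not normalized
#'
#' For every gene in a directional overlap (disease contrast vs knockout
#' contrast), runs a two-sided unpaired t-test on normalized log expression
#' between the two endpoint genotypes, wild-type (`WT_WT`) and double
#' mutant (`Q111_KO`).  A gene is *rescued* when (i) it sits in an
#' opposite-direction cell (counter-regulated by the knockout) and (ii) its
#' endpoint expression no longer differs (p > `alpha`).  Every overlap gene
#' is assigned to exactly one of `rescued_opposite_up` (up by the disease
#' allele), `rescued_opposite_down`, or `not_normalized`.
#'
#' @param expr Normalized log-expression matrix (genes x samples), e.g.
#'   from [normalize_log_cpm].
#' @param meta Sample metadata (see [genotype_group]).
#' @param overlap A `directional_overlap` built with A = disease contrast,
#'   B = knockout contrast.
#' @param alpha Endpoint-test threshold (default 0.05).
#' @param variance_mode Passed to the per-gene t-tests.
#' @return An object of class `rescue_result`: gene-id vectors
#'   `rescued_opposite_up`, `rescued_opposite_down`, `not_normalized`;
#'   `endpoint_p` named per-gene p-values; counts in `n_rescued`.
#' @export
rescue_classify <- function(expr, meta, overlap, alpha = 0.05,
                            variance_mode = "pooled") {
  stopifnot(inherits(overlap, "directional_overlap"))
  check_alpha(alpha)
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("rescue_classify: expression samples missing from metadata",
         call. = FALSE)
  }
  grp <- genotype_group(meta)
  a_cols <- which(grp == "WT_WT")
  b_cols <- which(grp == "Q111_KO")
  if (length(a_cols) < 2L || length(b_cols) < 2L) {
    stop("rescue_classify: need >= 2 samples in WT_WT and Q111_KO",
         call. = FALSE)
  }
  all_genes <- unlist(overlap$genes, use.names = FALSE)
  missing <- setdiff(all_genes, rownames(expr))
  if (length(missing)) {
    stop("rescue_classify: overlap genes absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  p_endpoint <- vapply(all_genes, function(g) {
    two_sample_ttest(expr[g, a_cols], expr[g, b_cols],
                     variance_mode = variance_mode)$p_two_sided
  }, numeric(1))
  names(p_endpoint) <- all_genes
  normalized <- names(p_endpoint)[p_endpoint > alpha]
  resc_up <- intersect(overlap$genes$up_down, normalized)
  resc_down <- intersect(overlap$genes$down_up, normalized)
  not_norm <- setdiff(all_genes, c(resc_up, resc_down))
  structure(list(rescued_opposite_up = resc_up,
                 rescued_opposite_down = resc_down,
                 not_normalized = not_norm,
                 endpoint_p = p_endpoint,
                 n_rescued = length(resc_up) + length(resc_down),
                 alpha = alpha),
            class = "rescue_result")
}

#' @export
print.rescue_result <- function(x, ...) {
  cat(sprintf(
    "Rescue classification: %d rescued (%d up-by-disease + %d down-by-disease), %d not normalized\n",
    x$n_rescued, length(x$rescued_opposite_up),
    length(x$rescued_opposite_down), length(x$not_normalized)))
  invisible(x)
}

#' Permutation test for reduced relative impact of the disease allele
#'
#' For a gene set of interest, counts how many member genes have a strictly
#' smaller absolute log2 fold-change of the disease allele in the knockout
#' background than in the wild-type background
#' (`|lfc_ko| < |lfc_wt|`; ties count as no reduction), then compares this
#' count with its null distribution over `n_perm` random gene sets of the
#' same size drawn without replacement from the shared gene universe.  The
#' empirical p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, so it is never zero.
#'
#' @param lfc_wt_background,lfc_ko_background Named numeric vectors of
#'   per-gene log2 fold-changes (disease vs wild-type allele) in the two
#'   backgrounds; names define the universe (their intersection is used).
#' @param gene_set Character vector of genes, a strict subset of the
#'   universe.
#' @param n_perm Number of permutations (default 100000).
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @return An object of class `permutation_result`: `set_size`,
#'   `universe_size`, `n_perm`, `observed_stat`, `null_mean`,
#'   `null_quantiles`, `p_empirical`, `seed`.
#' @export
relative_impact_permutation <- function(lfc_wt_background, lfc_ko_background,
                                        gene_set, n_perm = 100000, seed) {
  if (missing(seed)) stop("relative_impact_permutation: seed is required",
                          call. = FALSE)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) {
    stop("relative_impact_permutation: n_perm must be >= 1", call. = FALSE)
  }
  universe <- intersect(names(lfc_wt_background), names(lfc_ko_background))
  gene_set <- unique(as.character(gene_set))
  if (!all(gene_set %in% universe)) {
    stop("relative_impact_permutation: gene set not contained in universe: ",
         paste(utils::head(setdiff(gene_set, universe), 5), collapse = ", "),
         call. = FALSE)
  }
  if (length(universe) <= length(gene_set)) {
    stop("relative_impact_permutation: universe must exceed the gene set",
         call. = FALSE)
  }
  reduced <- abs(lfc_ko_background[universe]) <
    abs(lfc_wt_background[universe])          # strict; ties not reduced
  observed <- sum(reduced[gene_set])
  k <- length(gene_set)
  N <- length(universe)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(reduced[sample.int(N, k)]),
           numeric(1))
  })
  p <- (1 + sum(null_stats >= observed)) / (n_perm + 1)
  structure(list(set_size = k, universe_size = N, n_perm = n_perm,
                 observed_stat = observed,
                 null_mean = mean(null_stats),
                 null_quantiles = stats::quantile(
                   null_stats, c(0.025, 0.25, 0.5, 0.75, 0.975)),
                 p_empirical = p, seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Relative-impact permutation: %d/%d set genes reduced; null mean %.2f over %d draws from %d genes; p = %.3g (seed %d)\n",
    x$observed_stat, x$set_size, x$null_mean, x$n_perm, x$universe_size,
    x$p_empirical, x$seed))
  invisible(x)
}

#' Cross-study concordance of two DEG tables
#'
#' Counts genes significant in both studies and splits them by direction
#' agreement of the fold change.
#'
#' @param deg_a,deg_b `deg_table` data frames sharing a gene namespace.
#' @param threshold_mode `"nominal_p"` or `"fdr"`.
#' @param alpha Significance threshold.
#' @return List of class `concordance_result` with `threshold_mode`,
#'   `n_common`, `n_both_up`, `n_both_down`, `n_opposite`, `genes_both_up`,
#'   `genes_both_down`.
#' @export
cross_study_concordance <- function(deg_a, deg_b,
                                    threshold_mode = c("nominal_p", "fdr"),
                                    alpha = 0.05) {
  threshold_mode <- match.arg(threshold_mode)
  check_alpha(alpha)
  ov <- directional_overlap(deg_a, deg_b, alpha = alpha,
                            threshold_mode = threshold_mode)
  structure(list(threshold_mode = threshold_mode,
                 n_common = ov$n_total_overlap,
                 n_both_up = unname(ov$counts["up_up"]),
                 n_both_down = unname(ov$counts["down_down"]),
                 n_opposite = unname(ov$counts["up_down"] +
                                       ov$counts["down_up"]),
                 genes_both_up = ov$genes$up_up,
                 genes_both_down = ov$genes$down_down),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Cross-study concordance (%s): %d common significant genes (%d up in both, %d down in both, %d opposite)\n",
    x$threshold_mode, x$n_common, x$n_both_up, x$n_both_down, x$n_opposite))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited gene-set format: one set per line, fields are set
#' name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("read_gmt: malformed line (need name, description, >=1 gene)",
           call. = FALSE)
    }
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Gene-set over-representation of a query list against a background
#'
#' For each gene set, a one-sided Fisher exact test of the overlap between
#' the query list and the set, both restricted to the background (the list
#' of all analyzed genes); BH adjustment is applied across sets.  Sets with
#' no background members are skipped with a warning.
#'
#' @param query Character vector of genes of interest; must be a subset of
#'   `background`.
#' @param background Character vector, the analyzed-gene universe.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt]).
#' @return A data.frame of class `enrichment_result`: `set`, `set_size`
#'   (within background), `overlap`, `p`, `fdr`, sorted by p.
#' @export
geneset_enrichment <- function(query, background, sets) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  bad <- setdiff(query, background)
  if (length(bad)) {
    stop("geneset_enrichment: query genes absent from background: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  N <- length(background)
  K <- length(query)
  rows <- lapply(names(sets), function(nm) {
    sg <- intersect(sets[[nm]], background)
    if (length(sg) == 0L) {
      warning("geneset_enrichment: set '", nm,
              "' has no background members; skipped", call. = FALSE)
      return(NULL)
    }
    k <- length(intersect(query, sg))
    fr <- fisher_one_sided(k, K, length(sg), N)
    data.frame(set = nm, set_size = length(sg), overlap = k,
               p = fr$p_one_sided)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0))
  }
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
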