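#' Simulate a cohort of fragment-analysis peak traces
#'
#' Emulates somatic CAG expansion in a population of cells per mouse under a
#' Poisson step model: each cell is stable with probability
#' `stable_fraction`; otherwise it gains `k ~ Poisson(lambda * age_months)`
#' CAG units (one unit per expansion event).  The per-mouse repeat-length
#' histogram of the cell population becomes the peak heights of a trace,
#' optionally perturbed by multiplicative log-normal height noise.  The
#' analytic expected expansion index is
#' `(1 - stable_fraction) * lambda * age_months`.
#'
#' @param n_mice_per_group Number of mice simulated for each genotype.
#' @param genotype_rate Named numeric vector of expansion rates lambda
#'   (CAG units per cell per month), one per genotype, e.g.
#'   `c(WT = 3.0, KO = 2.5)`.
#' @param age_months Age at sampling in months.
#' @param stable_fraction Fraction of cells that never expand (e.g.
#'   non-MSN cells in bulk striatum), default 0.
#' @param n_cells Cells aggregated per trace (default 10000).
#' @param modal_repeat Inherited CAG length, default 111.
#' @param height_noise_cv Coefficient of variation of multiplicative
#'   log-normal peak-height noise, default 0 (none).
#' @param seed Integer RNG seed (required).
#' @return List with `traces` (named list of [peak_trace]) and `truth`
#'   (data.frame `mouse_id`, `genotype`, `true_index` -- the analytic
#'   expectation).
#' @examples
#' sim <- simulate_trace_cohort(2, c(WT = 3, KO = 2.5), age_months = 5,
#'                              n_cells = 1000, seed = 1)
#' expansion_index(sim$traces[[1]])
#' @export
simulate_trace_cohort <- function(n_mice_per_group,
                                  genotype_rate,
                                  age_months,
                                  stable_fraction = 0,
                                  n_cells = 10000,
                                  modal_repeat = 111,
                                  height_noise_cv = 0,
                                  seed) {
  if (missing(seed)) stop("simulate_trace_cohort: seed is required",
                          call. = FALSE)
  stopifnot(n_mice_per_group >= 1, n_cells >= 1, age_months > 0,
            stable_fraction >= 0, stable_fraction <= 1,
            height_noise_cv >= 0)
  if (is.null(names(genotype_rate)) || any(genotype_rate < 0)) {
    stop("simulate_trace_cohort: genotype_rate must be a named vector of nonnegative rates",
         call. = FALSE)
  }
  with_seed(seed, {
    traces <- list()
    truth <- NULL
    for (g in names(genotype_rate)) {
      lam <- genotype_rate[[g]] * age_months
      for (m in seq_len(n_mice_per_group)) {
        id <- sprintf("%s_m%02d", g, m)
        stable <- stats::rbinom(1, n_cells, stable_fraction)
        gains <- if (n_cells - stable > 0) {
          stats::rpois(n_cells - stable, lam)
        } else integer(0)
        changes <- c(rep(0L, stable), gains)
        tab <- table(changes)
        lens <- modal_repeat + as.integer(names(tab))
        h <- as.numeric(tab)
        if (height_noise_cv > 0) {
          sdlog <- sqrt(log(1 + height_noise_cv^2))
          h <- h * stats::rlnorm(length(h), meanlog = -sdlog^2 / 2,
                                 sdlog = sdlog)
        }
        traces[[id]] <- peak_trace(id, lens, h)
        truth <- rbind(truth, data.frame(
          mouse_id = id, genotype = g,
          true_index = (1 - stable_fraction) * lam))
      }
    }
    list(traces = traces, truth = truth)
  })
}

#' Simulate a four-genotype-group RNA-seq count matrix with planted truth
#'
#' Generates negative-binomial counts (`variance = mu + dispersion * mu^2`)
#' for the four Htt x Hdac genotype groups with disjoint planted gene
#' classes.  With baseline mean `b` and effect `delta` (log2 units), group
#' means are shifted as follows (WT_WT, Q111_WT, WT_KO, Q111_KO):
#' \describe{
#'   \item{null}{0, 0, 0, 0}
#'   \item{q111_up / q111_down}{disease-allele shift +/-delta in both
#'     Q111 groups}
#'   \item{ko_up / ko_down}{knockout shift +/-delta in both KO groups}
#'   \item{rescued_up / rescued_down}{+/-delta in Q111_WT only; the double
#'     mutant reverts to baseline (complete rescue)}
#'   \item{exacerbated}{+/-delta in Q111_WT and WT_KO, +/-2*delta in
#'     Q111_KO (the knockout doubles the disease-direction shift); the
#'     direction is split evenly up/down within the class}
#' }
#' Library sizes are equal in expectation: planted classes are split into
#' up/down halves and the baselines of the down-shifted members are
#' rescaled so the expected count mass gained by up-shifted genes equals
#' the mass lost by down-shifted ones in every group.  (The double-shift
#' group of the exacerbated class retains a small residual excess, a few
#' percent of one library at the default fractions.)  Composition effects
#' on CPM are therefore negligible and no size factors are planted.
#'
#' @param n_genes Number of genes (default 5000).
#' @param group_sizes Named integer vector of samples per group; the
#'   default `c(WT_WT = 8, Q111_WT = 7, WT_KO = 9, Q111_KO = 11)` mirrors a
#'   realistic post-QC striatal cohort.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline mean counts (defaults meanlog `log(100)`, sdlog 1.3).
#' @param dispersion NB dispersion (default 0.05).
#' @param fractions Named fractions of genes per planted class
#'   (`q111_up`, `q111_down`, `ko_up`, `ko_down`, `rescued`, `exacerbated`);
#'   must sum to <= 1; `rescued` is split evenly into up/down.
#' @param delta Planted effect size in log2 units (default 1.5).
#' @param seed Integer RNG seed (required).
#' @return List with `counts` (genes x samples integer matrix), `meta`
#'   (data.frame `sample_id`, `htt_genotype`, `hdac_genotype`, `sex`,
#'   `batch`), and `truth` (data.frame `gene_id`, `class`).
#' @export
simulate_count_matrix <- function(n_genes = 5000,
                                  group_sizes = c(WT_WT = 8, Q111_WT = 7,
                                                  WT_KO = 9, Q111_KO = 11),
                                  baseline_meanlog = log(100),
                                  baseline_sdlog = 1.3,
                                  dispersion = 0.05,
                                  fractions = c(q111_up = 0.015,
                                                q111_down = 0.015,
                                                ko_up = 0.055,
                                                ko_down = 0.055,
                                                rescued = 0.02,
                                                exacerbated = 0.02),
                                  delta = 1.5,
                                  seed) {
  if (missing(seed)) stop("simulate_count_matrix: seed is required",
                          call. = FALSE)
  groups <- c("WT_WT", "Q111_WT", "WT_KO", "Q111_KO")
  if (!all(groups %in% names(group_sizes))) {
    stop("simulate_count_matrix: group_sizes needs all four genotype groups",
         call. = FALSE)
  }
  frac_names <- c("q111_up", "q111_down", "ko_up", "ko_down", "rescued",
                  "exacerbated")
  fr <- stats::setNames(rep(0, length(frac_names)), frac_names)
  fr[names(fractions)] <- fractions
  if (any(fr < 0) || sum(fr) > 1 + 1e-12) {
    stop("simulate_count_matrix: fractions must be nonnegative and sum to <= 1",
         call. = FALSE)
  }
  stopifnot(n_genes >= 1, dispersion > 0, delta > 0)

  n_class <- stats::setNames(floor(fr * n_genes), frac_names)
  half <- function(n) c(floor(n / 2), n - floor(n / 2))
  n_resc <- half(n_class[["rescued"]])
  n_exac <- half(n_class[["exacerbated"]])
  classes <- c(rep("q111_up", n_class[["q111_up"]]),
               rep("q111_down", n_class[["q111_down"]]),
               rep("ko_up", n_class[["ko_up"]]),
               rep("ko_down", n_class[["ko_down"]]),
               rep("rescued_up", n_resc[1]),
               rep("rescued_down", n_resc[2]),
               rep("exacerbated_up", n_exac[1]),
               rep("exacerbated_down", n_exac[2]))
  if (length(classes) > n_genes) {
    stop("simulate_count_matrix: planted classes exceed n_genes", call. = FALSE)
  }
  classes <- c(classes, rep("null", n_genes - length(classes)))

  # log2 shift of each class per group: WT_WT, Q111_WT, WT_KO, Q111_KO
  shift <- function(cl) {
    switch(cl,
      null = c(0, 0, 0, 0),
      q111_up = c(0, delta, 0, delta),
      q111_down = c(0, -delta, 0, -delta),
      ko_up = c(0, 0, delta, delta),
      ko_down = c(0, 0, -delta, -delta),
      rescued_up = c(0, delta, 0, 0),
      rescued_down = c(0, -delta, 0, 0),
      exacerbated_up = c(0, delta, delta, 2 * delta),
      exacerbated_down = c(0, -delta, -delta, -2 * delta))
  }
  shift_mat <- t(vapply(classes, shift, numeric(4)))  # genes x 4
  colnames(shift_mat) <- groups

  sample_group <- rep(groups, times = group_sizes[groups])
  n_samp <- length(sample_group)
  sample_ids <- sprintf("s%02d_%s", seq_len(n_samp), sample_group)
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, meanlog = baseline_meanlog,
                          sdlog = baseline_sdlog)
    # library balance: within each up/down class pair, rescale the
    # down-members' baselines so the expected mass gained by the up
    # members equals the mass lost by the down members (computed at the
    # single-shift magnitude delta; the 2*delta group of the exacerbated
    # class keeps a small residual)
    gain <- 2^delta - 1
    loss <- 1 - 2^(-delta)
    for (pair in list(c("q111_up", "q111_down"), c("ko_up", "ko_down"),
                      c("rescued_up", "rescued_down"),
                      c("exacerbated_up", "exacerbated_down"))) {
      up <- classes == pair[1]
      dn <- classes == pair[2]
      if (any(up) && any(dn)) {
        base[dn] <- base[dn] *
          (sum(base[up]) * gain) / (sum(base[dn]) * loss)
      }
    }
    mu <- base * 2^shift_mat[, sample_group, drop = FALSE]
    counts <- matrix(stats::rnbinom(n_genes * n_samp,
                                    size = 1 / dispersion, mu = mu),
                     nrow = n_genes)
    dimnames(counts) <- list(sprintf("gene%05d", seq_len(n_genes)),
                             sample_ids)
    meta <- data.frame(
      sample_id = sample_ids,
      htt_genotype = ifelse(grepl("^Q111", sample_group), "Q111", "WT"),
      hdac_genotype = ifelse(grepl("_KO$", sample_group), "KO", "WT"),
      sex = rep_len(c("M", "F"), n_samp),
      batch = "b1")
    truth <- data.frame(gene_id = rownames(counts),
                        class = sub("^exacerbated_(up|down)$", "exacerbated",
                                    classes))
    list(counts = counts, meta = meta, truth = truth)
  })
}

#' Simulate per-mouse nuclear intensities coupled to expansion indices
#'
#' `intensity = intercept + slope * index + Normal(0, noise_sd)`, one value
#' per mouse, seeded.
#'
#' @param true_indices Named numeric vector of per-mouse expansion indices.
#' @param intercept,slope Linear coupling parameters.
#' @param noise_sd Additive Gaussian noise sd (>= 0).
#' @param seed Integer RNG seed (required).
#' @return Named numeric vector of intensities, same names as
#'   `true_indices`.
#' @export
simulate_intensities <- function(true_indices, intercept, slope, noise_sd,
                                 seed) {
  if (missing(seed)) stop("simulate_intensities: seed is required",
                          call. = FALSE)
  stopifnot(noise_sd >= 0)
  with_seed(seed, {
    out <- intercept + slope * as.numeric(true_indices) +
      stats::rnorm(length(true_indices), 0, noise_sd)
    names(out) <- names(true_indices)
    out
  })
}
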