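#' Summarize per-image nuclear quantifications into per-mouse phenotypes
#'
#' Each image contributes the integrated staining intensity normalized by
#' its total nucleus count (`integrated_intensity / n_total_nuclei`), and,
#' when inclusion counts are present, the percentage of nuclei carrying an
#' inclusion (`100 * n_inclusions / n_total_nuclei`).  Per mouse, images are
#' combined by an unweighted mean (the aggregation is per image, not per
#' pooled nucleus).
#'
#' @param images Data frame with columns `mouse_id`, `image_id`,
#'   `integrated_intensity`, `n_positive_nuclei`, `n_total_nuclei` and
#'   optionally `n_inclusions`.
#' @return Data frame with one row per mouse: `mouse_id`, `n_images`,
#'   `mean_intensity_per_nucleus`, and `pct_nuclei_with_inclusion` when
#'   inclusion counts were given.
#' @examples
#' img <- data.frame(mouse_id = "m1", image_id = paste0("i", 1:4),
#'                   integrated_intensity = c(100, 100, 200, 200),
#'                   n_positive_nuclei = 40, n_total_nuclei = 50)
#' summarize_intensity(img)  # mean per-nucleus intensity 3
#' @export
summarize_intensity <- function(images) {
  req <- c("mouse_id", "image_id", "integrated_intensity",
           "n_positive_nuclei", "n_total_nuclei")
  if (!all(req %in% names(images))) {
    stop("summarize_intensity: missing columns: ",
         paste(setdiff(req, names(images)), collapse = ", "), call. = FALSE)
  }
  bad <- images$n_total_nuclei <= 0
  if (any(bad)) {
    stop("summarize_intensity: zero total nuclei in image(s): ",
         paste(images$image_id[bad], collapse = ", "), call. = FALSE)
  }
  if (any(images$n_positive_nuclei > images$n_total_nuclei)) {
    stop("summarize_intensity: more positive than total nuclei", call. = FALSE)
  }
  if (any(images$integrated_intensity < 0)) {
    stop("summarize_intensity: negative intensity", call. = FALSE)
  }
  per_img <- images$integrated_intensity / images$n_total_nuclei
  ids <- unique(as.character(images$mouse_id))
  out <- data.frame(
    mouse_id = ids,
    n_images = as.integer(table(factor(images$mouse_id, levels = ids))),
    mean_intensity_per_nucleus = as.numeric(
      tapply(per_img, factor(images$mouse_id, levels = ids), mean)))
  if ("n_inclusions" %in% names(images) && !all(is.na(images$n_inclusions))) {
    pct <- 100 * images$n_inclusions / images$n_total_nuclei
    out$pct_nuclei_with_inclusion <- as.numeric(
      tapply(pct, factor(images$mouse_id, levels = ids),
             function(v) mean(v, na.rm = TRUE)))
  }
  out
}

#' Compare a per-mouse phenotype between two genotype groups
#'
#' Two-tailed unpaired t-test on per-mouse phenotype values (delegates to
#' [two_sample_ttest]).
#'
#' @param pheno_a,pheno_b Numeric vectors of per-mouse values, or data
#'   frames from [summarize_intensity] (then
#'   `mean_intensity_per_nucleus` is used).
#' @param variance_mode Passed to [two_sample_ttest].
#' @return A `group_comparison`.
#' @export
phenotype_group_compare <- function(pheno_a, pheno_b,
                                    variance_mode = "pooled") {
  vals <- function(p) {
    if (is.data.frame(p)) p$mean_intensity_per_nucleus else as.numeric(p)
  }
  two_sample_ttest(vals(pheno_a), vals(pheno_b),
                   variance_mode = variance_mode)
}

#' Correlate nuclear-staining intensity with expansion index across mice
#'
#' Pairs the two per-mouse measures by `mouse_id` and computes the Pearson
#' correlation with its two-sided p-value.
#'
#' @param expansion Data frame with columns `mouse_id`, `index`, or a named
#'   numeric vector.
#' @param intensity Data frame with columns `mouse_id`,
#'   `mean_intensity_per_nucleus`, or a named numeric vector.
#' @return A `correlation_result`.
#' @export
correlate_intensity_expansion <- function(expansion, intensity) {
  as_named <- function(x, col) {
    if (is.data.frame(x)) {
      stats::setNames(x[[col]], x$mouse_id)
    } else if (!is.null(names(x))) {
      x
    } else {
      stop("correlate_intensity_expansion: inputs must be keyed by mouse_id",
           call. = FALSE)
    }
  }
  e <- as_named(expansion, "index")
  i <- as_named(intensity, "mean_intensity_per_nucleus")
  common <- intersect(names(e), names(i))
  unmatched <- c(setdiff(names(e), common), setdiff(names(i), common))
  if (length(unmatched)) {
    stop("correlate_intensity_expansion: unpaired mice: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  if (anyNA(e[common]) || anyNA(i[common])) {
    stop("correlate_intensity_expansion: missing values for mice: ",
         paste(common[is.na(e[common]) | is.na(i[common])], collapse = ", "),
         call. = FALSE)
  }
  pearson_correlation(e[common], i[common])
}
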