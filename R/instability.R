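#' Construct a fragment-analysis peak trace
#'
#' A peak trace is one sample's repeat-length profile from a fragment
#' analysis run (e.g. a GeneMapper export of a PCR across the HTT CAG
#' tract): a map from CAG repeat length to fluorescence peak height.
#'
#' @param sample_id Sample identifier (single string).
#' @param repeat_units Integer vector of distinct CAG repeat lengths.
#' @param height Nonnegative numeric vector of peak heights (arbitrary
#'   fluorescence units), same length as `repeat_units`; at least one must
#'   be positive.
#' @return An object of class `peak_trace`.
#' @examples
#' peak_trace("m1", c(111, 112, 113), c(600, 300, 100))
#' @export
peak_trace <- function(sample_id, repeat_units, height) {
  stopifnot(length(sample_id) == 1L)
  repeat_units <- as.numeric(repeat_units)
  height <- as.numeric(height)
  if (length(repeat_units) != length(height) || length(height) == 0L) {
    stop("peak_trace: repeat_units and height must be nonempty and of equal length",
         call. = FALSE)
  }
  if (any(abs(repeat_units - round(repeat_units)) > 1e-6)) {
    stop("peak_trace: repeat units must be integers", call. = FALSE)
  }
  repeat_units <- as.integer(round(repeat_units))
  if (anyDuplicated(repeat_units)) {
    stop("peak_trace: duplicate repeat lengths", call. = FALSE)
  }
  if (anyNA(height) || any(height < 0)) {
    stop("peak_trace: heights must be nonnegative", call. = FALSE)
  }
  if (!any(height > 0)) {
    stop("peak_trace: at least one peak height must be positive", call. = FALSE)
  }
  ord <- order(repeat_units)
  structure(
    list(sample_id = as.character(sample_id),
         peaks = data.frame(repeat_units = repeat_units[ord],
                            height = height[ord])),
    class = "peak_trace")
}

#' @export
print.peak_trace <- function(x, ...) {
  cat(sprintf("Peak trace '%s': %d peaks, repeats %d-%d\n",
              x$sample_id, nrow(x$peaks),
              min(x$peaks$repeat_units), max(x$peaks$repeat_units)))
  invisible(x)
}

#' Read a long-format peak table into peak traces
#'
#' Expects a TSV with header columns `sample_id`, `height` and either
#' `repeat_units` (integer CAG counts) or `fragment_size` (bp).  Fragment
#' sizes are converted with `repeat_units = round((fragment_size -
#' fragment_offset) / fragment_unit)`; the offset (non-repeat flank length
#' of the amplicon) must then be supplied explicitly -- there is no
#' instrument autodetection.  Zero-height rows are dropped; duplicated
#' (sample, repeat) pairs are an error.
#'
#' @param path Path to the TSV file.
#' @param fragment_offset Optional numeric: bp occupied by non-repeat
#'   sequence, required when the file has `fragment_size` instead of
#'   `repeat_units`.
#' @param fragment_unit bp per repeat unit (default 3 for CAG).
#' @return A named list of [peak_trace] objects, one per sample.
#' @export
read_peak_table <- function(path, fragment_offset = NULL, fragment_unit = 3) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  if (!"sample_id" %in% names(tab) || !"height" %in% names(tab)) {
    stop("read_peak_table: columns 'sample_id' and 'height' are required",
         call. = FALSE)
  }
  if ("repeat_units" %in% names(tab)) {
    ru <- as.numeric(tab$repeat_units)
    if (any(abs(ru - round(ru)) > 1e-6)) {
      stop("read_peak_table: non-integer repeat_units", call. = FALSE)
    }
  } else if ("fragment_size" %in% names(tab)) {
    if (is.null(fragment_offset)) {
      stop("read_peak_table: fragment_size column requires fragment_offset",
           call. = FALSE)
    }
    ru <- round((as.numeric(tab$fragment_size) - fragment_offset) / fragment_unit)
  } else {
    stop("read_peak_table: need a 'repeat_units' or 'fragment_size' column",
         call. = FALSE)
  }
  h <- as.numeric(tab$height)
  if (anyNA(h) || any(h < 0)) {
    stop("read_peak_table: heights must be nonnegative", call. = FALSE)
  }
  keep <- h > 0
  tab <- data.frame(sample_id = as.character(tab$sample_id),
                    repeat_units = as.integer(ru), height = h)[keep, ]
  if (anyDuplicated(tab[c("sample_id", "repeat_units")])) {
    stop("read_peak_table: duplicated (sample_id, repeat_units) rows",
         call. = FALSE)
  }
  ids <- unique(tab$sample_id)
  traces <- lapply(ids, function(id) {
    sub <- tab[tab$sample_id == id, ]
    peak_trace(id, sub$repeat_units, sub$height)
  })
  names(traces) <- ids
  traces
}

#' Call the main (modal) allele of a trace
#'
#' The modal allele is the repeat length of the highest peak; ties are
#' broken toward the smaller repeat length.
#'
#' @param trace A [peak_trace].
#' @return Integer repeat length.
#' @export
call_main_allele <- function(trace) {
  stopifnot(inherits(trace, "peak_trace"))
  p <- trace$peaks
  # peaks are sorted by repeat length, so which.max takes the smaller tie
  p$repeat_units[which.max(p$height)]
}

#' Expansion index of a peak trace
#'
#' Quantifies the mean positive CAG-length change in the sampled cell
#' population.  Peaks strictly to the right of the modal allele are the
#' expansion peaks; each is normalized by the summed height of the main
#' allele plus all (retained) expansion peaks, multiplied by its CAG change
#' from the main allele, and the products are summed:
#' `index = sum h_i * d_i`.  Contraction peaks (left of the modal allele)
#' enter neither numerator nor denominator.
#'
#' @param trace A [peak_trace].
#' @param min_relative_height Retain only expansion peaks whose height is at
#'   least this fraction of the main-allele peak height.  Default 0 (no
#'   filtering), the convention used for striatal indices.
#' @return An object of class `expansion_result`: list with `sample_id`,
#'   `modal_repeat`, `index`, and `contributions` (data.frame with columns
#'   `cag_change`, `normalized_height`).
#' @examples
#' tr <- peak_trace("m1", c(111, 112, 113), c(600, 300, 100))
#' expansion_index(tr)$index  # 0.3*1 + 0.1*2 = 0.5
#' @export
expansion_index <- function(trace, min_relative_height = 0) {
  stopifnot(inherits(trace, "peak_trace"),
            min_relative_height >= 0, min_relative_height <= 1)
  modal <- call_main_allele(trace)
  p <- trace$peaks
  h_main <- p$height[p$repeat_units == modal]
  exp_peaks <- p[p$repeat_units > modal, , drop = FALSE]
  exp_peaks <- exp_peaks[exp_peaks$height >= min_relative_height * h_main &
                           exp_peaks$height > 0, , drop = FALSE]
  if (nrow(exp_peaks) == 0L) {
    contributions <- data.frame(cag_change = integer(0),
                                normalized_height = numeric(0))
    index <- 0
  } else {
    denom <- h_main + sum(exp_peaks$height)
    h_i <- exp_peaks$height / denom
    d_i <- exp_peaks$repeat_units - modal
    contributions <- data.frame(cag_change = d_i, normalized_height = h_i)
    index <- sum(h_i * d_i)
  }
  structure(list(sample_id = trace$sample_id, modal_repeat = modal,
                 index = index, contributions = contributions),
            class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf("Expansion index '%s': modal CAG %d, index %.4g (%d expansion peaks)\n",
              x$sample_id, x$modal_repeat, x$index, nrow(x$contributions)))
  invisible(x)
}

#' Compare expansion indices between two genotype groups
#'
#' Two-tailed unpaired t-test on the per-mouse expansion indices, the
#' group-level comparison reported for instability cohorts.
#'
#' @param results_a,results_b Lists of `expansion_result` objects (or plain
#'   numeric index vectors), at least 2 mice per group.
#' @param variance_mode Passed to [two_sample_ttest].
#' @return A `group_comparison`.
#' @export
instability_group_compare <- function(results_a, results_b,
                                      variance_mode = "pooled") {
  idx <- function(r) {
    if (is.numeric(r)) return(as.numeric(r))
    vapply(r, function(x) {
      stopifnot(inherits(x, "expansion_result"))
      x$index
    }, numeric(1))
  }
  two_sample_ttest(idx(results_a), idx(results_b),
                   variance_mode = variance_mode)
}

#' Contraction-assay fold changes over a reference condition
#'
#' For a selectable contraction assay (reporter reactivated by repeat
#' contraction), the positive-colony count of each condition is adjusted by
#' cell survival, `adjusted = positives / (plated * plating_efficiency)`,
#' optionally scaled by a survival fraction, and expressed as fold change of
#' the adjusted rate over the reference (vehicle) condition.  Replicate rows
#' of a condition are averaged on the adjusted-rate scale.
#'
#' @param records Data frame with columns `condition`, `positive_colonies`,
#'   `plated_cells`, `plating_efficiency` and optionally `survival_fraction`
#'   (defaults to 1).
#' @param reference_condition Condition used as denominator (e.g. "DMSO").
#' @return Named numeric vector of fold changes; the reference maps to 1.
#' @examples
#' rec <- data.frame(condition = c("DMSO", "SAHA"),
#'                   positive_colonies = c(10, 30),
#'                   plated_cells = 4.5e6, plating_efficiency = 0.5)
#' contraction_fold_change(rec, "DMSO")  # SAHA -> 3
#' @export
contraction_fold_change <- function(records, reference_condition) {
  req <- c("condition", "positive_colonies", "plated_cells",
           "plating_efficiency")
  if (!all(req %in% names(records))) {
    stop("contraction_fold_change: missing columns: ",
         paste(setdiff(req, names(records)), collapse = ", "), call. = FALSE)
  }
  surv <- if ("survival_fraction" %in% names(records)) {
    as.numeric(records$survival_fraction)
  } else rep(1, nrow(records))
  if (any(records$plated_cells <= 0) || any(records$plating_efficiency <= 0) ||
      any(records$plating_efficiency > 1) || any(surv <= 0) || any(surv > 1)) {
    stop("contraction_fold_change: invalid plated/efficiency/survival values",
         call. = FALSE)
  }
  if (any(records$positive_colonies < 0)) {
    stop("contraction_fold_change: negative colony counts", call. = FALSE)
  }
  adj <- records$positive_colonies /
    (records$plated_cells * records$plating_efficiency * surv)
  by_cond <- tapply(adj, as.character(records$condition), mean)
  if (!reference_condition %in% names(by_cond)) {
    stop("contraction_fold_change: reference condition '",
         reference_condition, "' absent", call. = FALSE)
  }
  ref <- by_cond[[reference_condition]]
  if (ref <= 0) {
    stop("contraction_fold_change: reference condition has zero adjusted rate",
         call. = FALSE)
  }
  fold <- by_cond / ref
  fold[names(by_cond)]
}

#' Write per-sample expansion results
#'
#' Writes a TSV (`sample_id`, `modal_repeat`, `index`) and a JSON report
#' including the per-peak contributions.
#'
#' @param results List of `expansion_result` objects.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_expansion_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(
    sample_id = vapply(results, `[[`, character(1), "sample_id"),
    modal_repeat = vapply(results, `[[`, numeric(1), "modal_repeat"),
    index = vapply(results, `[[`, numeric(1), "index"))
  tsv <- file.path(out_dir, "expansion_indices.tsv")
  data.table::fwrite(tab, tsv, sep = "\t")
  js <- file.path(out_dir, "expansion_report.json")
  jsonlite::write_json(
    lapply(results, function(r) {
      list(sample_id = r$sample_id, modal_repeat = r$modal_repeat,
           index = r$index, contributions = r$contributions)
    }),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}
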