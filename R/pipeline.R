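#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (typically parsed from a JSON file)
#' with elements: `stages` (character vector, in any order; dependencies
#' are resolved), `seed` (integer), `out_dir`, plus per-stage parameter
#' blocks (`trace_sim`, `count_sim`, `de`, `overlap`, `permutation`) and
#' optional `thresholds` (`alpha`, `min_count`, `n_perm`).
#'
#' @param config Named list or path to a JSON config file.
#' @return The validated config list (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("validate_config: config file not found: ", config, call. = FALSE)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("validate_config: config must be a list",
                             call. = FALSE)
  known <- c("simulate_traces", "expansion", "instability_compare",
             "simulate_counts", "de", "overlap_rescue")
  if (is.null(config$stages) || !all(config$stages %in% known)) {
    stop("validate_config: stages must be drawn from: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed)))) {
    stop("validate_config: integer seed is required", call. = FALSE)
  }
  config$seed <- as.integer(config$seed)
  if (is.null(config$out_dir)) {
    stop("validate_config: out_dir is required", call. = FALSE)
  }
  th <- config$thresholds
  defaults <- list(alpha = 0.05, min_count = 6, n_perm = 1000)
  for (nm in names(defaults)) {
    if (is.null(th[[nm]])) th[[nm]] <- defaults[[nm]]
  }
  if (th$alpha <= 0 || th$alpha >= 1) {
    stop("validate_config: alpha must lie in (0, 1)", call. = FALSE)
  }
  if (th$min_count < 0) stop("validate_config: min_count must be >= 0",
                             call. = FALSE)
  if (th$n_perm < 1) stop("validate_config: n_perm must be >= 1",
                          call. = FALSE)
  config$thresholds <- th
  for (f in config$input_files) {
    if (!file.exists(f)) {
      stop("validate_config: referenced file does not exist: ", f,
           call. = FALSE)
    }
  }
  config
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
}

#' Run configured pipeline stages end-to-end
#'
#' Executes the requested stages in dependency order
#' (simulate_traces -> expansion -> instability_compare;
#' simulate_counts -> de -> overlap_rescue), writes each stage's TSV/JSON
#' outputs under `out_dir`, and finishes with a `manifest.json` recording
#' the config, seed, stage outputs with md5 checksums, and the package
#' version.  Identical config + seed yields byte-identical result files.
#'
#' @param config Named list or JSON path (see [validate_config]).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  order_all <- c("simulate_traces", "expansion", "instability_compare",
                 "simulate_counts", "de", "overlap_rescue")
  stages <- order_all[order_all %in% config$stages]
  needs <- list(expansion = "simulate_traces",
                instability_compare = "expansion",
                de = "simulate_counts",
                overlap_rescue = "de")
  state <- list()
  outputs <- list()
  th <- config$thresholds

  for (st in stages) {
    dep <- needs[[st]]
    if (!is.null(dep) && is.null(state[[dep]])) {
      stop("run_pipeline: stage '", st, "' requires upstream stage '",
           dep, "'", call. = FALSE)
    }
    pipeline_log("stage %s", st)
    if (st == "simulate_traces") {
      ts <- config$trace_sim
      state$simulate_traces <- simulate_trace_cohort(
        n_mice_per_group = ts$n_mice_per_group %||% 10,
        # defaults give 5-month expected indices 15.25 (WT) vs 12.75 (KO)
        # with half the bulk-striatum cells (non-MSN) stable
        genotype_rate = unlist(ts$genotype_rate %||%
                                 list(WT = 6.1, KO = 5.1)),
        age_months = ts$age_months %||% 5,
        stable_fraction = ts$stable_fraction %||% 0.5,
        n_cells = ts$n_cells %||% 10000,
        modal_repeat = ts$modal_repeat %||% 111,
        height_noise_cv = ts$height_noise_cv %||% 0.05,
        seed = config$seed)
      f <- file.path(config$out_dir, "trace_truth.tsv")
      data.table::fwrite(state$simulate_traces$truth, f, sep = "\t")
      outputs[[st]] <- f
    } else if (st == "expansion") {
      res <- lapply(state$simulate_traces$traces, expansion_index)
      state$expansion <- res
      outputs[[st]] <- unname(write_expansion_results(res, config$out_dir))
    } else if (st == "instability_compare") {
      truth <- state$simulate_traces$truth
      gts <- unique(truth$genotype)
      if (length(gts) != 2L) {
        stop("run_pipeline: instability_compare needs exactly 2 genotypes",
             call. = FALSE)
      }
      res <- state$expansion
      idx_of <- function(g) res[truth$mouse_id[truth$genotype == g]]
      cmp <- instability_group_compare(idx_of(gts[1]), idx_of(gts[2]))
      f <- file.path(config$out_dir, "instability_compare.json")
      jsonlite::write_json(unclass(cmp), f, auto_unbox = TRUE, digits = NA)
      state$instability_compare <- cmp
      outputs[[st]] <- f
    } else if (st == "simulate_counts") {
      cs <- config$count_sim
      args <- list(seed = config$seed)
      for (nm in c("n_genes", "dispersion", "delta")) {
        if (!is.null(cs[[nm]])) args[[nm]] <- cs[[nm]]
      }
      if (!is.null(cs$group_sizes)) args$group_sizes <- unlist(cs$group_sizes)
      if (!is.null(cs$fractions)) args$fractions <- unlist(cs$fractions)
      state$simulate_counts <- do.call(simulate_count_matrix, args)
      f <- file.path(config$out_dir, "sample_meta.tsv")
      data.table::fwrite(state$simulate_counts$meta, f, sep = "\t")
      f2 <- file.path(config$out_dir, "gene_truth.tsv")
      data.table::fwrite(state$simulate_counts$truth, f2, sep = "\t")
      outputs[[st]] <- c(f, f2)
    } else if (st == "de") {
      sim <- state$simulate_counts
      filt <- filter_genes(sim$counts, sim$meta, min_count = th$min_count)
      ids <- config$de$contrasts %||% c(3, 2)
      degs <- lapply(ids, function(i) de_test(filt, sim$meta, i))
      names(degs) <- paste0("contrast", ids)
      paths <- vapply(names(degs), function(nm) {
        f <- file.path(config$out_dir, paste0("deg_", nm, ".tsv"))
        write_deg_table(degs[[nm]], f)
      }, character(1))
      state$de <- list(degs = degs, filtered = filt)
      outputs[[st]] <- unname(paths)
    } else if (st == "overlap_rescue") {
      sim <- state$simulate_counts
      degs <- state$de$degs
      if (length(degs) < 2L) {
        stop("run_pipeline: overlap_rescue needs two DE contrasts",
             call. = FALSE)
      }
      ov <- directional_overlap(degs[[1]], degs[[2]], alpha = th$alpha)
      expr <- normalize_log_cpm(state$de$filtered)
      rc <- rescue_classify(expr, sim$meta, ov, alpha = th$alpha)
      f <- file.path(config$out_dir, "overlap_cells.tsv")
      data.table::fwrite(
        data.frame(cell = names(ov$counts), n = as.integer(ov$counts)),
        f, sep = "\t")
      f2 <- file.path(config$out_dir, "rescued_genes.tsv")
      data.table::fwrite(
        data.frame(gene_id = c(rc$rescued_opposite_up,
                               rc$rescued_opposite_down),
                   direction = c(rep("up_by_disease",
                                     length(rc$rescued_opposite_up)),
                                 rep("down_by_disease",
                                     length(rc$rescued_opposite_down)))),
        f2, sep = "\t")
      state$overlap_rescue <- list(overlap = ov, rescue = rc)
      outputs[[st]] <- c(f, f2)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cagdyn")),
    seed = config$seed,
    thresholds = th,
    stages = stages,
    outputs = lapply(outputs, function(fs)
      lapply(fs, function(f) list(path = basename(f),
                                  md5 = unname(tools::md5sum(f))))))
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  pipeline_log("done: %d stage(s), manifest at %s", length(stages), mf)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
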